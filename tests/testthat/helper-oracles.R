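# Independent oracles used across the test files.

# Exhaustive switch-point search for the Karnik-Mendel centroids:
# enumerate every switch point k in 0..n and take min/max.
km_exhaustive <- function(x, up, lo) {
  n <- length(x)
  yl <- Inf; yr <- -Inf
  for (k in 0:n) {
    wl <- lo; wr <- up
    if (k > 0) {
      wl[seq_len(k)] <- up[seq_len(k)]
      wr[seq_len(k)] <- lo[seq_len(k)]
    }
    if (sum(wl) > 0) yl <- min(yl, sum(wl * x) / sum(wl))
    if (sum(wr) > 0) yr <- max(yr, sum(wr * x) / sum(wr))
  }
  c(yl = yl, yr = yr)
}

# Brute-force Mamdani truncate-and-max aggregation, written directly
# from the triangle formula (independent of consequent_grid / infer).
brute_aggregate <- function(consequents, firing, out_part, n_grid = 1001L) {
  wmax <- max(out_part$w)
  grid <- seq(out_part$universe[1] - out_part$half - wmax,
              out_part$universe[2] + out_part$half + wmax,
              length.out = n_grid)
  ns <- length(out_part$z)
  up <- matrix(0, ns, n_grid); lo <- matrix(0, ns, n_grid)
  for (r in seq_along(consequents)) {
    pk <- out_part$peaks[consequents[r]]
    f <- firing[[r]]
    fm <- if (is.matrix(f)) f else matrix(rep(f, each = ns), ns)
    for (s in seq_len(ns)) {
      mu_up <- pmax(0, 1 - abs(grid - pk) / (out_part$half + out_part$w[s]))
      mu_lo <- pmax(0, 1 - abs(grid - pk) / (out_part$half - out_part$w[s]))
      up[s, ] <- pmax(up[s, ], pmin(fm[s, 2], mu_up))
      lo[s, ] <- pmax(lo[s, ], pmin(fm[s, 1], mu_lo))
    }
  }
  list(grid = grid, upper = up, lower = lo, z = out_part$z)
}

# Type-1 Mamdani centroid oracle for a set of fired rules
t1_mamdani <- function(consequents, strengths, out_part, n_grid = 2001L) {
  grid <- seq(out_part$universe[1] - out_part$half,
              out_part$universe[2] + out_part$half, length.out = n_grid)
  env <- numeric(n_grid)
  for (r in seq_along(consequents)) {
    mu <- pmax(0, 1 - abs(grid - out_part$peaks[consequents[r]]) /
                 out_part$half)
    env <- pmax(env, pmin(strengths[r], mu))
  }
  sum(env * grid) / sum(env)
}

# Continuous-time delay-ODE oracle for a linear block in modal form,
# integrated with deSolve::dede, fed a zero-order-held input sequence.
ode_block_response <- function(block, u, dt) {
  m <- soflc:::block_modes(block)
  times <- seq(0, length(u) * dt, by = dt)
  ufun <- function(t) {
    i <- floor(t / dt) + 1
    if (t >= length(u) * dt) u[length(u)] else u[max(1, i)]
  }
  deriv <- function(t, y, parms) {
    list(-m$p * y + m$r * ufun(t))
  }
  sol <- deSolve::ode(y = numeric(length(m$p)), times = times,
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = 1e-9, atol = 1e-11)
  pre <- rowSums(sol[, -1, drop = FALSE])
  # apply the pure delay by shifting the output in time
  outt <- times - block$dead_time
  y <- stats::approx(times, pre, xout = pmax(0, outt), rule = 2)$y
  y[outt < 0] <- 0
  y[-1]  # drop t = 0, align with block_response sampling
}

short_cfg <- function(...) {
  simulation_config(duration = 60, stage_switch = 30,
                    noise = noise_config(param_fraction = 0.01,
                                         meas_fraction = 0.1), ...)
}
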