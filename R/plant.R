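#' Multivariable anesthetic patient model parameters
#'
#' Bundles the transfer-function blocks and Hill curve of the two-drug
#' patient model. Atracurium infusion `u1` drives neuromuscular block
#' through the pharmacodynamic block `g11` (three poles, one zero, 1 min
#' dead time) followed by the Hill curve; inhaled isoflurane `u2` lowers
#' mean arterial pressure through the first-order block `g22`
#' (gain -15 mmHg/percent, 0.42 min dead time) and additionally deepens
#' paralysis through the interaction block `g12` (gain 0.27). Atracurium
#' has no effect on MAP: the coupling matrix is lower-triangular.
#'
#' The interaction can enter either in the concentration domain
#' (`interaction = "pre_hill"`, default: the Hill curve sees the sum of
#' the two linear-path outputs as total effect-site concentration) or be
#' added to the normalized paralysis after the Hill curve
#' (`"post_hill"`). The pre-Hill form keeps the linear superposition of
#' the coupling matrix ahead of the single static nonlinearity and makes
#' both stages of the surgical protocol reachable by a controller whose
#' output increments are nonnegative; see the package vignette.
#'
#' @param g11 atracurium pharmacodynamic [linear_block()].
#' @param hill [hill_params()] for the concentration-effect curve.
#' @param g22 isoflurane-to-MAP [linear_block()].
#' @param g12 isoflurane-to-paralysis interaction [linear_block()].
#' @param pk optional pharmacokinetic [linear_block()] cascaded ahead of
#'   `g11` on the atracurium path (e.g. [atracurium_pk_block()]); `NULL`
#'   (default) uses the pharmacodynamic block alone, whose time constants
#'   already span the kinetic ones. When enabled, the cascade is held at
#'   its nominal parameters under parametric noise.
#' @param baseline_bp awake mean arterial pressure, mmHg.
#' @param dt simulation step, minutes (0.01 = 100 steps per minute).
#' @param u1_scale scale factor from normalized infusion units to the
#'   concentration units of the Hill curve (ug/mL per unit).
#' @param interaction where the isoflurane-paralysis interaction enters.
#' @return an object of class `"plant_parameters"`.
#' @export
plant_parameters <- function(g11 = linear_block(1, poles = c(4.81, 34.42, 3.08),
                                                zeros = 10.64, dead_time = 1),
                             hill = hill_params(),
                             g22 = linear_block(-15, poles = 2, dead_time = 0.42),
                             g12 = linear_block(0.27, poles = c(2.83, 1.25),
                                                dead_time = 1),
                             pk = NULL,
                             baseline_bp = 120,
                             dt = 0.01,
                             u1_scale = 1,
                             interaction = c("pre_hill", "post_hill")) {
  interaction <- match.arg(interaction)
  stopifnot(inherits(g11, "linear_block"), inherits(g22, "linear_block"),
            inherits(g12, "linear_block"), inherits(hill, "hill_params"))
  if (!is.null(pk)) stopifnot(inherits(pk, "linear_block"))
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (baseline_bp <= 0) stop("baseline_bp must be > 0", call. = FALSE)
  structure(list(g11 = g11, hill = hill, g22 = g22, g12 = g12, pk = pk,
                 baseline_bp = baseline_bp, dt = dt, u1_scale = u1_scale,
                 interaction = interaction),
            class = "plant_parameters")
}

#' Stand-alone atracurium pharmacokinetic block
#'
#' The kinetic transfer function of atracurium (gain 9.94, the same three
#' time constants as the pharmacodynamic path). Not cascaded by default --
#' the pharmacodynamic block already carries these poles -- but available
#' through the `pk` argument of [plant_parameters()] for experiments that
#' want the kinetic stage modeled separately.
#'
#' @return a [linear_block()].
#' @export
atracurium_pk_block <- function() {
  linear_block(9.94, poles = c(10.64, 3.08, 34.42))
}

#' Noise configuration for the nonfixed patient model
#'
#' `param_fraction` is the relative standard deviation of the white
#' multiplicative noise applied independently to every model parameter at
#' every sampling instant (the "nonfixed" model; 1% default).
#' `meas_fraction` scales the additive white measurement noise as a
#' fraction of a per-channel reference SD; the protocol uses 10% and 20%.
#'
#' @param param_fraction parametric noise fraction (>= 0).
#' @param meas_fraction measurement noise fraction (>= 0).
#' @param reference_sd named vector `c(mr = , bp = )` of reference signal
#'   SDs: normalized paralysis units and mmHg respectively.
#' @param seed optional RNG seed stored for bookkeeping.
#' @return an object of class `"noise_config"`.
#' @export
noise_config <- function(param_fraction = 0.01, meas_fraction = 0,
                         reference_sd = c(mr = 0.1, bp = 10), seed = NULL) {
  if (param_fraction < 0 || meas_fraction < 0)
    stop("noise fractions must be >= 0", call. = FALSE)
  if (!all(c("mr", "bp") %in% names(reference_sd)) ||
      any(reference_sd[c("mr", "bp")] <= 0))
    stop("reference_sd must have positive 'mr' and 'bp' entries",
         call. = FALSE)
  structure(list(param_fraction = param_fraction,
                 meas_fraction = meas_fraction,
                 reference_sd = reference_sd, seed = seed),
            class = "noise_config")
}

# ---- flat parameter vector used for per-step perturbation -------------------

# order matters: it fixes the RNG draw sequence of a run
plant_theta <- function(params) {
  c(g11_K = params$g11$gain, g11_T = params$g11$poles,
    g11_z = params$g11$zeros, g11_tau = params$g11$dead_time,
    g12_K = params$g12$gain, g12_T = params$g12$poles,
    g12_tau = params$g12$dead_time,
    g22_K = params$g22$gain, g22_T = params$g22$poles,
    g22_tau = params$g22$dead_time,
    hill_emax = params$hill$emax, hill_xe50 = params$hill$xe50,
    hill_alpha = params$hill$alpha)
}

#' Perturb all model parameters with multiplicative white noise
#'
#' Every numeric parameter `p` of the plant (block gains, time constants,
#' dead times, Hill parameters) is replaced by `p * max(eps, 1 + fraction * z)`
#' with `z` a standard Gaussian draw; the multiplier is clamped positive so
#' signs and stability are preserved. In the nonfixed model this is
#' redrawn independently at every sampling instant.
#'
#' @param nominal a [plant_parameters()] object.
#' @param fraction relative noise SD (>= 0); 0 returns `nominal` unchanged.
#' @return a perturbed `"plant_parameters"` object.
#' @export
perturb_parameters <- function(nominal, fraction) {
  stopifnot(inherits(nominal, "plant_parameters"), fraction >= 0)
  if (fraction == 0) return(nominal)
  th <- plant_theta(nominal)
  th <- th * pmax(.Machine$double.eps, 1 + fraction * stats::rnorm(length(th)))
  theta_to_params(th, nominal)
}

theta_to_params <- function(th, nominal) {
  n11 <- length(nominal$g11$poles)
  n12 <- length(nominal$g12$poles)
  i <- 1L
  take <- function(n) { v <- th[seq(i, i + n - 1L)]; i <<- i + n; v }
  g11 <- linear_block(take(1), poles = take(n11),
                      zeros = take(length(nominal$g11$zeros)),
                      dead_time = take(1))
  g12 <- linear_block(take(1), poles = take(n12), dead_time = take(1))
  g22 <- linear_block(take(1), poles = take(1), dead_time = take(1))
  hl <- hill_params(take(1), take(1), take(1))
  plant_parameters(g11 = g11, hill = hl, g22 = g22, g12 = g12,
                   pk = nominal$pk, baseline_bp = nominal$baseline_bp,
                   dt = nominal$dt, u1_scale = nominal$u1_scale,
                   interaction = nominal$interaction)
}

#' Additive measurement noise
#'
#' Adds zero-mean Gaussian noise of SD `meas_fraction * reference_sd[channel]`
#' to a clean signal value, emulating monitor noise on the paralysis (EMG)
#' and MAP channels.
#'
#' @param clean clean signal value(s).
#' @param channel `"mr"` or `"bp"`.
#' @param noise a [noise_config()].
#' @return noisy measurement(s), same length as `clean`.
#' @export
add_measurement_noise <- function(clean, channel = c("mr", "bp"),
                                  noise = noise_config()) {
  channel <- match.arg(channel)
  stopifnot(inherits(noise, "noise_config"))
  clean + noise$meas_fraction * noise$reference_sd[[channel]] *
    stats::rnorm(length(clean))
}

# ---- incremental plant state ------------------------------------------------

# ZOH mode coefficients for one block; small n, called every step of the
# nonfixed model, so kept free of object construction.
mode_ab <- function(K, Tp, Tz, dt) {
  n <- length(Tp)
  p <- 1 / Tp
  r <- numeric(n)
  for (i in seq_len(n)) {
    num <- K
    if (length(Tz)) num <- num * prod(1 - Tz * p[i])
    r[i] <- num / (Tp[i] * prod(1 - Tp[-i] * p[i]))
  }
  a <- exp(-p * dt)
  list(a = a, b = (r / p) * (1 - a))
}

#' Initialize an incremental plant state
#'
#' Creates the mutable state (modal filter memory plus dead-time ring
#' buffers) for stepping the patient model one `dt` at a time with
#' [step_plant()]. The plant starts at rest: zero paralysis, MAP at
#' baseline.
#'
#' @param params a [plant_parameters()] object.
#' @return an environment of class `"plant_state"`.
#' @export
plant_state <- function(params) {
  stopifnot(inherits(params, "plant_parameters"))
  if (!is.null(params$pk))
    stopifnot(length(params$pk$zeros) == 0L)
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$theta <- plant_theta(params)
  st$dt <- params$dt
  st$n11 <- length(params$g11$poles)
  st$n12 <- length(params$g12$poles)
  st$x11 <- numeric(st$n11)
  st$x12 <- numeric(st$n12)
  st$x22 <- 0
  st$xpk <- if (is.null(params$pk)) NULL else numeric(length(params$pk$poles))
  buflen <- function(tau) max(2L, as.integer(round(2 * tau / params$dt)) + 2L)
  st$buf11 <- numeric(buflen(params$g11$dead_time))
  st$buf12 <- numeric(buflen(params$g12$dead_time))
  st$buf22 <- numeric(buflen(params$g22$dead_time))
  st$k <- 0L
  class(st) <- c("plant_state", class(st))
  st
}

buf_push_read <- function(buf, k, value, delay_steps) {
  n <- length(buf)
  buf[(k - 1L) %% n + 1L] <- value
  D <- min(delay_steps, n - 1L)
  out <- if (k - D < 1L) 0 else buf[(k - D - 1L) %% n + 1L]
  list(buf = buf, out = out)
}

#' Step the patient model by one sampling interval
#'
#' Advances the multivariable plant one `dt` with atracurium input `u1`
#' (normalized infusion units) and isoflurane input `u2` (percent), both
#' held over the interval. With `param_fraction > 0` every model
#' parameter is independently perturbed for this step (nonfixed model),
#' consuming one Gaussian draw per parameter from the global RNG.
#'
#' @param state a [plant_state()] environment (modified in place).
#' @param u1 atracurium infusion, normalized units (>= 0).
#' @param u2 isoflurane concentration, percent (>= 0).
#' @param param_fraction parametric white-noise fraction for this step.
#' @return named vector `c(paralysis = , map = )`: paralysis normalized to
#'   the unit interval and MAP in mmHg.
#' @export
step_plant <- function(state, u1, u2, param_fraction = 0) {
  stopifnot(inherits(state, "plant_state"))
  if (u1 < 0 || u2 < 0) stop("drug inputs must be >= 0", call. = FALSE)
  th <- state$theta
  if (param_fraction > 0)
    th <- th * pmax(.Machine$double.eps,
                    1 + param_fraction * stats::rnorm(length(th)))
  p <- state$params
  dt <- state$dt
  n11 <- state$n11; n12 <- state$n12
  nz11 <- length(p$g11$zeros)
  # layout of th: see plant_theta()
  K11 <- th[[1L]]; T11 <- th[1L + seq_len(n11)]
  z11 <- if (nz11) th[1L + n11 + seq_len(nz11)] else numeric(0)
  tau1 <- th[[n11 + nz11 + 2L]]
  o <- n11 + nz11 + 2L
  K12 <- th[[o + 1L]]; T12 <- th[o + 1L + seq_len(n12)]; tau4 <- th[[o + n12 + 2L]]
  o <- o + n12 + 2L
  K22 <- th[[o + 1L]]; T22 <- th[[o + 2L]]; tau2 <- th[[o + 3L]]
  o <- o + 3L
  emax <- th[[o + 1L]]; xe50 <- th[[o + 2L]]; alpha <- th[[o + 3L]]

  k <- state$k + 1L
  state$k <- k

  # atracurium path input (optionally through the PK cascade)
  uin1 <- u1 * p$u1_scale
  if (!is.null(state$xpk)) {
    mpk <- mode_ab(p$pk$gain, p$pk$poles, numeric(0), dt)
    state$xpk <- mpk$a * state$xpk + mpk$b * uin1
    uin1 <- sum(state$xpk)
  }

  m11 <- mode_ab(K11, T11, z11, dt)
  state$x11 <- m11$a * state$x11 + m11$b * uin1
  pr11 <- buf_push_read(state$buf11, k, sum(state$x11),
                        as.integer(round(tau1 / dt)))
  state$buf11 <- pr11$buf

  m12 <- mode_ab(K12, T12, numeric(0), dt)
  state$x12 <- m12$a * state$x12 + m12$b * u2
  pr12 <- buf_push_read(state$buf12, k, sum(state$x12),
                        as.integer(round(tau4 / dt)))
  state$buf12 <- pr12$buf

  m22 <- mode_ab(K22, T22, numeric(0), dt)
  state$x22 <- m22$a * state$x22 + m22$b * u2
  pr22 <- buf_push_read(state$buf22, k, state$x22,
                        as.integer(round(tau2 / dt)))
  state$buf22 <- pr22$buf

  if (p$interaction == "pre_hill") {
    conc <- max(0, pr11$out + pr12$out)
    eff <- emax * conc^alpha / (conc^alpha + xe50^alpha)
    paralysis <- eff / 100
  } else {
    conc <- max(0, pr11$out)
    eff <- emax * conc^alpha / (conc^alpha + xe50^alpha)
    paralysis <- eff / 100 + pr12$out
  }
  paralysis <- min(1, max(0, paralysis))
  c(paralysis = paralysis, map = p$baseline_bp + pr22$out)
}

#' Noise-free open-loop response of the patient model
#'
#' Drives the plant with prescribed input trajectories at `dt` resolution
#' with all noise disabled, using the exact zero-order-hold recursions.
#' Useful for model verification (steady-state gains, dead times) and as
#' the reference trajectory for the closed-loop protocol.
#'
#' @param u1 atracurium input: a single value (held) or a vector with one
#'   value per step.
#' @param u2 isoflurane input, same convention.
#' @param params a [plant_parameters()] object.
#' @param horizon simulation length, minutes.
#' @return a data frame with columns `time_min`, `u1`, `u2`, `paralysis`,
#'   `map`.
#' @examples
#' r <- open_loop_response(0, 2, horizon = 60)
#' tail(r$map, 1)  # 2% isoflurane lowers MAP by 30 mmHg: 120 -> 90
#' @export
open_loop_response <- function(u1, u2, params = plant_parameters(), horizon) {
  stopifnot(inherits(params, "plant_parameters"), horizon > 0)
  n <- as.integer(round(horizon / params$dt))
  u1 <- rep_len(as.numeric(u1), n)
  u2 <- rep_len(as.numeric(u2), n)
  if (any(u1 < 0) || any(u2 < 0))
    stop("drug inputs must be >= 0", call. = FALSE)
  dt <- params$dt
  uin1 <- u1 * params$u1_scale
  if (!is.null(params$pk))
    uin1 <- block_response(discretize(params$pk, dt), uin1)
  lin11 <- block_response(discretize(params$g11, dt), uin1)
  lin12 <- block_response(discretize(params$g12, dt), u2)
  lin22 <- block_response(discretize(params$g22, dt), u2)
  if (params$interaction == "pre_hill") {
    paralysis <- hill_effect(pmax(0, lin11 + lin12), params$hill) / 100
  } else {
    paralysis <- hill_effect(pmax(0, lin11), params$hill) / 100 + lin12
  }
  data.frame(time_min = seq_len(n) * dt, u1 = u1, u2 = u2,
             paralysis = pmin(1, pmax(0, paralysis)),
             map = params$baseline_bp + lin22)
}
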