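#' Configuration of the two-stage surgical simulation protocol
#'
#' The protocol runs for 300 minutes at a 0.01-minute step (30,000
#' intervals; 100 intervals per minute), in two stages with a set-point
#' switch midway: muscle relaxation targets 0.8 then 0.9 (normalized) and
#' MAP targets 100 then 90 mmHg. An atracurium bolus of 5 normalized
#' units is infused for the first 5 minutes; paralysis then settles until
#' minute 15 with both drugs off, MAP staying at the 120 mmHg baseline;
#' the controller is switched on at minute 15. Measurement noise of 10%
#' or 20% of the per-channel reference SD is added to the monitored
#' signals and 1% parametric white noise makes the patient model
#' nonfixed.
#'
#' @param duration total length, minutes.
#' @param stage_switch time of the stage-1 to stage-2 set-point switch.
#' @param mr_setpoints,bp_setpoints length-2 vectors of per-stage set
#'   points. (The muscle-relaxation set points are also meaningful in the
#'   reversed order 0.9/0.8; pass `mr_setpoints = c(0.9, 0.8)` for that
#'   variant.)
#' @param bolus_amplitude,bolus_duration,settle_until bolus protocol,
#'   normalized units and minutes.
#' @param controller controller kind, see [soflc_controller()].
#' @param rulebases `"expert"`, `"extracted"`, or a list of two
#'   [rulebase()] objects.
#' @param noise a [noise_config()].
#' @param gains a [control_gains()].
#' @param fou_width,fou_style,n_zslices,ctrl_period controller geometry
#'   and timing, see [soflc_controller()].
#' @param plant a [plant_parameters()] (its `dt` is the simulation step).
#' @param seed RNG seed for the run.
#' @param self_organize enable online rule modification.
#' @return an object of class `"simulation_config"`.
#' @export
simulation_config <- function(duration = 300, stage_switch = 150,
                              mr_setpoints = c(0.8, 0.9),
                              bp_setpoints = c(100, 90),
                              bolus_amplitude = 5, bolus_duration = 5,
                              settle_until = 15,
                              controller = "type1",
                              rulebases = "expert",
                              noise = noise_config(param_fraction = 0.01,
                                                   meas_fraction = 0.1),
                              gains = control_gains(),
                              fou_width = 0.1, fou_style = "inner",
                              n_zslices = 5L,
                              ctrl_period = 1,
                              plant = plant_parameters(),
                              seed = 1L,
                              self_organize = TRUE) {
  stopifnot(duration > 0, stage_switch > 0, stage_switch < duration,
            bolus_duration >= 0, settle_until >= bolus_duration,
            inherits(noise, "noise_config"),
            inherits(gains, "control_gains"),
            inherits(plant, "plant_parameters"),
            length(mr_setpoints) == 2L, length(bp_setpoints) == 2L)
  structure(list(duration = duration, stage_switch = stage_switch,
                 mr_setpoints = mr_setpoints, bp_setpoints = bp_setpoints,
                 bolus_amplitude = bolus_amplitude,
                 bolus_duration = bolus_duration,
                 settle_until = settle_until,
                 controller = controller, rulebases = rulebases,
                 noise = noise, gains = gains, fou_width = fou_width,
                 fou_style = fou_style,
                 n_zslices = n_zslices, ctrl_period = ctrl_period,
                 plant = plant, seed = seed,
                 self_organize = self_organize),
            class = "simulation_config")
}

#' Run the closed-loop surgical simulation
#'
#' Executes the two-stage protocol of [simulation_config()]: bolus,
#' settling, then closed-loop control with the configured SOFLC variant.
#' The controller's incremental outputs are integrated into the drug
#' signals, which are clamped nonnegative. All randomness (parametric
#' and measurement noise) flows from `config$seed`, and the number of
#' RNG draws per step is independent of the controller kind, so runs
#' with equal seeds are noise-matched across kinds.
#'
#' @param config a [simulation_config()].
#' @return an object of class `"soflc_run"`: list with `trace` (a data
#'   frame with one row per plant step: `time_min`, `mr_set`, `mr_clean`,
#'   `mr_meas`, `bp_set`, `bp_clean`, `bp_meas`, `u_atracurium`,
#'   `u_isoflurane`, `n_rules_fired`, `n_rules_added`), `controller`
#'   (final state, including self-organized rule-bases and firing
#'   statistics) and `config`.
#' @export
run_closed_loop <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pl <- config$plant
  dt <- pl$dt
  n <- as.integer(round(config$duration / dt))
  ctrl_steps <- max(1L, as.integer(round(config$ctrl_period / dt)))
  ctrl <- soflc_controller(kind = config$controller,
                           rulebases = config$rulebases,
                           gains = config$gains,
                           fou_width = config$fou_width,
                           fou_style = config$fou_style,
                           n_zslices = config$n_zslices,
                           ctrl_period = config$ctrl_period,
                           self_organize = config$self_organize)
  st <- plant_state(pl)
  nz <- config$noise
  sd_mr <- nz$meas_fraction * nz$reference_sd[["mr"]]
  sd_bp <- nz$meas_fraction * nz$reference_sd[["bp"]]

  u1 <- 0; u2 <- 0
  tr_mr_clean <- numeric(n); tr_bp_clean <- numeric(n)
  tr_mr_meas <- numeric(n); tr_bp_meas <- numeric(n)
  tr_u1 <- numeric(n); tr_u2 <- numeric(n)
  tr_mr_set <- numeric(n); tr_bp_set <- numeric(n)
  tr_fired <- integer(n); tr_added <- integer(n)
  meas_mr <- 0; meas_bp <- pl$baseline_bp

  for (k in seq_len(n)) {
    t <- k * dt
    stage <- if (t <= config$stage_switch) 1L else 2L
    set_mr <- config$mr_setpoints[stage]
    set_bp <- config$bp_setpoints[stage]
    if (t <= config$bolus_duration) {
      u1 <- config$bolus_amplitude; u2 <- 0
    } else if (t <= config$settle_until) {
      u1 <- 0; u2 <- 0
    } else if (k %% ctrl_steps == 0L) {
      out <- controller_step(ctrl, meas_mr, meas_bp, set_mr, set_bp, u1, u2)
      u1 <- max(0, u1 + out$du1)
      u2 <- max(0, u2 + out$du2)
      tr_fired[k] <- out$n_fired
      tr_added[k] <- out$n_added
    }
    y <- step_plant(st, u1, u2, nz$param_fraction)
    zm <- stats::rnorm(2)
    meas_mr <- y[[1L]] + sd_mr * zm[1L]
    meas_bp <- y[[2L]] + sd_bp * zm[2L]
    tr_mr_clean[k] <- y[[1L]]; tr_bp_clean[k] <- y[[2L]]
    tr_mr_meas[k] <- meas_mr; tr_bp_meas[k] <- meas_bp
    tr_u1[k] <- u1; tr_u2[k] <- u2
    tr_mr_set[k] <- set_mr; tr_bp_set[k] <- set_bp
  }
  trace <- data.frame(time_min = seq_len(n) * dt,
                      mr_set = tr_mr_set, mr_clean = tr_mr_clean,
                      mr_meas = tr_mr_meas,
                      bp_set = tr_bp_set, bp_clean = tr_bp_clean,
                      bp_meas = tr_bp_meas,
                      u_atracurium = tr_u1, u_isoflurane = tr_u2,
                      n_rules_fired = tr_fired, n_rules_added = tr_added)
  structure(list(trace = trace, controller = ctrl, config = config),
            class = "soflc_run")
}

#' @export
print.soflc_run <- function(x, ...) {
  cat(sprintf("<soflc_run> %s / %s rules, %.0f min, noise %g/%g\n",
              x$config$controller,
              if (is.character(x$config$rulebases)) x$config$rulebases
              else "custom",
              x$config$duration, x$config$noise$param_fraction,
              x$config$noise$meas_fraction))
  invisible(x)
}

stage_window <- function(config, stage, window) {
  end <- if (stage == 1L) config$stage_switch else config$duration
  start <- end - window
  lo <- if (stage == 1L) 0 else config$stage_switch
  if (start < lo)
    stop("averaging window (", window, " min) exceeds the stage length",
         call. = FALSE)
  c(start, end)
}

#' Steady-state error of a closed-loop run
#'
#' Computed per stage over the final `window` minutes of the stage. The
#' default `method = "bias"` is the absolute difference between the
#' time-averaged signal and the set point (the time average suppresses
#' the zero-mean measurement noise); `method = "mae"` is the mean
#' absolute per-sample deviation.
#'
#' @param run a `"soflc_run"` from [run_closed_loop()].
#' @param stage 1 or 2.
#' @param channel `"mr"` or `"bp"`.
#' @param window averaging window, minutes (must fit inside the stage).
#' @param method `"bias"` or `"mae"`.
#' @param signal evaluate the clean (actual) or measured signal.
#' @return nonnegative error in the channel's units.
#' @export
steady_state_error <- function(run, stage = 1L, channel = c("mr", "bp"),
                               window = 50, method = c("bias", "mae"),
                               signal = c("clean", "measured")) {
  channel <- match.arg(channel)
  method <- match.arg(method)
  signal <- match.arg(signal)
  stopifnot(inherits(run, "soflc_run"), stage %in% c(1L, 2L))
  w <- stage_window(run$config, stage, window)
  tr <- run$trace
  sel <- tr$time_min > w[1] & tr$time_min <= w[2]
  col <- paste0(channel, "_", if (signal == "clean") "clean" else "meas")
  y <- tr[[col]][sel]
  sp <- tr[[paste0(channel, "_set")]][sel]
  if (method == "bias") abs(mean(y - sp)) else mean(abs(y - sp))
}

#' Control stability of a drug signal
#'
#' The population standard deviation of the control signal over the
#' controlled steady portion of the run: by default from the start of the
#' stage-1 steady-state window (`stage_switch - 50` minutes) to the end,
#' so the statistic measures dosing smoothness rather than the initial
#' bolus and dosing ramp, whose excursions are orders of magnitude larger
#' than the jitter of interest. Lower values mean smoother dosing.
#'
#' @param run a `"soflc_run"`.
#' @param channel `"atracurium"` or `"isoflurane"`.
#' @param from start of the evaluation window, minutes (`0` = the entire
#'   simulation).
#' @return nonnegative SD in the drug's units.
#' @export
control_stability <- function(run,
                              channel = c("atracurium", "isoflurane"),
                              from = NULL) {
  channel <- match.arg(channel)
  stopifnot(inherits(run, "soflc_run"))
  if (is.null(from))
    from <- max(run$config$settle_until, run$config$stage_switch - 50)
  u <- run$trace[[paste0("u_", channel)]][run$trace$time_min > from]
  if (!length(u)) stop("empty evaluation window", call. = FALSE)
  sqrt(mean((u - mean(u))^2))
}

#' All six performance metrics of a run
#'
#' @param run a `"soflc_run"`.
#' @param window steady-state window, minutes.
#' @return named vector: per-stage steady-state errors for MR and BP and
#'   whole-run control stabilities for both drugs.
#' @export
run_metrics <- function(run, window = 50) {
  c(sse_mr_s1 = steady_state_error(run, 1L, "mr", window),
    sse_bp_s1 = steady_state_error(run, 1L, "bp", window),
    sse_mr_s2 = steady_state_error(run, 2L, "mr", window),
    sse_bp_s2 = steady_state_error(run, 2L, "bp", window),
    stab_atr = control_stability(run, "atracurium"),
    stab_iso = control_stability(run, "isoflurane"))
}

#' Nonparametric comparison of metric samples
#'
#' Given per-variant matrices of repeated-run metrics (rows = matched
#' repetitions, columns = metrics), runs a Kruskal-Wallis test per metric
#' across all variants and, for each ordered hypothesis
#' `c(better, worse)`, a one-tailed paired Wilcoxon signed-rank test of
#' "the better variant's metric is smaller" (all metrics are
#' smaller-is-better). Degenerate cases (identical samples) report
#' p = 1.
#'
#' @param metrics named list of numeric matrices with identical dimnames.
#' @param hypotheses list of length-2 character vectors
#'   `c(better, worse)` naming entries of `metrics`.
#' @param alpha significance level.
#' @return list with data frames `kruskal` (metric, statistic, p_value,
#'   significant) and `wilcoxon` (better, worse, metric, p_value,
#'   accept).
#' @export
compare_metrics <- function(metrics, hypotheses = list(), alpha = 0.05) {
  stopifnot(is.list(metrics), length(metrics) >= 2L,
            !is.null(names(metrics)))
  mnames <- colnames(metrics[[1L]])
  reps <- nrow(metrics[[1L]])
  for (m in metrics) stopifnot(identical(dim(m), dim(metrics[[1L]])))
  kr <- do.call(rbind, lapply(mnames, function(mt) {
    vals <- unlist(lapply(metrics, function(m) m[, mt]))
    grp <- factor(rep(names(metrics), each = reps))
    if (stats::var(vals) == 0) {
      data.frame(metric = mt, statistic = 0, p_value = 1)
    } else {
      k <- stats::kruskal.test(vals, grp)
      data.frame(metric = mt, statistic = unname(k$statistic),
                 p_value = k$p.value)
    }
  }))
  kr$significant <- kr$p_value < alpha
  wx <- NULL
  for (h in hypotheses) {
    for (mt in mnames) {
      x <- metrics[[h[1]]][, mt]
      y <- metrics[[h[2]]][, mt]
      p <- if (all(x == y)) 1 else
        suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            alternative = "less")$p.value)
      wx <- rbind(wx, data.frame(better = h[1], worse = h[2], metric = mt,
                                 p_value = p, accept = p < alpha))
    }
  }
  list(kruskal = kr, wilcoxon = wx)
}

#' Repeated matched-seed runs and statistical comparison
#'
#' Runs every configuration in `variants` `reps` times; repetition `r`
#' of every variant uses seed `seed + r`, so the noise realizations are
#' matched across variants and the paired Wilcoxon comparisons are
#' legitimate. Aggregates [run_metrics()] and calls [compare_metrics()].
#'
#' @param variants named list of [simulation_config()] objects (their
#'   `seed` fields are overridden per repetition).
#' @param reps repetitions per variant (>= 2).
#' @param seed base seed.
#' @param hypotheses see [compare_metrics()]; defaults to the ordered
#'   controller-capability hypotheses when the variant names contain
#'   `type1`, `interval_t2` and `zslice_t2`.
#' @param alpha significance level.
#' @return list with `metrics` (named list of reps x 6 matrices),
#'   `kruskal`, `wilcoxon`.
#' @export
repeat_and_compare <- function(variants, reps = 10L, seed = 1L,
                               hypotheses = NULL, alpha = 0.05) {
  stopifnot(is.list(variants), length(variants) >= 2L,
            !is.null(names(variants)), reps >= 2L)
  metrics <- lapply(variants, function(cfg) {
    m <- t(vapply(seq_len(reps), function(r) {
      cfg$seed <- seed + r
      run_metrics(run_closed_loop(cfg))
    }, numeric(6)))
    m
  })
  if (is.null(hypotheses)) {
    v <- names(variants)
    hypotheses <- list()
    if (all(c("interval_t2", "type1") %in% v))
      hypotheses <- c(hypotheses, list(c("interval_t2", "type1")))
    if (all(c("zslice_t2", "type1") %in% v))
      hypotheses <- c(hypotheses, list(c("zslice_t2", "type1")))
    if (all(c("zslice_t2", "interval_t2") %in% v))
      hypotheses <- c(hypotheses, list(c("zslice_t2", "interval_t2")))
  }
  c(list(metrics = metrics),
    compare_metrics(metrics, hypotheses, alpha))
}
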