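fake_run <- function(mr_clean, bp_clean = NULL, u_atr = NULL, u_iso = NULL,
                     duration = 300, dt = 0.01) {
  n <- as.integer(duration / dt)
  cfg <- simulation_config(duration = duration, stage_switch = duration / 2)
  t <- seq_len(n) * dt
  stage <- ifelse(t <= cfg$stage_switch, 1L, 2L)
  tr <- data.frame(time_min = t,
                   mr_set = cfg$mr_setpoints[stage],
                   bp_set = cfg$bp_setpoints[stage])
  tr$mr_clean <- rep_len(mr_clean, n)
  tr$mr_meas <- tr$mr_clean
  tr$bp_clean <- if (is.null(bp_clean)) tr$bp_set else rep_len(bp_clean, n)
  tr$bp_meas <- tr$bp_clean
  tr$u_atracurium <- rep_len(if (is.null(u_atr)) 0 else u_atr, n)
  tr$u_isoflurane <- rep_len(if (is.null(u_iso)) 0 else u_iso, n)
  structure(list(trace = tr, config = cfg), class = "soflc_run")
}

test_that("steady-state error recovers offsets, sinusoids and zeros", {
  cfg <- simulation_config()
  on_target <- fake_run(mr_clean = NA)
  on_target$trace$mr_clean <- on_target$trace$mr_set
  expect_equal(steady_state_error(on_target, 1, "mr"), 0)
  expect_equal(steady_state_error(on_target, 2, "bp"), 0)

  off <- fake_run(mr_clean = NA)
  off$trace$mr_clean <- off$trace$mr_set + 0.05
  expect_equal(steady_state_error(off, 1, "mr"), 0.05)
  expect_equal(steady_state_error(off, 1, "mr", method = "mae"), 0.05)

  # sinusoid around the set point: per-sample MAE is 2a/pi, bias ~ 0
  sin_run <- fake_run(mr_clean = NA)
  a <- 0.04
  per <- 0.5  # minutes; whole number of periods fits in the 50-min window
  sin_run$trace$mr_clean <- sin_run$trace$mr_set +
    a * sin(2 * pi * sin_run$trace$time_min / per)
  expect_equal(steady_state_error(sin_run, 1, "mr", method = "mae"),
               2 * a / pi, tolerance = 0.01)
  expect_lt(steady_state_error(sin_run, 1, "mr", method = "bias"), 1e-4)

  expect_error(steady_state_error(on_target, 1, "mr", window = 200),
               "window")
})

test_that("control stability is the population SD of the drug signal", {
  const <- fake_run(0.8, u_iso = 1.5)
  expect_equal(control_stability(const, "isoflurane"), 0)
  alt <- fake_run(0.8, u_atr = c(0.5 - 0.2, 0.5 + 0.2))
  expect_equal(control_stability(alt, "atracurium"), 0.2, tolerance = 1e-6)
  set.seed(5)
  wn <- fake_run(0.8, u_iso = rnorm(30000, 1, 0.3))
  expect_equal(control_stability(wn, "isoflurane"), 0.3, tolerance = 0.03)
})

test_that("the protocol applies bolus, settling and a constant early MAP", {
  run <- run_closed_loop(short_cfg(seed = 3))
  tr <- run$trace
  expect_true(all(tr$u_atracurium[tr$time_min <= 5] == 5))
  expect_true(all(tr$u_atracurium[tr$time_min > 5 & tr$time_min <= 15] == 0))
  expect_true(all(tr$u_isoflurane[tr$time_min <= 15] == 0))
  expect_true(all(tr$bp_clean[tr$time_min <= 15] == 120))
  expect_true(all(tr$u_atracurium >= 0))
  expect_true(all(tr$u_isoflurane >= 0))
  expect_true(all(tr$mr_clean >= 0 & tr$mr_clean <= 1))
  # bolus saturates the neuromuscular block
  expect_gt(max(tr$mr_clean[tr$time_min <= 10]), 0.9)
  # set points switch at the configured stage boundary
  expect_equal(unique(tr$bp_set[tr$time_min <= 30]), 100)
  expect_equal(unique(tr$bp_set[tr$time_min > 30]), 90)
})

test_that("runs are deterministic given a seed", {
  r1 <- run_closed_loop(short_cfg(seed = 9))
  r2 <- run_closed_loop(short_cfg(seed = 9))
  expect_identical(r1$trace, r2$trace)
  r3 <- run_closed_loop(short_cfg(seed = 10))
  expect_false(identical(r1$trace, r3$trace))
})

test_that("noise-free closed loop converges to both set points", {
  cfg <- simulation_config(controller = "type1", seed = 1,
                           noise = noise_config(0, 0))
  run <- run_closed_loop(cfg)
  expect_lt(steady_state_error(run, 1, "mr"), 0.05)
  expect_lt(steady_state_error(run, 2, "mr"), 0.05)
  expect_lt(steady_state_error(run, 1, "bp"), 2)
  expect_lt(steady_state_error(run, 2, "bp"), 2)
  # the self-organizing layer was active
  expect_gt(length(run$controller$change_log), 0)
})

test_that("paired comparisons behave on degenerate and dominated samples", {
  m1 <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  same <- list(x = m1, y = m1)
  cmp <- compare_metrics(same, hypotheses = list(c("x", "y")))
  expect_true(all(cmp$wilcoxon$p_value > 0.05))
  expect_true(all(cmp$kruskal$p_value > 0.05))
  dom <- list(x = m1, y = m1 + matrix(seq(0.5, 2.4, by = 0.1), 10, 2))
  cmp2 <- compare_metrics(dom, hypotheses = list(c("x", "y")))
  expect_true(all(cmp2$wilcoxon$p_value < 0.05))
  expect_true(all(cmp2$wilcoxon$accept))
  # exact one-sided signed-rank null for n = 10, all differences negative
  expect_equal(cmp2$wilcoxon$p_value[1], 1 / 2^10, tolerance = 1e-6)
  three <- list(a = m1, b = m1, c = m1)
  expect_true(all(compare_metrics(three)$kruskal$p_value > 0.05))
})

test_that("the command-line interface writes its artifacts", {
  out <- tempfile()
  code <- soflc_cli(c("simulate", "--controller", "type1",
                      "--duration", "40", "--stage-switch", "20",
                      "--noise", "0.1", "--seed", "4", "--out", out))
  expect_identical(code, 0L)
  expect_true(file.exists(file.path(out, "trace.csv")))
  expect_true(file.exists(file.path(out, "metrics.json")))
  expect_true(file.exists(file.path(out, "firing_stats.csv")))
  met <- jsonlite::fromJSON(file.path(out, "metrics.json"))
  expect_true(all(c("sse_mr_s1", "stab_iso") %in% names(met)))
  out2 <- tempfile()
  code2 <- soflc_cli(c("open-loop", "--u2", "2", "--horizon", "30",
                       "--out", out2))
  expect_identical(code2, 0L)
  ol <- utils::read.csv(file.path(out2, "open_loop.csv"))
  expect_equal(tail(ol$map, 1), 90, tolerance = 0.5)
  expect_identical(soflc_cli(c("badcmd")), 2L)
  expect_identical(soflc_cli(c("simulate", "--nope", "1")), 2L)
})
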