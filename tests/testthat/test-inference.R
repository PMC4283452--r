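out4 <- function(fou = 0, nz = 1)
  build_partition("increment", c(0, 1), output_labels(),
                  fou_width = fou, n_zslices = nz)

test_that("firing intervals apply the min t-norm per bound", {
  expect_equal(firing_interval(c(0.2, 0.4), c(0.3, 0.9)),
               c(lower = 0.2, upper = 0.4))
  expect_equal(firing_interval(c(0, 0), c(0.5, 0.8)),
               c(lower = 0, upper = 0))
  expect_identical(firing_interval(0.7, 0.4), 0.4)  # crisp type-1 case
  m <- rbind(c(0.1, 0.5), c(0.2, 0.3))
  f <- firing_interval(m, rbind(c(0.4, 0.4), c(0.1, 0.6)))
  expect_equal(unname(f), rbind(c(0.1, 0.4), c(0.1, 0.3)))
})

test_that("aggregation equals the consequent at full firing, max across rules", {
  op <- out4()
  a1 <- infer(2L, list(c(1, 1)), op)
  mu <- pmax(0, 1 - abs(a1$grid - op$peaks[2]) / op$half)
  expect_equal(a1$upper[1, ], mu)
  # a duplicate weaker consequent never changes the aggregate
  a2 <- infer(c(2L, 2L), list(c(1, 1), c(0.4, 0.4)), op)
  expect_equal(a2$upper, a1$upper)
  expect_error(infer(integer(0), list(), op), "no rule")
})

test_that("three-rule aggregation matches the brute-force oracle", {
  for (setup in list(list(fou = 0, nz = 1), list(fou = 0.08, nz = 1),
                     list(fou = 0.08, nz = 5))) {
    op <- out4(setup$fou, setup$nz)
    ns <- setup$nz
    set.seed(31)
    for (rep in 1:5) {
      cons <- sample(1:4, 3, replace = TRUE)
      firing <- lapply(1:3, function(i) {
        lo <- matrix(runif(ns, 0, 0.6), ns)
        cbind(lo, lo + runif(ns, 0, 0.4))
      })
      a <- infer(cons, firing, op)
      b <- brute_aggregate(cons, firing, op)
      expect_equal(a$grid, b$grid)
      expect_equal(a$upper, b$upper)
      expect_equal(a$lower, b$lower)
    }
  }
})

test_that("iterative KM equals exhaustive switch-point search on small grids", {
  set.seed(17)
  for (rep in 1:200) {
    n <- sample(3:15, 1)
    x <- sort(runif(n, -2, 2))
    up <- runif(n)
    lo <- up * runif(n)
    if (all(up <= 0)) next
    got <- km_type_reduce(list(grid = x, upper = up, lower = lo))
    want <- km_exhaustive(x, up, lo)
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
})

test_that("KM collapses to the type-1 centroid on degenerate sets", {
  x <- seq(0, 1, length.out = 101)
  mu <- pmax(0, 1 - abs(x - 0.5) / 0.3)
  r <- km_type_reduce(list(grid = x, upper = mu, lower = mu))
  expect_equal(unname(r[1]), 0.5, tolerance = 1e-9)   # symmetric triangle
  expect_equal(unname(r[2]), 0.5, tolerance = 1e-9)
  mu2 <- pmax(0, 1 - abs(x - 0.3) / 0.25)^2          # asymmetric clipping
  r2 <- km_type_reduce(list(grid = x, upper = mu2, lower = mu2))
  expect_equal(unname(r2[1]), sum(mu2 * x) / sum(mu2), tolerance = 1e-9)
  expect_error(km_type_reduce(list(grid = x, upper = numeric(101),
                                   lower = numeric(101))), "zero")
})

test_that("KM bounds stay inside the grid and widen with the FOU", {
  set.seed(23)
  x <- seq(-1, 1, length.out = 201)
  base <- pmax(0, 1 - abs(x - 0.2) / 0.5)
  widths <- c(0, 0.1, 0.25, 0.4)
  prev <- NULL
  for (w in widths) {
    up <- pmin(1, base + w * (base > 0))
    lo <- pmax(0, base - w)
    r <- km_type_reduce(list(grid = x, upper = up, lower = lo))
    expect_gte(r[["yl"]], min(x)); expect_lte(r[["yr"]], max(x))
    expect_lte(r[["yl"]], r[["yr"]])
    if (!is.null(prev)) {
      expect_lte(r[["yl"]], prev[["yl"]] + 1e-12)
      expect_gte(r[["yr"]], prev[["yr"]] - 1e-12)
    }
    prev <- r
  }
})

test_that("defuzzification takes midpoints and z-weighted slice means", {
  expect_equal(defuzzify(c(0.3, 0.5)), 0.4)
  one <- matrix(c(0.3, 0.5), 1)
  expect_equal(defuzzify(one, z = 1), 0.4)
  eqc <- matrix(rep(c(0.2, 0.6), each = 5), 5)
  expect_equal(defuzzify(eqc, z = seq(0.2, 1, by = 0.2)), 0.4)
  skipna <- rbind(c(0.1, 0.3), c(NA, NA), c(0.5, 0.7))
  expect_equal(defuzzify(skipna, z = c(1, 2, 3)),
               (1 * 0.2 + 3 * 0.6) / 4)
  expect_error(defuzzify(c(NA_real_, NA_real_)), "empty")
})
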