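test_that("triangular membership peaks at 1 and clamps at the universe", {
  part <- build_partition("e", c(-1, 1), input_labels())
  expect_equal(membership(part$sets$ZE, 0), 1)
  expect_equal(membership(part$sets$PS, 1 / 3), 1)
  expect_equal(membership(part$sets$ZE, 1 / 3), 0)
  # outside values clamp to the edge: NB is full at and beyond the edge
  expect_equal(membership(part$sets$NB, -5, universe = part$universe), 1)
})

test_that("zero FOU width degenerates interval sets to type-1", {
  t1 <- build_partition("e", c(-1, 1), input_labels(), fou_width = 0)
  it <- build_partition("e", c(-1, 1), input_labels(), fou_width = 0.1)
  m <- membership(it$sets$ZE, 0.1)
  expect_true(m[["lower"]] <= m[["upper"]])
  expect_type(membership(t1$sets$ZE, 0.1), "double")
  # single-slice zSlice partition is numerically the interval partition
  z1 <- build_partition("e", c(-1, 1), input_labels(), fou_width = 0.1,
                        n_zslices = 1)
  for (x in seq(-1, 1, by = 0.13))
    expect_identical(membership(z1$sets$PS, x), membership(it$sets$PS, x))
})

test_that("zSlice membership intervals are nested across slices", {
  part <- build_partition("e", c(-1, 1), input_labels(), fou_width = 0.1,
                          n_zslices = 5)
  for (x in seq(-1, 1, length.out = 41)) {
    for (lab in input_labels()) {
      m <- membership(part$sets[[lab]], x)
      expect_true(all(diff(m[, "lower"]) >= 0))  # lower rises with z
      expect_true(all(diff(m[, "upper"]) <= 0))  # upper shrinks with z
      expect_true(all(m[, "lower"] <= m[, "upper"] + 1e-12))
    }
  }
})

test_that("oversized FOU widths are rejected", {
  expect_error(build_partition("e", c(-1, 1), input_labels(),
                               fou_width = 0.4), "fou_width")
})

test_that("build_fou_from_stats reflects the signal statistics", {
  s0 <- build_fou_from_stats(0.5, sd = 0, half_width = 1)
  expect_equal(soflc:::set_kind(s0), "type1")
  s1 <- build_fou_from_stats(0.5, sd = 0.1, scale = 1, half_width = 1)
  m <- membership(s1, 0.5 - 1)  # at the nominal left foot
  # upper and lower feet differ by twice the FOU half-width (0.2)
  expect_equal(m[["upper"]], 0.1 / 1.1, tolerance = 1e-12)
  expect_equal(m[["lower"]], 0)
  gs <- data.frame(mean = rep(0.5, 5),
                   sd = c(0.30, 0.22, 0.15, 0.10, 0.05))
  sz <- build_fou_from_stats(0.5, sd = 0.2, half_width = 1,
                             group_stats = gs)
  expect_length(sz$z, 5)
  expect_true(all(diff(sz$w) <= 0))  # widest FOU at the lowest z
  for (x in seq(-0.6, 1.6, length.out = 31)) {
    m <- membership(sz, x)
    expect_true(all(diff(m[, "upper"]) <= 1e-12))
    expect_true(all(diff(m[, "lower"]) >= -1e-12))
  }
  bad <- data.frame(mean = c(0, 3), sd = c(0.5, 0.4))
  expect_error(build_fou_from_stats(0, sd = 0.5, half_width = 1,
                                    group_stats = bad), "nestable")
})

test_that("crisp labelling picks the maximal label, ties toward ZE", {
  part <- build_partition("e", c(-1, 1), input_labels())
  expect_identical(label_inputs(0, part), "ZE")
  expect_identical(label_inputs(1, part), "PB")
  expect_identical(label_inputs(5, part), "PB")    # clamped
  expect_identical(label_inputs(0.5, part), "PS")  # PS/PM midpoint
  expect_identical(label_inputs(-0.5, part), "NS") # NS/NM midpoint
})
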