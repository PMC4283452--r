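mini_rb <- function() {
  rulebase(data.frame(
    in1_var = c("E_MR", "E_MR", "E_BP"),
    in1_label = c("ZE", "PS", "ZE"),
    in2_var = c("IE_MR", "IE_MR", "IE_BP"),
    in2_label = c("ZE", "ZE", "ZE"),
    consequent_label = c("PS", "PB", "ZE")), "atracurium")
}

test_that("a ZE correction leaves the rule-base untouched", {
  rb <- mini_rb()
  fired <- data.frame(pair = c(1, 6), in1_label = c("ZE", "ZE"),
                      in2_label = c("ZE", "ZE"))
  out <- so_update(rb, "ZE", fired)
  expect_identical(as.data.frame(out$rulebase), as.data.frame(rb))
  expect_equal(nrow(out$changes), 0)
})

test_that("corrections shift consequents with saturation at the label range", {
  rb <- mini_rb()
  fired <- data.frame(pair = c(1, 1), in1_label = c("ZE", "PS"),
                      in2_label = c("ZE", "ZE"))
  up <- so_update(rb, "PM", fired[1, ])
  r <- up$rulebase$rules
  expect_identical(r$consequent_label[r$in1_label == "ZE" &
                                        r$in2_var == "IE_MR"], "PB")
  # PB consequent saturates under a further positive correction
  up2 <- so_update(rb, "PB", fired[2, ])
  r2 <- up2$rulebase$rules
  expect_identical(r2$consequent_label[r2$in1_label == "PS"], "PB")
  expect_equal(nrow(up2$changes), 0)
  # negative corrections floor at ZE
  dn <- so_update(rb, "NB", fired[1, ])
  rd <- dn$rulebase$rules
  expect_identical(rd$consequent_label[rd$in1_label == "ZE" &
                                         rd$in2_var == "IE_MR"], "ZE")
})

test_that("unfired subsystems get a freshly generated rule, no duplicates", {
  rb <- mini_rb()
  labs <- c(E_MR = "NS", IE_MR = "ZE", E_BP = "PS", IE_BP = "ZE")
  out <- so_update(rb, "PM", fired = NULL, input_labels_now = labs)
  r <- out$rulebase$rules
  # one new rule per decomposed pair, consequent saturate(ZE + 2) = PM
  expect_equal(nrow(r), 3 + 6)
  expect_true(all(out$changes$new == "PM"))
  sig <- paste(r$in1_var, r$in1_label, r$in2_var, r$in2_label)
  expect_false(anyDuplicated(sig) > 0)
  # regenerating over an existing signature is ignored
  again <- so_update(out$rulebase, "PB", fired = NULL,
                     input_labels_now = labs)
  expect_equal(nrow(again$rulebase$rules), nrow(r))
  expect_equal(nrow(again$changes), 0)
})

test_that("firing percentages are fires over total inference operations", {
  ctrl <- soflc_controller("type1", rulebases = "extracted")
  for (ch in c("atracurium", "isoflurane")) ctrl$totals[[ch]][] <- 100L
  # plant three known counts on extracted atracurium rules
  labs <- input_labels()
  put <- function(p, i1, i2, n)
    ctrl$fires$atracurium[[p]][match(i1, labs), match(i2, labs)] <- n
  put(1, "PM", "ZE", 5L); put(2, "NS", "NS", 3L); put(6, "ZE", "ZE", 2L)
  fp <- firing_percentages(ctrl, "atracurium")
  expect_equal(sort(fp$percent, decreasing = TRUE)[1:3], c(5, 3, 2))
  expect_true(all(fp$percent >= 0 & fp$percent <= 100))
  ctrl$totals$atracurium[] <- 0L
  expect_error(firing_percentages(ctrl, "atracurium"), "no inference")
})

test_that("rule extraction removes exactly the sub-threshold rules", {
  rb <- mini_rb()
  stats <- data.frame(in1_var = c("E_MR", "E_MR", "E_BP"),
                      in1_label = c("ZE", "PS", "ZE"),
                      in2_var = c("IE_MR", "IE_MR", "IE_BP"),
                      in2_label = c("ZE", "ZE", "ZE"),
                      percent = c(1.2, 0.9, 5))
  red <- extract_rules(rb, stats, threshold = 1)
  expect_equal(length(red), 2)
  expect_false("PS" %in% red$rules$in1_label)
  expect_identical(as.data.frame(extract_rules(rb, stats, threshold = 0)),
                   as.data.frame(rb))
  expect_warning(extract_rules(rb, stats, threshold = 99), "inert")
  # a rule absent from the stats counts as never fired
  red2 <- extract_rules(rb, stats[-1, ], threshold = 1)
  expect_equal(length(red2), 1)
})

test_that("one controller step wires inference, stats and learning together", {
  ctrl <- soflc_controller("interval_t2")
  out <- controller_step(ctrl, meas_mr = 0.5, meas_bp = 118,
                         set_mr = 0.8, set_bp = 100, u1 = 0, u2 = 0)
  expect_gt(out$n_fired, 0)
  expect_true(is.finite(out$du1) && is.finite(out$du2))
  # large "need more drug" errors command positive changes from rest
  expect_gt(out$du2, 0)
  expect_true(all(ctrl$totals$atracurium == 1L))
  # tracking output: same command pulls DOWN an excessive drug signal
  ctrl2 <- soflc_controller("interval_t2")
  out2 <- controller_step(ctrl2, 0.5, 118, 0.8, 100, u1 = 50, u2 = 50)
  expect_lt(out2$du1, 0)
  expect_lt(out2$du2, 0)
})
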