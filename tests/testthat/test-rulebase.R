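test_that("the four bundled rule-bases load and round-trip losslessly", {
  for (name in c("expert_atracurium", "expert_isoflurane",
                 "extracted_atracurium", "extracted_isoflurane")) {
    rb <- read_rulebase(rulebase_file(name))
    csv <- tempfile(fileext = ".csv")
    js <- tempfile(fileext = ".json")
    write_rulebase(rb, csv)
    write_rulebase(rb, js)
    expect_identical(as.data.frame(read_rulebase(csv)), as.data.frame(rb))
    expect_identical(as.data.frame(read_rulebase(js)), as.data.frame(rb))
  }
})

test_that("the extracted rule-bases are strictly smaller than the expert ones", {
  exp_rb <- default_rulebases("expert")
  ext_rb <- default_rulebases("extracted")
  expect_lt(length(ext_rb$atracurium), length(exp_rb$atracurium))
  expect_lt(length(ext_rb$isoflurane), length(exp_rb$isoflurane))
})

test_that("unknown labels and malformed files are parse errors", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("output_var,in1_var,in1_label,in2_var,in2_label,consequent_label",
               "atracurium,E_MR,ZE,E_BP,ZE,PS",
               "atracurium,E_MR,XX,E_BP,ZE,PS"), f)
  expect_error(read_rulebase(f), "line\\(s\\) 2")
  writeLines(c("a,b", "1,2"), f)
  expect_error(read_rulebase(f), "columns")
  expect_error(read_rulebase(tempfile()), "no such file")
})

test_that("duplicate antecedent signatures resolve last-wins with a warning", {
  df <- data.frame(in1_var = "E_MR", in1_label = "ZE",
                   in2_var = "E_BP", in2_label = "ZE",
                   consequent_label = c("PS", "PB"))
  expect_warning(rb <- rulebase(df, "atracurium"), "last")
  expect_identical(rb$rules$consequent_label, "PB")
})

test_that("swapped antecedent variable order is canonicalized", {
  df <- data.frame(in1_var = "E_BP", in1_label = "PS",
                   in2_var = "E_MR", in2_label = "NS",
                   consequent_label = "PM")
  rb <- rulebase(df, "isoflurane")
  expect_identical(rb$rules$in1_var, "E_MR")
  expect_identical(rb$rules$in1_label, "NS")
  expect_identical(rb$rules$in2_label, "PS")
  expect_error(rulebase(data.frame(in1_var = "E_MR", in1_label = "ZE",
                                   in2_var = "E_MR", in2_label = "ZE",
                                   consequent_label = "PS"), "x"),
               "unknown input pair")
})

test_that("decomposition yields the six canonical unordered pairs", {
  d <- decompose_inputs()
  expect_equal(nrow(d), 6)
  expect_true(all(d$var1 != d$var2))
  got <- apply(cbind(d$var1, d$var2), 1, function(r) paste(sort(r), collapse = "+"))
  want <- apply(utils::combn(controller_input_vars(), 2), 2,
                function(r) paste(sort(r), collapse = "+"))
  expect_setequal(got, want)
  x <- c(E_MR = 0.1, IE_MR = -0.2, E_BP = 0.3, IE_BP = 0)
  dx <- decompose_inputs(x)
  expect_equal(dx$x1, unname(x[dx$var1]))
  expect_equal(dx$x2, unname(x[dx$var2]))
})

test_that("matrix form round-trips a rule-base", {
  rb <- default_rulebases("extracted")$isoflurane
  mats <- soflc:::rb_to_matrices(rb)
  back <- soflc:::matrices_to_rb(mats, rb$output)
  key <- function(r) paste(r$in1_var, r$in1_label, r$in2_var, r$in2_label,
                           r$consequent_label)
  expect_setequal(key(back$rules), key(rb$rules))
})
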