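#' Controller input variables and their decomposed pairs
#'
#' The controller has four inputs: error of muscle relaxation (`E_MR`),
#' its integral (`IE_MR`), error of blood pressure (`E_BP`) and its
#' integral (`IE_BP`). The 4-input/2-output control problem is decomposed
#' into two-input/one-output subsystems, one per unordered pair of
#' inputs, taken in a fixed canonical order.
#'
#' @return `controller_input_vars()`: the four variable names.
#'   `decompose_inputs()`: a data frame with columns `pair`, `var1`,
#'   `var2` (six rows, canonical order); when `inputs` is supplied, also
#'   columns `x1`, `x2` with the paired values.
#' @param inputs optional named numeric vector with entries `E_MR`,
#'   `IE_MR`, `E_BP`, `IE_BP`.
#' @examples
#' decompose_inputs()
#' @export
controller_input_vars <- function() c("E_MR", "IE_MR", "E_BP", "IE_BP")

#' @rdname controller_input_vars
#' @export
decompose_inputs <- function(inputs = NULL) {
  v <- controller_input_vars()
  pairs <- data.frame(pair = 1:6,
                      var1 = c("E_MR", "E_MR", "E_MR", "IE_MR", "IE_MR", "E_BP"),
                      var2 = c("IE_MR", "E_BP", "IE_BP", "E_BP", "IE_BP", "IE_BP"),
                      stringsAsFactors = FALSE)
  if (!is.null(inputs)) {
    if (!all(v %in% names(inputs)))
      stop("inputs must be named with ", paste(v, collapse = ", "),
           call. = FALSE)
    pairs$x1 <- unname(inputs[pairs$var1])
    pairs$x2 <- unname(inputs[pairs$var2])
  }
  pairs
}

pair_index <- function(var1, var2) {
  p <- decompose_inputs()
  i <- which(p$var1 == var1 & p$var2 == var2)
  if (length(i)) return(list(pair = i, swapped = FALSE))
  i <- which(p$var1 == var2 & p$var2 == var1)
  if (length(i)) return(list(pair = i, swapped = TRUE))
  stop("unknown input pair: (", var1, ", ", var2, ")", call. = FALSE)
}

#' Construct a rule-base
#'
#' A rule-base is a set of two-antecedent rules
#' `IF var1 is lab1 AND var2 is lab2 THEN output is cons`, for one output
#' channel (atracurium or isoflurane). Antecedent labels range over
#' NB..PB, consequents over ZE..PB. There is at most one rule per
#' antecedent signature (pair of variables plus their labels): the
#' self-organizing layer replaces consequents rather than duplicating
#' rules, and duplicated signatures in `rules` resolve last-wins with a
#' warning.
#'
#' @param rules data frame with columns `in1_var`, `in1_label`,
#'   `in2_var`, `in2_label`, `consequent_label`.
#' @param output output channel name, e.g. `"atracurium"`.
#' @return an object of class `"rulebase"`.
#' @export
rulebase <- function(rules, output = "output") {
  need <- c("in1_var", "in1_label", "in2_var", "in2_label",
            "consequent_label")
  stopifnot(is.data.frame(rules), all(need %in% names(rules)))
  rules <- rules[need]
  for (col in need) rules[[col]] <- as.character(rules[[col]])
  ok_in <- rules$in1_label %in% input_labels() &
    rules$in2_label %in% input_labels()
  if (any(!ok_in))
    stop("unknown antecedent label in rules at row(s) ",
         paste(which(!ok_in), collapse = ", "), call. = FALSE)
  ok_out <- rules$consequent_label %in% output_labels()
  if (any(!ok_out))
    stop("unknown consequent label in rules at row(s) ",
         paste(which(!ok_out), collapse = ", "), call. = FALSE)
  # canonicalize pair order
  for (r in seq_len(nrow(rules))) {
    pi <- pair_index(rules$in1_var[r], rules$in2_var[r])
    if (pi$swapped) {
      rules[r, c("in1_var", "in1_label", "in2_var", "in2_label")] <-
        rules[r, c("in2_var", "in2_label", "in1_var", "in1_label")]
    }
  }
  sig <- paste(rules$in1_var, rules$in1_label, rules$in2_var,
               rules$in2_label)
  if (anyDuplicated(sig)) {
    warning("duplicate antecedent signatures: keeping the last occurrence",
            call. = FALSE)
    rules <- rules[!duplicated(sig, fromLast = TRUE), , drop = FALSE]
  }
  rownames(rules) <- NULL
  structure(list(output = output, rules = rules), class = "rulebase")
}

#' @export
print.rulebase <- function(x, ...) {
  cat(sprintf("<rulebase> output: %s, %d rules\n", x$output,
              nrow(x$rules)))
  invisible(x)
}

#' @export
length.rulebase <- function(x) nrow(x$rules)

#' @export
as.data.frame.rulebase <- function(x, ...) {
  cbind(output_var = x$output, x$rules)
}

#' Read / write a rule-base file
#'
#' Rule-bases are serialized as CSV with a required header
#' `output_var,in1_var,in1_label,in2_var,in2_label,consequent_label`
#' (or an equivalent JSON array of records, chosen by file extension).
#' Round trips are lossless; files with duplicated antecedent signatures
#' load last-wins with a warning; unknown label tokens are an error
#' naming the offending line.
#'
#' @param path file path (`.csv` or `.json`).
#' @return `read_rulebase()`: a [rulebase()]. `write_rulebase()`: the
#'   path, invisibly.
#' @export
read_rulebase <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("output_var", "in1_var", "in1_label", "in2_var", "in2_label",
            "consequent_label")
  if (!all(need %in% names(df)))
    stop("rule-base file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- which(!(df$in1_label %in% input_labels()) |
                 !(df$in2_label %in% input_labels()) |
                 !(df$consequent_label %in% output_labels()))
  if (length(bad))
    stop("unknown label token in ", path, " at data line(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  out <- unique(df$output_var)
  if (length(out) != 1L)
    stop("rule-base file must describe a single output channel",
         call. = FALSE)
  rulebase(df[setdiff(need, "output_var")], output = out)
}

#' @rdname read_rulebase
#' @param rb a [rulebase()].
#' @export
write_rulebase <- function(rb, path) {
  stopifnot(inherits(rb, "rulebase"))
  df <- as.data.frame(rb)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", pretty = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Bundled rule-base fixtures
#'
#' The package ships four rule-bases: the expert-derived atracurium and
#' isoflurane rule-bases (anesthesiologist knowledge over the six
#' decomposed input pairs) and the pretrained extracted rule-bases (the
#' subset of frequently-fired rules distilled from self-organized runs;
#' strictly smaller, concentrated on mid-range input conditions).
#'
#' @param kind `"expert"` or `"extracted"`.
#' @return `default_rulebases()`: a list with elements `atracurium` and
#'   `isoflurane`. `rulebase_file()`: path to a bundled CSV.
#' @export
default_rulebases <- function(kind = c("expert", "extracted")) {
  kind <- match.arg(kind)
  list(atracurium = read_rulebase(rulebase_file(paste0(kind, "_atracurium"))),
       isoflurane = read_rulebase(rulebase_file(paste0(kind, "_isoflurane"))))
}

#' @rdname default_rulebases
#' @param name fixture name, one of `"expert_atracurium"`,
#'   `"expert_isoflurane"`, `"extracted_atracurium"`,
#'   `"extracted_isoflurane"`, `"pi_matrix"`.
#' @export
rulebase_file <- function(name) {
  f <- system.file("extdata", paste0(name, ".csv"), package = "soflc",
                   mustWork = TRUE)
  f
}

# ---- fast matrix form used by the engine ------------------------------------
# one 7x7 integer matrix per decomposed pair; 0 = no rule, otherwise the
# consequent's index in output_labels()

rb_to_matrices <- function(rb) {
  labs <- input_labels()
  mats <- replicate(6, matrix(0L, 7, 7, dimnames = list(labs, labs)),
                    simplify = FALSE)
  for (r in seq_len(nrow(rb$rules))) {
    pi <- pair_index(rb$rules$in1_var[r], rb$rules$in2_var[r])
    i <- match(rb$rules$in1_label[r], labs)
    j <- match(rb$rules$in2_label[r], labs)
    mats[[pi$pair]][i, j] <- match(rb$rules$consequent_label[r],
                                   output_labels())
  }
  mats
}

matrices_to_rb <- function(mats, output) {
  labs <- input_labels()
  pairs <- decompose_inputs()
  rows <- list()
  for (p in 1:6) {
    idx <- which(mats[[p]] > 0L, arr.ind = TRUE)
    if (nrow(idx)) {
      rows[[p]] <- data.frame(
        in1_var = pairs$var1[p], in1_label = labs[idx[, 1]],
        in2_var = pairs$var2[p], in2_label = labs[idx[, 2]],
        consequent_label = output_labels()[mats[[p]][idx]],
        stringsAsFactors = FALSE)
    }
  }
  rulebase(do.call(rbind, rows), output = output)
}
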