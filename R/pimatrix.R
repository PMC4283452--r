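#' The self-organizing performance-index matrix
#'
#' A 7x7 lookup of correction labels indexed by the crisp label of a
#' channel's error (rows) and integral error (columns), both over NB..PB.
#' The correction label expresses the required change of the controller
#' output for that channel: negative labels shift fired rules' consequents
#' down (less drug increment), positive ones up. The matrix is designed
#' for fast convergence around equilibrium, is monotone nondecreasing
#' along every row and column, and is odd-symmetric: the correction at
#' `(e, ie)` is the negation of the correction at `(-e, -ie)`. It is
#' patient-independent and shared by the muscle-relaxation and
#' blood-pressure channels. Shipped as `pi_matrix.csv`; both properties
#' are verified at load.
#'
#' @return `pi_matrix()`: a 7x7 character matrix with NB..PB dimnames.
#' @export
pi_matrix <- function() {
  f <- rulebase_file("pi_matrix")
  df <- utils::read.csv(f, stringsAsFactors = FALSE, row.names = 1)
  m <- as.matrix(df)
  labs <- input_labels()
  if (!identical(rownames(m), labs) || !identical(colnames(m), labs))
    stop("pi matrix must be 7x7 with NB..PB row and column names",
         call. = FALSE)
  if (!all(m %in% labs))
    stop("pi matrix contains unknown correction labels", call. = FALSE)
  idx <- matrix(match(m, labs), 7, 7)
  if (any(apply(idx, 1, diff) < 0) || any(apply(idx, 2, diff) < 0))
    stop("pi matrix must be nondecreasing along rows and columns",
         call. = FALSE)
  m
}

#' Look up the correction label for an (error, integral-error) pair
#'
#' @param matrix the matrix from [pi_matrix()].
#' @param e_label,ie_label crisp linguistic labels (NB..PB) of the
#'   channel's error and integral error (see [label_inputs()]).
#' @return the correction label.
#' @examples
#' pi_lookup(pi_matrix(), "ZE", "ZE")  # "ZE"
#' @export
pi_lookup <- function(matrix, e_label, ie_label) {
  labs <- input_labels()
  if (!(e_label %in% labs) || !(ie_label %in% labs))
    stop("labels must be one of ", paste(labs, collapse = ", "),
         call. = FALSE)
  matrix[e_label, ie_label]
}

#' Signed index offset of a correction label
#'
#' Maps the correction label to the signed number of steps by which a
#' consequent label index is shifted: ZE -> 0, PS/NS -> +/-1,
#' PM/NM -> +/-2, PB/NB -> +/-3.
#'
#' @param label a correction label (NB..PB).
#' @return integer offset in -3..3.
#' @export
correction_offset <- function(label) {
  off <- c(NB = -3L, NM = -2L, NS = -1L, ZE = 0L,
           PS = 1L, PM = 2L, PB = 3L)
  if (!label %in% names(off))
    stop("unknown correction label: ", label, call. = FALSE)
  off[[label]]
}
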