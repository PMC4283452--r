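#' Firing interval of a two-antecedent rule
#'
#' Combines the membership grades of the two antecedent sets with the
#' minimum t-norm, applied separately to the lower and to the upper
#' bounds. Accepts crisp grades (type-1), intervals `c(lower, upper)`,
#' or per-slice interval matrices (zSlices), in any matching combination;
#' crisp grades are treated as degenerate intervals.
#'
#' @param m1,m2 membership grades of the two antecedents, as returned by
#'   [membership()].
#' @return same shape as the inputs: a crisp strength, an interval
#'   `c(lower, upper)` with `lower <= upper`, or a per-slice matrix.
#' @examples
#' firing_interval(c(0.2, 0.4), c(0.3, 0.9))  # -> c(0.2, 0.4)
#' @export
firing_interval <- function(m1, m2) {
  as_im <- function(m) {
    if (is.matrix(m)) m
    else if (length(m) == 2L && !is.null(names(m))) rbind(m)
    else if (length(m) == 1L) cbind(lower = m, upper = m)
    else rbind(m)
  }
  a <- as_im(m1); b <- as_im(m2)
  stopifnot(nrow(a) == nrow(b))
  out <- pmin(a, b)
  colnames(out) <- c("lower", "upper")
  if (nrow(out) == 1L) {
    v <- out[1L, ]
    if (length(m1) == 1L && length(m2) == 1L) return(unname(v["lower"]))
    return(v)
  }
  out
}

# sample the upper/lower MFs of every output label of a partition on a
# grid; returns list(grid, up, lo) with up/lo arrays (nlab, nslice, ngrid)
consequent_grid <- function(partition, n_grid = 1001L) {
  height <- identical(partition$style, "height")
  inner <- identical(partition$style, "inner")
  wmax <- if (height || inner) 0 else max(partition$w)
  hull <- c(partition$universe[1] - partition$half - wmax,
            partition$universe[2] + partition$half + wmax)
  grid <- seq(hull[1], hull[2], length.out = n_grid)
  nl <- length(partition$peaks); ns <- length(partition$z)
  up <- array(0, dim = c(nl, ns, n_grid))
  lo <- array(0, dim = c(nl, ns, n_grid))
  for (i in seq_len(nl)) {
    d <- abs(grid - partition$peaks[i])
    for (s in seq_len(ns)) {
      if (height) {
        up[i, s, ] <- pmax(0, 1 - d / partition$half)
        lo[i, s, ] <- (1 - partition$w[s]) * up[i, s, ]
      } else if (inner) {
        up[i, s, ] <- pmax(0, 1 - d / partition$half)
        lo[i, s, ] <- pmax(0, 1 - d / (partition$half - partition$w[s]))
      } else {
        up[i, s, ] <- pmax(0, 1 - d / (partition$half + partition$w[s]))
        lo[i, s, ] <- pmax(0, 1 - d / (partition$half - partition$w[s]))
      }
    }
  }
  list(grid = grid, up = up, lo = lo)
}

#' Mamdani aggregation of fired rules onto an output grid
#'
#' Truncates each fired rule's consequent set at the rule's firing
#' interval (minimum t-norm) and aggregates across rules with the
#' pointwise maximum, per bound and per slice, producing the aggregated
#' output set that the type reducer consumes.
#'
#' @param consequents integer vector: index of each fired rule's
#'   consequent label in `output_partition$labels`.
#' @param firing list (one entry per fired rule) of firing intervals as
#'   returned by [firing_interval()] (crisp, interval, or per-slice
#'   matrix).
#' @param output_partition a [build_partition()] for the output variable.
#' @param n_grid number of uniform grid points.
#' @return an object of class `"aggregated_set"`: list with `grid`, `z`,
#'   and `upper`, `lower` matrices of size `n_slices x n_grid`.
#' @export
infer <- function(consequents, firing, output_partition, n_grid = 1001L) {
  stopifnot(inherits(output_partition, "fuzzy_partition"),
            length(consequents) == length(firing))
  if (length(consequents) == 0L)
    stop("no rule fires: the aggregated output set is empty", call. = FALSE)
  cg <- consequent_grid(output_partition, n_grid)
  ns <- length(output_partition$z)
  upper <- matrix(0, ns, n_grid)
  lower <- matrix(0, ns, n_grid)
  for (r in seq_along(consequents)) {
    f <- firing[[r]]
    fm <- if (is.matrix(f)) f
          else matrix(rep(if (length(f) == 1L) c(f, f) else f, each = ns), ns)
    ci <- consequents[r]
    for (s in seq_len(ns)) {
      upper[s, ] <- pmax(upper[s, ], pmin(fm[s, 2L], cg$up[ci, s, ]))
      lower[s, ] <- pmax(lower[s, ], pmin(fm[s, 1L], cg$lo[ci, s, ]))
    }
  }
  structure(list(grid = cg$grid, z = output_partition$z,
                 upper = upper, lower = lower),
            class = "aggregated_set")
}

# one Karnik-Mendel switch-point centroid; left = TRUE gives y_l
km_bound <- function(x, up, lo, left) {
  th <- (up + lo) / 2
  s <- sum(th)
  y <- sum(th * x) / s
  n <- length(x)
  for (it in 1:200) {
    k <- findInterval(y, x)
    k <- min(max(k, 0L), n)
    w <- if (left) lo else up
    if (k > 0L) {
      head <- seq_len(k)
      w[head] <- if (left) up[head] else lo[head]
    }
    sw <- sum(w)
    if (sw == 0) return(y)
    ynew <- sum(w * x) / sw
    if (abs(ynew - y) <= 1e-12 * max(1, abs(ynew))) return(ynew)
    y <- ynew
  }
  y
}

#' Karnik-Mendel type reduction
#'
#' Collapses an aggregated interval set on a grid into the interval
#' `[y_l, y_r]` of switch-point centroids, using the classic iterative
#' Karnik-Mendel procedure: `y_l` weights grid points up to the switch
#' point with the upper membership and beyond it with the lower (and
#' conversely for `y_r`). A degenerate set (upper = lower) reduces to the
#' ordinary type-1 centroid on both bounds.
#'
#' @param aggregated an `"aggregated_set"` from [infer()], or a list with
#'   `grid`, `upper`, `lower` where upper/lower are single envelopes
#'   (vectors) or `n_slices x n_grid` matrices.
#' @return a `1 x 2` matrix per slice stack: matrix with columns
#'   `yl`, `yr`, one row per slice (rows of all-zero envelope are `NA`).
#'   For a single-slice input a named vector `c(yl = , yr = )`.
#' @export
km_type_reduce <- function(aggregated) {
  up <- aggregated$upper
  lo <- aggregated$lower
  if (!is.matrix(up)) { up <- rbind(up); lo <- rbind(lo) }
  x <- aggregated$grid
  ns <- nrow(up)
  out <- matrix(NA_real_, ns, 2L, dimnames = list(NULL, c("yl", "yr")))
  any_mass <- FALSE
  for (s in seq_len(ns)) {
    if (all(up[s, ] <= 0)) next
    any_mass <- TRUE
    out[s, 1L] <- km_bound(x, up[s, ], lo[s, ], left = TRUE)
    out[s, 2L] <- km_bound(x, up[s, ], lo[s, ], left = FALSE)
  }
  if (!any_mass)
    stop("aggregated set is identically zero: no centroid", call. = FALSE)
  if (ns == 1L) return(out[1L, ])
  out
}

#' Defuzzify a type-reduced set
#'
#' An interval `[y_l, y_r]` defuzzifies to its midpoint. A stack of
#' per-slice intervals defuzzifies to the z-weighted mean of the slice
#' midpoints, `sum(z_i c_i) / sum(z_i)`; slices whose aggregated set was
#' empty (NA rows) are excluded from the weighting.
#'
#' @param reduced a `c(yl, yr)` interval or the per-slice matrix returned
#'   by [km_type_reduce()].
#' @param z z-levels for the per-slice form (defaults to equally spaced
#'   `k/n`).
#' @return crisp value.
#' @examples
#' defuzzify(c(0.3, 0.5))  # 0.4
#' @export
defuzzify <- function(reduced, z = NULL) {
  if (!is.matrix(reduced)) {
    if (length(reduced) != 2L || any(is.na(reduced)))
      stop("empty type-reduced set", call. = FALSE)
    return(unname(mean(reduced)))
  }
  ci <- rowMeans(reduced)
  if (is.null(z)) z <- seq_len(nrow(reduced)) / nrow(reduced)
  keep <- !is.na(ci)
  if (!any(keep)) stop("empty type-reduced set", call. = FALSE)
  sum(z[keep] * ci[keep]) / sum(z[keep])
}
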