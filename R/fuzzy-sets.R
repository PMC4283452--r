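#' @title Triangular fuzzy sets: type-1, interval type-2, zSlices
#' @description
#' All membership functions in the package are triangular. A type-1 set is
#' a triangle; an interval type-2 set is a triangle whose feet are blurred
#' outward (upper membership function) and inward (lower membership
#' function) by a footprint-of-uncertainty (FOU) half-width `w`; a zSlices
#' general type-2 set is a stack of interval sets at secondary-membership
#' levels `z_k = k/n`, with nested FOUs shrinking as `z` rises. A set with
#' one slice and `w = 0` degenerates exactly to type-1, which is how the
#' three controller variants share a single inference engine.
#' @name fuzzy-sets
NULL

# slice FOU widths shrink linearly with z: slice k of n has width
# w * (n - k + 1) / n, so a single slice keeps the full width.
slice_widths <- function(fou_width, n_zslices) {
  k <- seq_len(n_zslices)
  list(z = k / n_zslices, w = fou_width * (n_zslices - k + 1) / n_zslices)
}

new_fuzzy_set <- function(label, peaks, half, z, w, style = "feet") {
  if (style %in% c("feet", "inner") && any(w >= half))
    stop("fou_width too large: lower membership function would vanish ",
         "(need fou half-width < triangle half-width ", half, ")",
         call. = FALSE)
  if (style == "height" && any(w >= 1))
    stop("fou_width too large: height-style widths are fractions in [0, 1)",
         call. = FALSE)
  if (any(w < 0)) stop("fou widths must be >= 0", call. = FALSE)
  structure(list(label = label, peaks = rep_len(peaks, length(z)),
                 half = half, z = z, w = w, style = style),
            class = "fuzzy_set")
}

set_kind <- function(set) {
  if (length(set$z) > 1L) "zslice"
  else if (set$w[1] > 0) "interval"
  else "type1"
}

#' Membership grade of a fuzzy set at a point
#'
#' For a type-1 set returns a crisp grade in `[0, 1]`; for an interval
#' type-2 set the interval `c(lower, upper)` where the vertical line at
#' `x` crosses the FOU; for a zSlices set one such interval per slice
#' (a `n_slices x 2` matrix with the z-levels as row names). Intervals of
#' successive slices are nested. `x` is clamped to `universe` when given.
#'
#' @param set a `"fuzzy_set"` (from [build_partition()] partitions or
#'   [build_fou_from_stats()]).
#' @param x a single numeric input.
#' @param universe optional `c(lo, hi)` clamp range.
#' @return grade, interval, or matrix of per-slice intervals.
#' @export
membership <- function(set, x, universe = NULL) {
  stopifnot(inherits(set, "fuzzy_set"), length(x) == 1L)
  if (!is.null(universe)) x <- min(max(x, universe[1]), universe[2])
  d <- abs(x - set$peaks)
  if (identical(set$style, "height")) {
    up <- pmax(0, 1 - d / set$half)
    lo <- (1 - set$w) * up
  } else if (identical(set$style, "inner")) {
    up <- pmax(0, 1 - d / set$half)
    lo <- pmax(0, 1 - d / (set$half - set$w))
  } else {
    up <- pmax(0, 1 - d / (set$half + set$w))
    lo <- pmax(0, 1 - d / (set$half - set$w))
  }
  kind <- set_kind(set)
  if (kind == "type1") return(unname(up))
  m <- cbind(lower = lo, upper = up)
  rownames(m) <- paste0("z=", format(set$z))
  if (kind == "interval") return(m[1L, ])
  m
}

#' Build a linguistic variable as an even triangular partition
#'
#' Places one triangular label set per entry of `labels`, peaks evenly
#' spaced across `universe` with 50% overlap (each triangle's feet sit on
#' the neighbouring peaks). `fou_width > 0` adds a footprint of
#' uncertainty in one of three geometries: `fou_style = "feet"` blurs
#' every triangle's feet outward (upper) and inward (lower) by
#' `+/- fou_width` (universe units); `"inner"` keeps the upper membership
#' function equal to the type-1 triangle and only pulls the lower foot in
#' by `fou_width`, so the firing reach matches type-1; `"height"` keeps
#' the support and scales the lower membership function down to
#' `(1 - fou_width)` of the upper (`fou_width` a fraction of membership
#' height). `n_zslices > 1` stacks nested slices whose FOU widths shrink
#' linearly with the z-level, giving a zSlices general type-2 partition.
#' Inputs outside the universe are treated as saturated at its edge (see
#' [membership()]).
#'
#' @param name variable name.
#' @param universe numeric `c(lo, hi)`.
#' @param labels character vector of ordered linguistic labels, e.g.
#'   `c("NB","NM","NS","ZE","PS","PM","PB")`.
#' @param fou_width FOU half-width: universe units (less than the peak
#'   spacing) for `"feet"`, a fraction in `[0, 1)` for `"height"`.
#' @param n_zslices number of zSlices (1 = interval/type-1).
#' @param fou_style FOU geometry, see above.
#' @return an object of class `"fuzzy_partition"`: a list with the
#'   geometry and one `"fuzzy_set"` per label in `$sets`.
#' @examples
#' part <- build_partition("e", c(-1, 1), input_labels(), fou_width = 0.1)
#' membership(part$sets$ZE, 0.1)
#' @export
build_partition <- function(name, universe, labels, fou_width = 0,
                            n_zslices = 1L,
                            fou_style = c("feet", "inner", "height")) {
  fou_style <- match.arg(fou_style)
  stopifnot(length(universe) == 2L, universe[1] < universe[2],
            length(labels) >= 2L, fou_width >= 0, n_zslices >= 1L)
  peaks <- seq(universe[1], universe[2], length.out = length(labels))
  half <- peaks[2] - peaks[1]
  sw <- slice_widths(fou_width, n_zslices)
  sets <- lapply(seq_along(labels), function(i)
    new_fuzzy_set(labels[i], peaks[i], half, sw$z, sw$w, fou_style))
  names(sets) <- labels
  structure(list(name = name, universe = universe, labels = labels,
                 peaks = peaks, half = half, fou_width = fou_width,
                 style = fou_style, z = sw$z, w = sw$w, sets = sets),
            class = "fuzzy_partition")
}

#' Standard linguistic label vocabularies
#'
#' Input variables use seven labels from negative big to positive big;
#' controller output increments use the four nonnegative labels.
#'
#' @return character vector of ordered labels.
#' @export
input_labels <- function() c("NB", "NM", "NS", "ZE", "PS", "PM", "PB")

#' @rdname input_labels
#' @export
output_labels <- function() c("ZE", "PS", "PM", "PB")

#' Build a type-2 set from signal statistics
#'
#' Heuristic FOU construction from summary statistics of a monitored
#' signal: the set is a triangle centered on `center` with half-width
#' `half_width`, and the FOU half-width is `scale * sd`, so a more
#' variable signal yields a wider footprint. With `group_stats` (a data
#' frame with columns `mean` and `sd`, one row per patient group, at most
#' five) one slice is built per group, ordered by decreasing dispersion so
#' the widest FOU sits at the lowest z-level; nesting is verified on a
#' grid and non-nestable geometries are an error.
#'
#' @param center triangle center (signal mean).
#' @param sd signal standard deviation (>= 0; 0 gives a type-1 set).
#' @param scale multiplier from SD to FOU half-width.
#' @param half_width triangle half-width; default three scaled SDs (must
#'   be supplied when `sd = 0`).
#' @param group_stats optional per-group data frame (`mean`, `sd`).
#' @param label label attached to the set.
#' @return a `"fuzzy_set"`.
#' @export
build_fou_from_stats <- function(center, sd, scale = 1,
                                 half_width = NULL, group_stats = NULL,
                                 label = "SET") {
  stopifnot(sd >= 0, scale >= 0)
  if (is.null(half_width)) {
    half_width <- 3 * scale * sd
    if (half_width == 0)
      stop("half_width must be supplied when sd = 0", call. = FALSE)
  }
  if (is.null(group_stats)) {
    w <- scale * sd
    set <- new_fuzzy_set(label, center, half_width,
                         z = 1, w = w)
    return(set)
  }
  stopifnot(is.data.frame(group_stats),
            all(c("mean", "sd") %in% names(group_stats)),
            nrow(group_stats) >= 1L, nrow(group_stats) <= 5L)
  ord <- order(group_stats$sd, decreasing = TRUE)
  gs <- group_stats[ord, , drop = FALSE]
  n <- nrow(gs)
  set <- new_fuzzy_set(label, peaks = gs$mean, half = half_width,
                       z = seq_len(n) / n, w = scale * gs$sd)
  # verify FOU nesting on a grid (group means may shift the triangles)
  hull <- range(set$peaks) + c(-1, 1) * (half_width + max(set$w))
  xg <- seq(hull[1], hull[2], length.out = 501)
  for (k in seq_len(n - 1L)) {
    upk  <- pmax(0, 1 - abs(xg - set$peaks[k]) / (set$half + set$w[k]))
    lok  <- pmax(0, 1 - abs(xg - set$peaks[k]) / (set$half - set$w[k]))
    upk1 <- pmax(0, 1 - abs(xg - set$peaks[k + 1]) / (set$half + set$w[k + 1]))
    lok1 <- pmax(0, 1 - abs(xg - set$peaks[k + 1]) / (set$half - set$w[k + 1]))
    if (any(upk1 > upk + 1e-12) || any(lok1 < lok - 1e-12))
      stop("group FOUs are not nestable even after sorting by dispersion",
           call. = FALSE)
  }
  set
}

#' Crisp linguistic label of an input value
#'
#' Returns the label whose (upper, widest-slice) membership at `x` is
#' maximal; ties are broken toward the ZE label. Used by the
#' self-organizing layer, whose performance-index lookup needs one crisp
#' label per input.
#'
#' @param x crisp input (clamped to the universe).
#' @param partition a [build_partition()] object.
#' @return a label string.
#' @export
label_inputs <- function(x, partition) {
  stopifnot(inherits(partition, "fuzzy_partition"), length(x) == 1L)
  x <- min(max(x, partition$universe[1]), partition$universe[2])
  mu <- pmax(0, 1 - abs(x - partition$peaks) /
               (partition$half + partition$w[1]))
  best <- which(mu >= max(mu) - 1e-9)
  if (length(best) > 1L) {
    ze <- match("ZE", partition$labels, nomatch = NA_integer_)
    if (!is.na(ze)) best <- best[order(abs(best - ze), best)]
  }
  partition$labels[best[1L]]
}

# fast internal: memberships of all labels at x, array (nlab, nslice, 2)
# [, , 1] lower, [, , 2] upper
part_memberships <- function(partition, x) {
  x <- min(max(x, partition$universe[1]), partition$universe[2])
  d <- abs(x - partition$peaks)
  nl <- length(partition$peaks)
  ns <- length(partition$z)
  if (identical(partition$style, "height")) {
    mu <- pmax(0, 1 - d / partition$half)
    up <- matrix(mu, nl, ns)
    lo <- up * rep(1 - partition$w, each = nl)
  } else if (identical(partition$style, "inner")) {
    up <- matrix(pmax(0, 1 - d / partition$half), nl, ns)
    lo <- pmax(0, 1 - outer(d, partition$half - partition$w, "/"))
  } else {
    up <- pmax(0, 1 - outer(d, partition$half + partition$w, "/"))
    lo <- pmax(0, 1 - outer(d, partition$half - partition$w, "/"))
  }
  array(c(lo, up), dim = c(nl, ns, 2L))
}
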