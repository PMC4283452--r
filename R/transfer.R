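#' Linear transfer-function block with dead time
#'
#' Represents a proper rational transfer function in time-constant form,
#' \deqn{G(s) = K \frac{\prod_k (1 + z_k s)}{\prod_i (1 + T_i s)} e^{-\tau s},}
#' the building block of the patient model: the atracurium pharmacodynamic
#' path, the isoflurane-to-MAP path and the isoflurane-to-paralysis
#' interaction path are all of this form. Pole time constants must be
#' positive and distinct (all the physiological blocks are), and the block
#' must be proper (at least as many poles as zeros).
#'
#' @param gain steady-state (DC) gain `K`; units depend on the block
#'   (e.g. mmHg per percent isoflurane).
#' @param poles vector of pole time constants `T_i`, in minutes.
#' @param zeros vector of zero time constants `z_k`, in minutes (may be
#'   empty).
#' @param dead_time pure transport delay `tau`, in minutes.
#' @return an object of class `"linear_block"`.
#' @seealso [discretize()], [plant_parameters()]
#' @examples
#' iso_bp <- linear_block(-15, poles = 2, dead_time = 0.42)
#' dc_gain(iso_bp)
#' @export
linear_block <- function(gain, poles, zeros = numeric(0), dead_time = 0) {
  stopifnot(is.numeric(gain), length(gain) == 1L, is.finite(gain))
  poles <- as.numeric(poles)
  zeros <- as.numeric(zeros)
  if (length(poles) < 1L || any(poles <= 0))
    stop("all pole time constants must be > 0", call. = FALSE)
  if (anyDuplicated(poles))
    stop("pole time constants must be distinct", call. = FALSE)
  if (length(zeros) > length(poles))
    stop("improper transfer function: more zeros than poles", call. = FALSE)
  if (length(dead_time) != 1L || dead_time < 0)
    stop("dead_time must be a single value >= 0", call. = FALSE)
  structure(list(gain = gain, poles = poles, zeros = zeros,
                 dead_time = dead_time),
            class = "linear_block")
}

#' @export
print.linear_block <- function(x, ...) {
  num <- if (length(x$zeros))
    paste0("(", paste0("1 + ", x$zeros, "s", collapse = ")("), ")") else "1"
  den <- paste0("(", paste0("1 + ", x$poles, "s", collapse = ")("), ")")
  cat(sprintf("G(s) = %g %s / %s exp(-%gs)\n", x$gain, num, den, x$dead_time))
  invisible(x)
}

#' Steady-state gain of a block
#'
#' @param block a [linear_block()] or discretized block.
#' @return the DC gain `K`.
#' @export
dc_gain <- function(block) {
  if (inherits(block, "discrete_block")) return(sum(block$b / (1 - block$a)))
  block$gain
}

# Partial-fraction (modal) decomposition over distinct real poles:
# residue of mode i in G(s) = sum_i r_i / (s + p_i), p_i = 1/T_i.
block_modes <- function(block) {
  Tp <- block$poles
  p <- 1 / Tp
  r <- vapply(seq_along(Tp), function(i) {
    num <- block$gain * prod(1 - block$zeros * p[i])
    den <- Tp[i] * prod(1 - Tp[-i] * p[i])
    num / den
  }, numeric(1))
  list(p = p, r = r)
}

#' Discretize a linear block with zero-order hold
#'
#' Converts a continuous [linear_block()] into an exact zero-order-hold
#' discrete recursion at sampling step `dt`, using the modal (partial
#' fraction) form: each first-order mode `r_i/(s + p_i)` becomes
#' `x_i[k] = a_i x_i[k-1] + b_i u[k]` with `a_i = exp(-p_i dt)` and
#' `b_i = (r_i/p_i)(1 - a_i)`. The dead time becomes an integer delay of
#' `round(tau/dt)` steps, so the discrete DC gain equals the continuous
#' gain exactly and the delay semantics are exact to half a step.
#'
#' @param block a [linear_block()].
#' @param dt sampling step in minutes; must be well below the smallest
#'   pole time constant (refused at `dt >=` smallest pole).
#' @return an object of class `"discrete_block"` with fields `a`, `b`
#'   (per-mode coefficients), `delay_steps` and `dt`.
#' @examples
#' blk <- discretize(linear_block(-15, poles = 2, dead_time = 0.42), dt = 0.01)
#' # step response settles at the DC gain:
#' tail(block_response(blk, rep(1, 6000)), 1)
#' @export
discretize <- function(block, dt) {
  stopifnot(inherits(block, "linear_block"), is.numeric(dt), length(dt) == 1L)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (dt >= min(block$poles))
    stop("unstable discretization: dt must be smaller than the smallest ",
         "pole time constant (", min(block$poles), " min)", call. = FALSE)
  m <- block_modes(block)
  a <- exp(-m$p * dt)
  structure(list(a = a, b = (m$r / m$p) * (1 - a),
                 delay_steps = as.integer(round(block$dead_time / dt)),
                 dt = dt, block = block),
            class = "discrete_block")
}

#' Response of a discretized block to an input sequence
#'
#' Steps the discrete recursion from rest through the input sequence `u`
#' (one value per `dt` interval, zero-order held) and returns the sampled
#' output, dead time included. Output sample `k` is the block output at
#' time `k * dt`.
#'
#' @param dblock a `"discrete_block"` from [discretize()].
#' @param u numeric input sequence.
#' @return numeric output sequence of the same length.
#' @export
block_response <- function(dblock, u) {
  stopifnot(inherits(dblock, "discrete_block"))
  u <- as.numeric(u)
  pre <- 0
  for (i in seq_along(dblock$a))
    pre <- pre + as.numeric(stats::filter(dblock$b[i] * u, dblock$a[i],
                                          method = "recursive"))
  D <- dblock$delay_steps
  if (D > 0L) pre <- c(numeric(D), pre)[seq_along(u)]
  pre
}
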