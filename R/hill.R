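#' Hill concentration-effect parameters
#'
#' Parameters of the sigmoidal Hill curve relating effect-site drug
#' concentration to drug effect. Defaults are the atracurium values used
#' throughout the package: maximal effect 100%, half-effect concentration
#' 0.404 ug/mL and slope exponent 2.98.
#'
#' @param emax maximal effect, in percent (> 0).
#' @param xe50 concentration producing half the maximal effect, ug/mL (> 0).
#' @param alpha Hill slope exponent (> 0).
#' @return an object of class `"hill_params"`.
#' @export
hill_params <- function(emax = 100, xe50 = 0.404, alpha = 2.98) {
  if (emax <= 0 || xe50 <= 0 || alpha <= 0)
    stop("emax, xe50 and alpha must all be > 0", call. = FALSE)
  structure(list(emax = emax, xe50 = xe50, alpha = alpha),
            class = "hill_params")
}

#' Hill equation drug effect
#'
#' Evaluates the Hill curve
#' \deqn{E = E_{max} \frac{X^\alpha}{X^\alpha + X_{50}^\alpha}}
#' at effect-site concentration(s) `concentration`. The effect is strictly
#' increasing in concentration, zero at zero, equal to `emax/2` at
#' `xe50`, and bounded above by `emax`.
#'
#' @param concentration effect-site concentration(s), ug/mL; must be >= 0.
#' @param params a [hill_params()] object.
#' @return effect in percent, same length as `concentration`.
#' @examples
#' hill_effect(0.404)  # half-effect concentration -> 50
#' @export
hill_effect <- function(concentration, params = hill_params()) {
  stopifnot(inherits(params, "hill_params"))
  if (any(concentration < 0))
    stop("concentration must be >= 0", call. = FALSE)
  xa <- concentration ^ params$alpha
  params$emax * xa / (xa + params$xe50 ^ params$alpha)
}
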