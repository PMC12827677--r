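#' Mixing coefficient for a target marker radiopacity
#'
#' Computes the contrast-agent mixing fraction needed to print a marker with
#' a target CT number, given the attenuation of the pure resin and of the
#' pure contrast agent:
#' \deqn{k = \frac{CT_{goal} - CT_{resin}}{CT_{CA} - CT_{resin}}}
#' The achievable attenuation is constrained by the two pure-component
#' values; when the target lies outside that interval the function warns
#' (reporting the achievable range) and still returns the out-of-range `k`.
#'
#' @param ctGoal target CT number, HU.
#' @param ctResin attenuation of the pure resin, HU.
#' @param ctCA attenuation of the pure contrast agent, HU.
#' @return the mixing fraction `k` (dimensionless; in `[0, 1]` iff the goal
#'   is achievable).
#' @examples
#' mixingCoefficient(4600, 100, 25100)  # 0.18
#' @seealso [predictedCT()], the exact inverse.
#' @export
mixingCoefficient <- function(ctGoal, ctResin, ctCA) {
  if (any(ctCA == ctResin))
    stop("degenerate denominator: ctCA must differ from ctResin")
  k <- (ctGoal - ctResin) / (ctCA - ctResin)
  if (any(k < 0 | k > 1)) {
    lo <- pmin(ctResin, ctCA); hi <- pmax(ctResin, ctCA)
    warning(sprintf(
      "target %s HU outside the achievable range [%g, %g] HU (k = %s)",
      paste(signif(ctGoal[k < 0 | k > 1], 6), collapse = ", "),
      min(lo), max(hi), paste(signif(k[k < 0 | k > 1], 6), collapse = ", ")))
  }
  k
}

#' Predicted CT number of a resin / contrast-agent mixture
#'
#' Inverse of [mixingCoefficient()]: the CT number expected for a mixture
#' with fraction `k` of contrast agent,
#' \eqn{CT = CT_{resin} + k (CT_{CA} - CT_{resin})}.
#'
#' @param k mixing fraction (dimensionless).
#' @param ctResin,ctCA pure-component attenuations, HU.
#' @return predicted CT number, HU.
#' @examples
#' predictedCT(0.18, 100, 25100)  # 4600
#' @export
predictedCT <- function(k, ctResin, ctCA) {
  ctResin + k * (ctCA - ctResin)
}
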