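#' Logistic psychometric function for heat-pain calibration
#'
#' Builds the temperature-to-rating mapping used to calibrate stimulus
#' temperatures to target VAS levels. The mapping is a logistic curve onto
#' the open interval (0, 100),
#' \deqn{VAS(T) = 100 / (1 + \exp\{-k (T - T_{50})\}),}
#' where \eqn{T_{50}} is the temperature rated VAS 50 and the `slope`
#' argument is the derivative of the curve at the midpoint in VAS units per
#' degree Celsius (so the internal rate is \eqn{k = 4\,\mathrm{slope}/100}).
#' A logistic is used because it is a sigmoid with a closed-form inverse, so
#' the temperatures producing target ratings (VAS 30/50/70) are obtained
#' exactly by inversion.
#'
#' @param midpoint Temperature (degrees C) rated VAS 50.
#' @param slope Steepness at the midpoint, in VAS units per degree C.
#'   Must be positive.
#' @return An object of class `"psychometric"`: a list with elements
#'   `forward` (temperature -> expected VAS), `inverse` (VAS in (0, 100) ->
#'   temperature), `midpoint`, `slope` and the logistic rate `k`.
#' @examples
#' psy <- make_psychometric(midpoint = 45, slope = 35)
#' psy$forward(45)        # 50 by symmetry
#' psy$inverse(30)        # temperature producing VAS 30
#' @export
make_psychometric <- function(midpoint, slope) {
  stopifnot(is.numeric(midpoint), length(midpoint) == 1L, is.finite(midpoint),
            is.numeric(slope), length(slope) == 1L, is.finite(slope))
  if (slope <= 0)
    stop("psychometric 'slope' must be positive (VAS per degree C)", call. = FALSE)
  k <- 4 * slope / 100
  forward <- function(temperature_c) {
    100 * stats::plogis(k * (temperature_c - midpoint))
  }
  inverse <- function(vas) {
    if (any(vas <= 0 | vas >= 100))
      stop("'vas' must lie strictly inside (0, 100) to be invertible", call. = FALSE)
    midpoint + stats::qlogis(vas / 100) / k
  }
  structure(list(forward = forward, inverse = inverse,
                 midpoint = midpoint, slope = slope, k = k),
            class = "psychometric")
}

#' @export
print.psychometric <- function(x, ...) {
  cat("Logistic psychometric mapping: temperature (degrees C) -> VAS (0-100)\n")
  cat(sprintf("  midpoint T50: %.2f C   slope at midpoint: %.2f VAS/C\n",
              x$midpoint, x$slope))
  span <- x$inverse(70) - x$inverse(30)
  cat(sprintf("  calibration span VAS 30 -> 70: %.3f C\n", span))
  invisible(x)
}
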