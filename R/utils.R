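# Internal numeric helpers shared across modules.

# FWHM of a Gaussian = 2*sqrt(2*ln 2) * sigma
FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2))

fwhmToSigma <- function(fwhm) fwhm / FWHM_PER_SIGMA

sigmaToFwhm <- function(sigma) sigma * FWHM_PER_SIGMA

#' Analytic integral of an axis-aligned 2D Gaussian
#'
#' For a component \eqn{a \exp(-(x-c_1)^2/2\sigma_1^2 - (y-c_2)^2/2\sigma_2^2)}
#' the integral over the plane is \eqn{2\pi a \sigma_1 \sigma_2}, i.e.
#' \eqn{a \, \pi \, \mathrm{fwhm}_1 \mathrm{fwhm}_2 / (4 \ln 2)}.
#'
#' @param amplitude peak height (intensity units).
#' @param fwhm1,fwhm2 full widths at half maximum along the two axes (ppm).
#' @return the integral (intensity x ppm^2), vectorized over its arguments.
#' @examples
#' gaussianIntegral2D(1, 2, 3)
#' @export
gaussianIntegral2D <- function(amplitude, fwhm1, fwhm2) {
  amplitude * 2 * pi * fwhmToSigma(fwhm1) * fwhmToSigma(fwhm2)
}

# Wrap angles (degrees) into [-180, 180)
wrapAngle <- function(a) ((a + 180) %% 360) - 180

# Shortest signed periodic difference a - b in degrees
angleDiff <- function(a, b) wrapAngle(a - b)

# Set the RNG when a seed is supplied; NULL leaves the RNG stream alone.
applySeed <- function(seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# validity helper: collapse character(0) to TRUE
validOrMsgs <- function(msgs) if (length(msgs)) msgs else TRUE

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
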