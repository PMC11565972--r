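#' Line-broadening specification
#'
#' Gaussian broadening applied to a binned shift histogram, given as FWHM
#' in ppm per dimension. The default of 1.5 ppm in both dimensions models a
#' homogeneous per-conformer line width.
#'
#' @slot fwhm numeric(2): FWHM in ppm along (axis1, axis2).
#' @export
setClass("BroadeningSpec", slots = c(fwhm = "numeric"))

setValidity("BroadeningSpec", function(object) {
  if (length(object@fwhm) != 2 || any(!is.finite(object@fwhm)) ||
      any(object@fwhm <= 0))
    "fwhm must be two positive finite values" else TRUE
})

#' @describeIn BroadeningSpec-class constructor.
#' @param fwhm1,fwhm2 FWHM in ppm on the direct and indirect dimensions.
#' @export
broadening <- function(fwhm1 = 1.5, fwhm2 = fwhm1) {
  new("BroadeningSpec", fwhm = c(fwhm1, fwhm2))
}

# Dense Gaussian convolution matrix along an axis: entry [i, j] is the
# Gaussian density (per ppm) at distance (i - j) grid steps. Multiplying a
# histogram by these matrices performs separable broadening while keeping
# the Riemann integral equal to the bin-count total (up to edge truncation).
.convMatrix <- function(n, step, sigma) {
  i <- seq_len(n)
  dnorm(outer(i, i, "-") * step, sd = sigma)
}

#' Build a 2D cross-peak shape from per-conformer shift pairs
#'
#' Shift pairs are binned onto the grid (nearest grid point) and the
#' histogram is convolved with a separable 2D Gaussian kernel of the given
#' FWHM; this is equivalent to summing one Gaussian kernel per conformer.
#' The Riemann integral of the result equals the number of contributing
#' conformers, up to kernel mass truncated at the grid edges.
#'
#' @param shifts two-column matrix (or data.frame) of per-conformer
#'   (axis1 ppm, axis2 ppm) pairs; at least one row.
#' @param axis1,axis2 [PpmAxis-class] grid axes.
#' @param broadening a [BroadeningSpec-class] (default 1.5/1.5 ppm FWHM).
#' @param outOfRange `"error"` (default) to reject shifts outside the grid,
#'   `"clip"` to drop them with a warning.
#' @return a [Spectrum2D-class]; metadata records the conformer count and
#'   broadening.
#' @examples
#' ax1 <- ppmAxisCovering("13C-CA", 45, 60)
#' ax2 <- ppmAxisCovering("13C-CB", 10, 26)
#' s <- buildCrosspeak(cbind(53, 18), ax1, ax2)
#' @export
buildCrosspeak <- function(shifts, axis1, axis2, broadening = NULL,
                           outOfRange = c("error", "clip")) {
  outOfRange <- match.arg(outOfRange)
  if (is.null(broadening)) broadening <- new("BroadeningSpec",
                                             fwhm = c(1.5, 1.5))
  shifts <- as.matrix(shifts)
  if (!nrow(shifts) || ncol(shifts) != 2)
    stopf("shifts must be a two-column matrix with at least one row")
  x <- ppmValues(axis1); y <- ppmValues(axis2)
  inx <- shifts[, 1] >= min(x) & shifts[, 1] <= max(x)
  iny <- shifts[, 2] >= min(y) & shifts[, 2] <= max(y)
  keep <- inx & iny
  if (!all(keep)) {
    if (outOfRange == "error")
      stopf("%d shift pair(s) fall outside the grid (e.g. %.2f, %.2f)",
            sum(!keep), shifts[which(!keep)[1], 1], shifts[which(!keep)[1], 2])
    warning(sprintf("clipping %d shift pair(s) outside the grid",
                    sum(!keep)), call. = FALSE)
    shifts <- shifts[keep, , drop = FALSE]
    if (!nrow(shifts)) stopf("no shift pairs remain inside the grid")
  }
  j <- round((shifts[, 1] - axis1@start) / axis1@step) + 1L
  i <- round((shifts[, 2] - axis2@start) / axis2@step) + 1L
  H <- matrix(0, axis2@n, axis1@n)
  counts <- table(factor((j - 1L) * axis2@n + i,
                         levels = seq_len(axis1@n * axis2@n)))
  H[] <- as.numeric(counts)
  K2 <- .convMatrix(axis2@n, axis2@step, fwhmToSigma(broadening@fwhm[2]))
  K1 <- .convMatrix(axis1@n, axis1@step, fwhmToSigma(broadening@fwhm[1]))
  I <- K2 %*% H %*% K1
  spectrum2D(I, axis1, axis2,
             metadata = list(n_shifts = nrow(shifts),
                             broadening_fwhm = broadening@fwhm))
}

#' Normalize a spectrum to unit integrated intensity
#'
#' @param spectrum a [Spectrum2D-class] with non-zero total integral.
#' @return the spectrum scaled so its Riemann integral equals 1.
#' @examples
#' ax <- ppmAxisCovering("13C", 0, 10)
#' s <- buildCrosspeak(cbind(5, 5), ax, ax)
#' integrateSpectrum(normalizeIntegral(s))
#' @export
normalizeIntegral <- function(spectrum) {
  tot <- integrateSpectrum(spectrum)
  if (!is.finite(tot) || tot == 0)
    stopf("cannot normalize: spectrum has zero total integral")
  spectrum@intensity <- spectrum@intensity / tot
  spectrum@metadata$normalized <- TRUE
  spectrum
}

#' Match a target spectrum's intensity to a reference over an ROI
#'
#' Computes the factor `integral(reference over roi) / integral(target over
#' roi)` and returns the target multiplied by it, so both spectra carry the
#' same integrated intensity over the matching region.
#'
#' @param reference,target [Spectrum2D-class] objects.
#' @param roi a [roiWindow()] non-empty on both grids.
#' @return list with `factor` and `scaled` (the rescaled target).
#' @export
matchIntensity <- function(reference, target, roi) {
  refInt <- integrateSpectrum(reference, roi)
  tgtInt <- integrateSpectrum(target, roi)
  if (!is.finite(refInt) || refInt <= 0)
    stopf("reference ROI integral must be > 0 (got %g)", refInt)
  if (!is.finite(tgtInt) || tgtInt == 0)
    stopf("target ROI integral is zero; cannot match intensities")
  factor <- refInt / tgtInt
  target@intensity <- target@intensity * factor
  target@metadata$intensity_match_factor <- factor
  list(factor = factor, scaled = target)
}

#' Extract a peak-normalized 1D slice from a 2D spectrum
#'
#' Fixes a ppm value on one axis and returns the profile along the other,
#' scaled to unit maximum. The default takes the nearest grid row/column;
#' `interpolate = TRUE` linearly interpolates between the two flanking
#' rows/columns.
#'
#' @param spectrum a [Spectrum2D-class].
#' @param along `"axis1"` to return a profile over axis1 (slicing at a ppm
#'   on axis2), `"axis2"` for the converse.
#' @param at ppm position of the slice on the fixed axis.
#' @param interpolate linear interpolation between flanking grid lines.
#' @return data.frame with columns `ppm` and `intensity` (max 1).
#' @export
extractSlice <- function(spectrum, along = c("axis1", "axis2"), at,
                         interpolate = FALSE) {
  along <- match.arg(along)
  fixedAxis <- if (along == "axis1") spectrum@axis2 else spectrum@axis1
  lim <- axisLimits(fixedAxis)
  if (at < lim[1] || at > lim[2])
    stopf("slice position %.3f ppm outside axis '%s' range %.3f..%.3f",
          at, fixedAxis@label, lim[1], lim[2])
  v <- ppmValues(fixedAxis)
  profileOf <- function(idx) {
    if (along == "axis1") spectrum@intensity[idx, ] else
      spectrum@intensity[, idx]
  }
  if (interpolate) {
    lo <- max(which(v <= at)); hi <- min(which(v >= at))
    if (lo == hi) prof <- profileOf(lo)
    else {
      wHi <- (at - v[lo]) / (v[hi] - v[lo])
      prof <- (1 - wHi) * profileOf(lo) + wHi * profileOf(hi)
    }
  } else {
    prof <- profileOf(which.min(abs(v - at)))
  }
  runAxis <- if (along == "axis1") spectrum@axis1 else spectrum@axis2
  m <- max(prof)
  if (m > 0) prof <- prof / m
  data.frame(ppm = ppmValues(runAxis), intensity = as.numeric(prof))
}
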