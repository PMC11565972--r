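#' PpmAxis: a chemical-shift axis
#'
#' A regularly spaced ppm axis for one dimension of a 2D spectrum. The i-th
#' grid point (1-based) sits at \code{start + (i-1)*step}. A negative step
#' describes a descending axis as stored in many processed-NMR formats;
#' [spectrum2D()] flips descending axes so that spectra are always held with
#' ascending ppm internally.
#'
#' @slot label nucleus/atom label, e.g. \code{"13C-CA"}.
#' @slot start ppm of the first point.
#' @slot step ppm increment per point (non-zero; negative allowed).
#' @slot n number of points (>= 2).
#' @export
setClass("PpmAxis",
  slots = c(label = "character", start = "numeric", step = "numeric",
            n = "integer"))

setValidity("PpmAxis", function(object) {
  msgs <- character()
  if (length(object@n) != 1L || is.na(object@n) || object@n < 2L)
    msgs <- c(msgs, "n_points must be a single integer >= 2")
  if (length(object@step) != 1L || !is.finite(object@step) ||
      object@step == 0)
    msgs <- c(msgs, "step_ppm must be a single non-zero finite number")
  if (length(object@start) != 1L || !is.finite(object@start))
    msgs <- c(msgs, "start_ppm must be a single finite number")
  if (length(object@label) != 1L || is.na(object@label))
    msgs <- c(msgs, "label must be a single string")
  validOrMsgs(msgs)
})

#' Construct a ppm axis
#'
#' @param label nucleus/atom label (e.g. \code{"13C-CA"}); the token before
#'   the first \code{"-"} is taken as the nucleus family when deciding
#'   whether two axes are homonuclear.
#' @param start ppm value of the first point.
#' @param step ppm spacing (negative for a descending axis).
#' @param n number of points.
#' @return a [PpmAxis-class] object.
#' @examples
#' ppmAxis("13C-CA", 45, 0.1, 161)
#' @export
ppmAxis <- function(label, start, step, n) {
  new("PpmAxis", label = as.character(label), start = as.numeric(start),
      step = as.numeric(step), n = as.integer(n))
}

#' Helper: an ascending axis covering a ppm window
#' @param label axis label.
#' @param from,to ppm range (inclusive of `from`; `to` is covered).
#' @param step grid spacing in ppm (default 0.1).
#' @return a [PpmAxis-class].
#' @export
ppmAxisCovering <- function(label, from, to, step = 0.1) {
  n <- ceiling((to - from) / step) + 1L
  ppmAxis(label, from, step, n)
}

#' @describeIn ppmAxis ppm values of all grid points.
#' @param axis a [PpmAxis-class].
#' @export
ppmValues <- function(axis) axis@start + (seq_len(axis@n) - 1L) * axis@step

axisLimits <- function(axis) range(ppmValues(axis))

setMethod("show", "PpmAxis", function(object) {
  lim <- axisLimits(object)
  cat(sprintf("PpmAxis '%s': %d points, %.3f..%.3f ppm (step %.4g)\n",
              object@label, object@n, lim[1], lim[2], object@step))
})

#' Spectrum2D: a 2D intensity grid with ppm axes
#'
#' The container that all prediction, synthesis and fitting operate on.
#' Intensities are stored as an `n2 x n1` matrix: rows follow `axis2`
#' (indirect/y), columns follow `axis1` (direct/x). The logical `mask`
#' marks pixels that participate in fitting (see [maskDiagonal()]).
#'
#' @slot axis1 direct-dimension [PpmAxis-class] (columns).
#' @slot axis2 indirect-dimension [PpmAxis-class] (rows).
#' @slot intensity numeric matrix, `axis2@n` rows by `axis1@n` columns.
#' @slot mask logical matrix of the same shape; `TRUE` = used in fits.
#' @slot metadata provenance list (seeds, ground truth, processing notes).
#' @export
setClass("Spectrum2D",
  slots = c(axis1 = "PpmAxis", axis2 = "PpmAxis", intensity = "matrix",
            mask = "matrix", metadata = "list"))

setValidity("Spectrum2D", function(object) {
  msgs <- character()
  if (nrow(object@intensity) != object@axis2@n ||
      ncol(object@intensity) != object@axis1@n)
    msgs <- c(msgs, "intensity must be axis2@n rows x axis1@n columns")
  if (!all(is.finite(object@intensity)))
    msgs <- c(msgs, "intensities must all be finite")
  if (!identical(dim(object@mask), dim(object@intensity)))
    msgs <- c(msgs, "mask must have the same shape as intensity")
  if (!is.logical(object@mask))
    msgs <- c(msgs, "mask must be logical")
  if (object@axis1@step <= 0 || object@axis2@step <= 0)
    msgs <- c(msgs, "axes must be stored ascending (positive step)")
  validOrMsgs(msgs)
})

#' Construct a 2D spectrum
#'
#' Descending axes (negative step) are accepted and flipped, together with
#' the corresponding matrix dimension, so spectra are stored ascending.
#'
#' @param intensity numeric matrix (`axis2` points x `axis1` points).
#' @param axis1,axis2 [PpmAxis-class] objects for columns and rows.
#' @param mask optional logical matrix; default all `TRUE`.
#' @param metadata provenance list.
#' @return a [Spectrum2D-class].
#' @examples
#' s <- spectrum2D(matrix(0, 5, 4), ppmAxis("13C", 10, 1, 4),
#'                 ppmAxis("13C", 20, 1, 5))
#' @export
spectrum2D <- function(intensity, axis1, axis2, mask = NULL,
                       metadata = list()) {
  intensity <- as.matrix(intensity)
  if (axis1@step < 0) {
    axis1 <- ppmAxis(axis1@label, axis1@start + (axis1@n - 1L) * axis1@step,
                     -axis1@step, axis1@n)
    intensity <- intensity[, rev(seq_len(ncol(intensity))), drop = FALSE]
    if (!is.null(mask)) mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (axis2@step < 0) {
    axis2 <- ppmAxis(axis2@label, axis2@start + (axis2@n - 1L) * axis2@step,
                     -axis2@step, axis2@n)
    intensity <- intensity[rev(seq_len(nrow(intensity))), , drop = FALSE]
    if (!is.null(mask)) mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
  }
  if (is.null(mask))
    mask <- matrix(TRUE, nrow(intensity), ncol(intensity))
  new("Spectrum2D", axis1 = axis1, axis2 = axis2,
      intensity = intensity, mask = mask, metadata = metadata)
}

#' @describeIn spectrum2D intensity matrix accessor.
#' @param spectrum a [Spectrum2D-class].
#' @export
intensityMatrix <- function(spectrum) spectrum@intensity

#' @describeIn spectrum2D direct-dimension axis accessor.
#' @export
directAxis <- function(spectrum) spectrum@axis1

#' @describeIn spectrum2D indirect-dimension axis accessor.
#' @export
indirectAxis <- function(spectrum) spectrum@axis2

#' @describeIn spectrum2D fit-mask accessor.
#' @export
fitMask <- function(spectrum) spectrum@mask

#' @describeIn spectrum2D metadata accessor.
#' @export
spectrumMetadata <- function(spectrum) spectrum@metadata

pixelArea <- function(spectrum) spectrum@axis1@step * spectrum@axis2@step

setMethod("show", "Spectrum2D", function(object) {
  l1 <- axisLimits(object@axis1); l2 <- axisLimits(object@axis2)
  cat(sprintf("Spectrum2D: %d x %d grid\n", nrow(object@intensity),
              ncol(object@intensity)))
  cat(sprintf("  axis1 (x) '%s': %.2f..%.2f ppm\n", object@axis1@label,
              l1[1], l1[2]))
  cat(sprintf("  axis2 (y) '%s': %.2f..%.2f ppm\n", object@axis2@label,
              l2[1], l2[2]))
  cat(sprintf("  integral %.4g, max %.4g, %d masked pixels\n",
              integrateSpectrum(object), max(object@intensity),
              sum(!object@mask)))
  if (length(object@metadata))
    cat("  metadata fields:", paste(names(object@metadata), collapse = ", "),
        "\n")
})

#' Define a rectangular region of interest in ppm
#'
#' @param xlim,ylim length-2 ppm windows on the direct (axis1) and indirect
#'   (axis2) dimensions; order within each pair is irrelevant.
#' @return a list with sorted `xlim`, `ylim` (class `"roiWindow"`).
#' @examples
#' roiWindow(c(48, 58), c(12, 24))
#' @export
roiWindow <- function(xlim, ylim) {
  stopifnot(length(xlim) == 2, length(ylim) == 2,
            all(is.finite(c(xlim, ylim))))
  structure(list(xlim = sort(as.numeric(xlim)), ylim = sort(as.numeric(ylim))),
            class = "roiWindow")
}

# Swap the two dimensions of an ROI (image across the diagonal)
swapRoi <- function(roi) roiWindow(roi$ylim, roi$xlim)

# column / row index sets of an ROI on a spectrum grid
roiIndices <- function(spectrum, roi) {
  x <- ppmValues(spectrum@axis1); y <- ppmValues(spectrum@axis2)
  cols <- which(x >= roi$xlim[1] & x <= roi$xlim[2])
  rows <- which(y >= roi$ylim[1] & y <= roi$ylim[2])
  if (!length(cols) || !length(rows))
    stopf("ROI [%g,%g] x [%g,%g] is empty on this grid", roi$xlim[1],
          roi$xlim[2], roi$ylim[1], roi$ylim[2])
  list(rows = rows, cols = cols)
}

#' Riemann integral of a spectrum (optionally over an ROI)
#'
#' @param spectrum a [Spectrum2D-class].
#' @param roi optional [roiWindow()]; default whole grid.
#' @param maskedOnly if `TRUE`, only pixels with `mask == TRUE` contribute.
#' @return sum of intensities times pixel area.
#' @export
integrateSpectrum <- function(spectrum, roi = NULL, maskedOnly = FALSE) {
  I <- spectrum@intensity
  if (maskedOnly) I <- I * spectrum@mask
  if (!is.null(roi)) {
    idx <- roiIndices(spectrum, roi)
    I <- I[idx$rows, idx$cols, drop = FALSE]
  }
  sum(I) * pixelArea(spectrum)
}

#' Transpose a spectrum across its diagonal
#'
#' Swaps the two axes and transposes intensity and mask; for a homonuclear
#' spectrum this reflects every feature across the diagonal.
#'
#' @param spectrum a [Spectrum2D-class].
#' @return the transposed [Spectrum2D-class].
#' @export
transposeSpectrum <- function(spectrum) {
  spectrum2D(t(spectrum@intensity), axis1 = spectrum@axis2,
             axis2 = spectrum@axis1, mask = t(spectrum@mask),
             metadata = spectrum@metadata)
}

nucleusFamily <- function(axis) strsplit(axis@label, "-", fixed = TRUE)[[1]][1]

isHomonuclear <- function(spectrum) {
  identical(nucleusFamily(spectrum@axis1), nucleusFamily(spectrum@axis2))
}

#' Write / read a spectrum in the portable text format
#'
#' A spectrum is stored as two sibling files: `<stem>.tsv`, the bare
#' intensity matrix (rows = axis2 points), and `<stem>.json`, a sidecar with
#' both axis definitions, metadata, and (when present) the indices of masked
#' pixels.
#'
#' @param spectrum a [Spectrum2D-class].
#' @param stem path stem without extension.
#' @return `writeSpectrum2D` returns `stem` invisibly; `readSpectrum2D`
#'   returns the reconstructed [Spectrum2D-class].
#' @export
writeSpectrum2D <- function(spectrum, stem) {
  write.table(spectrum@intensity, paste0(stem, ".tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  axMeta <- function(a) list(label = a@label, start = a@start, step = a@step,
                             n = a@n)
  side <- list(format = "idpeaks-spectrum-1",
               axis1 = axMeta(spectrum@axis1), axis2 = axMeta(spectrum@axis2),
               metadata = spectrum@metadata)
  if (any(!spectrum@mask))
    side$mask_false_idx <- which(!spectrum@mask)
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname writeSpectrum2D
#' @export
readSpectrum2D <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  ax <- function(m) ppmAxis(m$label, m$start, m$step, m$n)
  I <- as.matrix(read.table(paste0(stem, ".tsv"), sep = "\t"))
  dimnames(I) <- NULL
  mask <- matrix(TRUE, nrow(I), ncol(I))
  if (!is.null(side$mask_false_idx))
    mask[as.integer(side$mask_false_idx)] <- FALSE
  md <- side$metadata
  if (is.null(md)) md <- list()
  spectrum2D(I, ax(side$axis1), ax(side$axis2), mask = mask,
             metadata = as.list(md))
}
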