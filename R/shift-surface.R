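#' ShiftSurface: a periodic backbone-dihedral to chemical-shift map
#'
#' A smooth, 360-degree-periodic surface mapping (phi, psi) to a 13C
#' chemical shift for each (residue type, atom) pair. The surface blends
#' basin-specific anchor shifts with normalized periodic-Gaussian kernel
#' weights centered on the Ramachandran basin centroids: near a basin
#' center the surface equals that basin's anchor; between basins it
#' interpolates continuously. This keeps the dihedral-to-shift map
#' self-contained while matching basin-level statistical-coil shift values.
#'
#' @slot anchors data.frame with columns `residue`, `atom`, `basin`,
#'   `shift` (ppm).
#' @slot centers data.frame with columns `basin`, `phi0`, `psi0` giving the
#'   kernel centroids.
#' @slot kernelWidth kernel scale in degrees (default 15).
#' @export
setClass("ShiftSurface",
  slots = c(anchors = "data.frame", centers = "data.frame",
            kernelWidth = "numeric"))

setValidity("ShiftSurface", function(object) {
  msgs <- character()
  need <- c("residue", "atom", "basin", "shift")
  if (!all(need %in% names(object@anchors)))
    return(paste("anchors must have columns:", paste(need, collapse = ", ")))
  if (any(object@anchors$shift < 10 | object@anchors$shift > 190))
    msgs <- c(msgs, "anchor shifts must lie in the 13C range 10-190 ppm")
  if (!all(object@anchors$basin %in% BASIN_LABELS))
    msgs <- c(msgs, "anchor basins must use the standard labels")
  if (object@kernelWidth <= 0)
    msgs <- c(msgs, "kernelWidth must be > 0")
  if (!all(c("basin", "phi0", "psi0") %in% names(object@centers)))
    msgs <- c(msgs, "centers must have columns basin, phi0, psi0")
  validOrMsgs(msgs)
})

#' Construct a shift surface
#'
#' @param anchors anchor table (`residue`, `atom`, `basin`, `shift`).
#' @param kernelWidth interpolation kernel scale in degrees.
#' @param centers basin centroid table; defaults to the canonical
#'   Ramachandran centroids shared with [defaultDihedralLibrary()].
#' @return a [ShiftSurface-class].
#' @export
shiftSurface <- function(anchors, kernelWidth = 15, centers = NULL) {
  if (is.null(centers))
    centers <- .basinGeometry()[, c("basin", "phi0", "psi0")]
  anchors$residue <- as.character(anchors$residue)
  anchors$atom <- as.character(anchors$atom)
  anchors$basin <- as.character(anchors$basin)
  new("ShiftSurface", anchors = anchors, centers = centers,
      kernelWidth = as.numeric(kernelWidth))
}

setMethod("show", "ShiftSurface", function(object) {
  pairs <- unique(object@anchors[, c("residue", "atom")])
  cat(sprintf("ShiftSurface: %d residue/atom pairs, kernel width %g deg\n",
              nrow(pairs), object@kernelWidth))
})

#' The packaged anchor table
#'
#' Alanine, glycine and leucine Calpha/Cbeta/CO anchors carry the
#' statistical-coil basin shift values the pipeline is calibrated to;
#' serine/threonine anchors and all positive-phi values without a
#' calibrated counterpart are configuration constants in the style of
#' secondary-shift reference compilations, not measured quantities.
#'
#' @return data.frame of anchors (`residue`, `atom`, `basin`, `shift`).
#' @examples
#' head(defaultShiftAnchors())
#' @export
defaultShiftAnchors <- function() {
  rec <- function(res, atom, alpha, coil, beta, pos)
    data.frame(residue = res, atom = atom,
               basin = c("alpha", "ppii_coil", "beta", "positive_phi"),
               shift = c(alpha, coil, beta, pos))
  rbind(
    rec("A", "CA", 55.3, 53.25, 51.3, 53.3),
    rec("A", "CB", 18.0, 18.6, 21.0, 16.0),
    rec("A", "CO", 179.4, 177.8, 176.1, 178.2),
    rec("G", "CA", 46.7, 44.7, 42.8, 45.2),
    rec("G", "CO", 176.3, 174.2, 172.1, 174.8),
    rec("L", "CA", 56.9, 54.5, 52.4, 53.7),
    rec("L", "CB", 41.2, 41.6, 42.7, 39.2),
    rec("L", "CO", 178.5, 177.1, 175.7, 177.4),
    rec("S", "CA", 60.8, 58.3, 56.6, 58.4),
    rec("S", "CB", 62.9, 63.8, 65.3, 61.8),
    rec("S", "CO", 176.8, 174.6, 173.5, 174.9),
    rec("T", "CA", 65.0, 61.8, 60.6, 61.9),
    rec("T", "CB", 68.2, 69.8, 71.2, 67.8),
    rec("T", "CO", 175.9, 174.5, 173.2, 174.7))
}

#' @describeIn defaultShiftAnchors the packaged [ShiftSurface-class] built
#'   from the default anchors.
#' @param kernelWidth kernel scale in degrees (default 15).
#' @export
defaultShiftSurface <- function(kernelWidth = 15) {
  shiftSurface(defaultShiftAnchors(), kernelWidth = kernelWidth)
}

#' Read an anchor table from tab-separated text
#'
#' Expected columns: `residue`, `atom`, `basin`, `shift`.
#'
#' @param path file path.
#' @return data.frame of anchors.
#' @export
readShiftAnchors <- function(path) {
  read.table(path, header = TRUE, sep = "\t",
             colClasses = c("character", "character", "character",
                            "numeric"))
}

anchorsFor <- function(surface, residue, atom) {
  a <- surface@anchors
  a <- a[a$residue == residue & a$atom == atom, , drop = FALSE]
  if (!nrow(a))
    stopf("no shift anchors for residue '%s', atom '%s'", residue, atom)
  a
}

#' Predict a chemical shift from backbone dihedrals
#'
#' The shift is the anchor values blended by normalized periodic-Gaussian
#' kernel weights centered on the basin centroids; it is continuous and
#' 360-degree periodic in both angles, and every prediction lies within the
#' range of the anchor values (convexity of the blend).
#'
#' @param surface a [ShiftSurface-class].
#' @param residue one-letter residue code.
#' @param atom one of `"CA"`, `"CB"`, `"CO"` (CB is absent for glycine).
#' @param phi,psi angles in degrees (vectorized, equal length).
#' @return predicted shift(s) in ppm.
#' @examples
#' predictShift(defaultShiftSurface(), "A", "CA", -63, -43)
#' @export
predictShift <- function(surface, residue, atom, phi, psi) {
  a <- anchorsFor(surface, residue, atom)
  ctr <- surface@centers[match(a$basin, surface@centers$basin), ]
  k2 <- 2 * surface@kernelWidth^2
  # log-weights, stabilized against underflow far from every basin
  lw <- sapply(seq_len(nrow(a)), function(i) {
    -(angleDiff(phi, ctr$phi0[i])^2 + angleDiff(psi, ctr$psi0[i])^2) / k2
  })
  lw <- matrix(lw, nrow = length(phi))
  lw <- lw - apply(lw, 1, max)
  w <- exp(lw)
  as.numeric((w %*% a$shift) / rowSums(w))
}

#' Predict shifts for one residue over a whole ensemble
#'
#' @param surface a [ShiftSurface-class].
#' @param ensemble a [DihedralEnsemble-class].
#' @param residueIndex 1-based position of the residue of interest.
#' @param atoms character vector of atoms, e.g. `c("CA", "CB")`.
#' @return numeric matrix, one row per conformer, one column per atom
#'   (in conformer order).
#' @examples
#' e <- sampleEnsemble(defaultDihedralLibrary(), "AAA", 5, seed = 1)
#' predictEnsembleShifts(defaultShiftSurface(), e, 2, c("CA", "CB"))
#' @export
predictEnsembleShifts <- function(surface, ensemble, residueIndex, atoms) {
  res <- ensembleResidues(ensemble)
  if (residueIndex < 1 || residueIndex > length(res))
    stopf("residue index %d outside 1..%d", residueIndex, length(res))
  rtype <- res[residueIndex]
  if (rtype == "G" && "CB" %in% atoms)
    stopf("atom 'CB' is not defined for glycine")
  d <- residueDihedrals(ensemble, residueIndex)
  out <- sapply(atoms, function(at)
    predictShift(surface, rtype, at, d$phi, d$psi))
  out <- matrix(out, nrow = nrow(d), dimnames = list(NULL, atoms))
  out
}
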