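CLASS_LABELS <- c("alpha", "coil", "beta")

#' ClassWindows: reference chemical-shift windows per conformational class
#'
#' For each residue type and atom, the mean and SD of the reference shift
#' for alpha-helix, random-coil and beta-strand conformations; a component
#' is "inside" a class window when it lies within mean +/- 2 SD on every
#' axis of the cross-peak. The positive-phi class is represented by an
#' anchor point (no tabulated SD) with a proximity radius; it applies to
#' components that fall inside no standard window but lie within the
#' radius of the anchor.
#'
#' @slot windows data.frame with columns `residue`, `atom`, `class`,
#'   `mean`, `sd` (`sd` is `NA` for `positive_phi` anchor rows).
#' @slot posRadius proximity radius (ppm) for positive-phi assignment.
#' @export
setClass("ClassWindows",
  slots = c(windows = "data.frame", posRadius = "numeric"))

setValidity("ClassWindows", function(object) {
  w <- object@windows
  msgs <- character()
  need <- c("residue", "atom", "class", "mean", "sd")
  if (!all(need %in% names(w)))
    return(paste("windows must have columns:", paste(need, collapse = ", ")))
  std <- w$class %in% CLASS_LABELS
  if (any(w$sd[std] <= 0, na.rm = TRUE) || any(is.na(w$sd[std])))
    msgs <- c(msgs, "alpha/coil/beta windows must have sd > 0")
  if (object@posRadius <= 0)
    msgs <- c(msgs, "posRadius must be positive")
  validOrMsgs(msgs)
})

#' @describeIn ClassWindows-class constructor.
#' @param windows window table (see class slots).
#' @param posRadius positive-phi proximity radius in ppm (default 1.5).
#' @export
classWindows <- function(windows, posRadius = 1.5) {
  windows$residue <- as.character(windows$residue)
  windows$atom <- as.character(windows$atom)
  windows$class <- as.character(windows$class)
  new("ClassWindows", windows = windows, posRadius = posRadius)
}

setMethod("show", "ClassWindows", function(object) {
  pairs <- unique(object@windows[, c("residue", "atom")])
  cat(sprintf("ClassWindows: %d residue/atom pairs, pos-phi radius %g ppm\n",
              nrow(pairs), object@posRadius))
})

#' The packaged reference class windows
#'
#' Window means/SDs are configuration constants in the style of
#' secondary-shift reference compilations (means aligned with the packaged
#' anchor table so that statistical-coil components classify onto their
#' generating basins); they are not fitted quantities.
#'
#' @return a [ClassWindows-class] covering A, G, L, S, T at CA/CB/CO.
#' @export
defaultClassWindows <- function() {
  rec <- function(res, atom, am, as., cm, cs, bm, bs, pos)
    data.frame(residue = res, atom = atom,
               class = c("alpha", "coil", "beta", "positive_phi"),
               mean = c(am, cm, bm, pos), sd = c(as., cs, bs, NA))
  w <- rbind(
    rec("A", "CA", 55.2, 1.2, 53.2, 1.0, 51.2, 1.2, 53.3),
    rec("A", "CB", 18.0, 0.9, 18.7, 1.0, 21.2, 1.0, 16.0),
    rec("A", "CO", 179.4, 1.3, 177.8, 1.2, 176.1, 1.4, 178.2),
    rec("G", "CA", 46.9, 1.0, 44.9, 1.0, 43.9, 1.2, 45.2),
    rec("G", "CO", 177.2, 1.2, 174.2, 1.2, 171.8, 1.5, 174.8),
    rec("L", "CA", 57.0, 1.0, 54.6, 1.0, 52.9, 1.3, 53.7),
    rec("L", "CB", 41.3, 0.9, 41.9, 1.0, 43.7, 1.6, 39.2),
    rec("L", "CO", 178.5, 1.2, 177.1, 1.2, 175.7, 1.4, 177.4),
    rec("S", "CA", 61.0, 1.2, 58.3, 1.1, 56.8, 1.3, 58.4),
    rec("S", "CB", 62.9, 1.0, 63.8, 1.0, 65.2, 1.3, 61.8),
    rec("T", "CA", 65.1, 1.3, 61.8, 1.2, 60.7, 1.4, 61.9),
    rec("T", "CB", 68.2, 1.0, 69.8, 1.1, 71.2, 1.4, 67.8))
  classWindows(w)
}

windowsFor <- function(windows, residue, atom, class) {
  w <- windows@windows
  row <- w[w$residue == residue & w$atom == atom & w$class == class, ,
           drop = FALSE]
  if (!nrow(row))
    stopf("no class window for residue '%s', atom '%s', class '%s'",
          residue, atom, class)
  row[1, ]
}

#' Classify a fitted component by reference shift windows
#'
#' For each of alpha/coil/beta the normalized distance is the maximum over
#' the two atoms of |center - mean| / sd; the component takes the class of
#' minimal distance when that distance is <= 2 (inside the +/- 2 SD window
#' on both axes). A component inside no standard window but within
#' `posRadius` ppm (Euclidean) of the positive-phi anchor is assigned
#' `positive_phi`. A component outside every window whose
#' only violations are excursions beyond the beta-strand mean in the
#' extended-shift direction is labelled `beta` with `extremeBeta = TRUE`;
#' any other out-of-window component is `unclassified` (nearest class
#' recorded).
#'
#' @param center numeric(2): component center (atom1 ppm, atom2 ppm).
#' @param residue one-letter residue code.
#' @param atoms character(2): the cross-peak atoms, e.g. `c("CA", "CB")`.
#' @param windows a [ClassWindows-class].
#' @return list with `class`, `extremeBeta`, `within2sd`, `nearest`, and
#'   the per-class normalized `distances`.
#' @examples
#' classifyComponent(c(55.1, 18.5), "A", c("CA", "CB"))
#' @export
classifyComponent <- function(center, residue, atoms,
                              windows = defaultClassWindows()) {
  stopifnot(length(center) == 2, length(atoms) == 2)
  wtab <- lapply(CLASS_LABELS, function(cl)
    lapply(atoms, function(at) windowsFor(windows, residue, at, cl)))
  names(wtab) <- CLASS_LABELS
  d <- vapply(CLASS_LABELS, function(cl) {
    max(vapply(1:2, function(i)
      abs(center[i] - wtab[[cl]][[i]]$mean) / wtab[[cl]][[i]]$sd,
      numeric(1)))
  }, numeric(1))
  posAnchor <- vapply(atoms, function(at)
    windowsFor(windows, residue, at, "positive_phi")$mean, numeric(1))
  posDist <- sqrt(sum((center - posAnchor)^2))
  betaMean <- vapply(1:2, function(i) wtab$beta[[i]]$mean, numeric(1))
  betaSd <- vapply(1:2, function(i) wtab$beta[[i]]$sd, numeric(1))
  coilMean <- vapply(1:2, function(i) wtab$coil[[i]]$mean, numeric(1))
  extDir <- sign(betaMean - coilMean)       # extended-shift direction
  beyond <- (center - betaMean) * extDir    # >0 = past beta mean, extended
  extremeExc <- beyond > 2 * betaSd
  nearest <- names(which.min(d))
  if (posDist <= windows@posRadius && min(d) > 2) {
    cls <- "positive_phi"; within <- TRUE; extreme <- FALSE
  } else if (min(d) <= 2) {
    cls <- nearest; within <- TRUE
    extreme <- cls == "beta" && any(extremeExc)
  } else {
    # outside every window: beta-with-extreme escape or unclassified
    offAxes <- vapply(1:2, function(i)
      abs(center[i] - betaMean[i]) > 2 * betaSd[i], logical(1))
    onlyExtended <- all(!offAxes | (beyond > 0))
    if (nearest == "beta" && onlyExtended && any(extremeExc)) {
      cls <- "beta"; within <- FALSE; extreme <- TRUE
    } else {
      cls <- "unclassified"; within <- FALSE; extreme <- FALSE
    }
  }
  list(class = cls, extremeBeta = extreme, within2sd = within,
       nearest = nearest, distances = d, posDistance = posDist)
}

#' Classify every component of a fit
#'
#' @param fit a [MixtureFit-class] or [DiagonalPairResult-class].
#' @param residue one-letter residue code of the cross-peak.
#' @param atoms character(2) cross-peak atoms.
#' @param windows a [ClassWindows-class].
#' @return data.frame: one row per component with centers, FWHMs,
#'   `fraction` (and `fraction_sd` for diagonal pairs), `class`,
#'   `extremeBeta`, `within2sd`.
#' @export
classifyFit <- function(fit, residue, atoms,
                        windows = defaultClassWindows()) {
  if (is(fit, "DiagonalPairResult")) {
    m <- fit@matched
    base <- data.frame(component = m$component, center1 = m$center1,
                       center2 = m$center2, fwhm1 = m$fwhm1,
                       fwhm2 = m$fwhm2, fraction = m$fractionMean,
                       fraction_sd = m$fractionSd)
  } else {
    cmp <- fit@components
    base <- data.frame(component = seq_len(nrow(cmp)),
                       center1 = cmp$center1, center2 = cmp$center2,
                       fwhm1 = cmp$fwhm1, fwhm2 = cmp$fwhm2,
                       fraction = cmp$fraction, fraction_sd = NA_real_)
  }
  cl <- lapply(seq_len(nrow(base)), function(i)
    classifyComponent(c(base$center1[i], base$center2[i]), residue, atoms,
                      windows))
  base$class <- vapply(cl, `[[`, character(1), "class")
  base$extremeBeta <- vapply(cl, `[[`, logical(1), "extremeBeta")
  base$within2sd <- vapply(cl, `[[`, logical(1), "within2sd")
  base
}

#' Per-condition conformational-class population report
#'
#' Aggregates matched diagonal-pair fits into a per-condition, per-class
#' population table: fractions of components sharing a class are summed,
#' their SDs combined in quadrature, and populations expressed in percent.
#' Per-condition percentages sum to 100 up to rounding.
#'
#' @param pairResults list of [DiagonalPairResult-class] objects whose
#'   metadata carries `residue` and `atoms` (see [fitDiagonalPair()]).
#' @param windows a [ClassWindows-class].
#' @param labels character vector of unique condition names, one per
#'   element of `pairResults`.
#' @return data.frame with columns `condition`, `residue`, `class`,
#'   `percent`, `percent_sd`, `n_components`.
#' @export
buildPopulationReport <- function(pairResults,
                                  windows = defaultClassWindows(),
                                  labels) {
  if (!length(pairResults))
    stopf("need at least one condition to report")
  if (length(labels) != length(pairResults))
    stopf("labels must name each pair result (%d vs %d)",
          length(labels), length(pairResults))
  if (anyDuplicated(labels))
    stopf("condition labels must be unique (duplicated: %s)",
          paste(unique(labels[duplicated(labels)]), collapse = ", "))
  rows <- lapply(seq_along(pairResults), function(i) {
    pr <- pairResults[[i]]
    residue <- pr@metadata$residue
    atoms <- pr@metadata$atoms
    if (is.null(residue) || anyNA(residue) || is.null(atoms) ||
        anyNA(atoms))
      stopf("pair result %d lacks residue/atoms metadata for classification",
            i)
    tab <- classifyFit(pr, residue, atoms, windows)
    agg <- lapply(split(tab, tab$class), function(g)
      data.frame(condition = labels[i], residue = residue,
                 class = g$class[1],
                 percent = 100 * sum(g$fraction),
                 percent_sd = 100 * sqrt(sum(g$fraction_sd^2)),
                 n_components = nrow(g)))
    do.call(rbind, agg)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a population report as tab-separated text
#' @param report data.frame from [buildPopulationReport()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writePopulationReport <- function(report, path) {
  write.table(report, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
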