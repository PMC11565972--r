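#' Constraints for cross-peak mixture fits
#'
#' Operationalizes "constrained peak motions": fitted centers may move at
#' most `centerBound` ppm from their initial guesses, FWHMs are bounded,
#' and the admissible component counts are `kRange`.
#'
#' @slot kRange integer vector of admissible component counts (subset of
#'   1..4).
#' @slot centerBound maximum center excursion from the initial guess (ppm).
#' @slot fwhmBounds length-2 (lower, upper) FWHM bounds in ppm.
#' @slot initialGuesses optional k x 2 matrix of initial centers
#'   (axis1 ppm, axis2 ppm); zero rows means "auto" (local maxima).
#' @export
setClass("FitConstraints",
  slots = c(kRange = "integer", centerBound = "numeric",
            fwhmBounds = "numeric", initialGuesses = "matrix"))

setValidity("FitConstraints", function(object) {
  msgs <- character()
  if (!length(object@kRange) || any(object@kRange < 1 | object@kRange > 4))
    msgs <- c(msgs, "kRange must be a subset of 1..4")
  if (object@centerBound <= 0)
    msgs <- c(msgs, "centerBound must be positive")
  if (length(object@fwhmBounds) != 2 || any(object@fwhmBounds <= 0) ||
      diff(object@fwhmBounds) <= 0)
    msgs <- c(msgs, "fwhmBounds must be positive and ordered (lo, hi)")
  if (nrow(object@initialGuesses) && ncol(object@initialGuesses) != 2)
    msgs <- c(msgs, "initialGuesses must have two columns")
  validOrMsgs(msgs)
})

#' @describeIn FitConstraints-class constructor.
#' @param kRange admissible component counts.
#' @param centerBound max center excursion in ppm (default 1.0).
#' @param fwhmBounds FWHM bounds in ppm (default 0.5 to 8).
#' @param initialGuesses optional matrix/list of initial centers.
#' @export
fitConstraints <- function(kRange = 1:4, centerBound = 1.0,
                           fwhmBounds = c(0.5, 8), initialGuesses = NULL) {
  if (is.null(initialGuesses))
    initialGuesses <- matrix(numeric(0), 0, 2)
  if (is.list(initialGuesses) && !is.data.frame(initialGuesses))
    initialGuesses <- do.call(rbind, initialGuesses)
  new("FitConstraints", kRange = as.integer(kRange),
      centerBound = as.numeric(centerBound),
      fwhmBounds = as.numeric(fwhmBounds),
      initialGuesses = as.matrix(initialGuesses))
}

#' MixtureFit: a fitted set of axis-aligned 2D Gaussians
#'
#' @slot components data.frame with one row per component: `center1`,
#'   `center2`, `fwhm1`, `fwhm2` (ppm), `amplitude`, `integral`,
#'   `fraction` (component integral over the sum of integrals).
#' @slot residualNorm residual sum of squares of the best fit.
#' @slot kSelected fitted component count.
#' @slot converged optimizer convergence flag.
#' @slot metadata provenance (ROI, seed, starts, per-start residuals,
#'   noise floor, degenerate flag).
#' @export
setClass("MixtureFit",
  slots = c(components = "data.frame", residualNorm = "numeric",
            kSelected = "integer", converged = "logical",
            metadata = "list"))

setValidity("MixtureFit", function(object) {
  msgs <- character()
  cmp <- object@components
  if (nrow(cmp)) {
    if (any(cmp$fwhm1 <= 0 | cmp$fwhm2 <= 0))
      msgs <- c(msgs, "component FWHMs must be positive")
    if (abs(sum(cmp$fraction) - 1) > 1e-6)
      msgs <- c(msgs, "fractions must sum to 1 (+/- 1e-6)")
  }
  validOrMsgs(msgs)
})

#' @describeIn MixtureFit-class component table accessor.
#' @param fit a [MixtureFit-class].
#' @export
fitComponents <- function(fit) fit@components

#' @describeIn MixtureFit-class fractional populations accessor.
#' @export
fractions <- function(fit) fit@components$fraction

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf("MixtureFit: k = %d, converged = %s, RSS = %.4g\n",
              object@kSelected, object@converged, object@residualNorm))
  cmp <- object@components
  if (nrow(cmp))
    print(data.frame(center1 = round(cmp$center1, 2),
                     center2 = round(cmp$center2, 2),
                     fwhm1 = round(cmp$fwhm1, 2),
                     fwhm2 = round(cmp$fwhm2, 2),
                     fraction = round(cmp$fraction, 3)))
})

# Evaluate a k-component model and (optionally) the objective gradient on
# the ROI grid. Parameters per component: cx, cy, fw1, fw2, a.
.mixModel <- function(par, x, y, k) {
  M <- matrix(0, length(y), length(x))
  comps <- vector("list", k)
  for (c in seq_len(k)) {
    p <- par[(c - 1) * 5 + 1:5]
    sx <- fwhmToSigma(p[3]); sy <- fwhmToSigma(p[4])
    ex <- exp(-((x - p[1])^2) / (2 * sx^2))
    ey <- exp(-((y - p[2])^2) / (2 * sy^2))
    comps[[c]] <- list(p = p, ex = ex, ey = ey, sx = sx, sy = sy)
    M <- M + p[5] * (ey %o% ex)
  }
  list(M = M, comps = comps)
}

.mixObjGrad <- function(par, x, y, D, W, k) {
  mm <- .mixModel(par, x, y, k)
  R <- (mm$M - D) * W
  f <- sum(R * R)
  g <- numeric(5 * k)
  R2 <- 2 * R
  for (c in seq_len(k)) {
    cm <- mm$comps[[c]]
    p <- cm$p
    exd <- cm$ex * (x - p[1]) / cm$sx^2
    eyd <- cm$ey * (y - p[2]) / cm$sy^2
    exs <- cm$ex * (x - p[1])^2 / cm$sx^3
    eys <- cm$ey * (y - p[2])^2 / cm$sy^3
    base <- (c - 1) * 5
    # d f / d cx = sum(R2 * a * ey %o% exd) etc.; use bilinear forms
    g[base + 1] <- p[5] * as.numeric(t(cm$ey) %*% R2 %*% exd)
    g[base + 2] <- p[5] * as.numeric(t(eyd) %*% R2 %*% cm$ex)
    g[base + 3] <- p[5] * as.numeric(t(cm$ey) %*% R2 %*% exs) /
      FWHM_PER_SIGMA
    g[base + 4] <- p[5] * as.numeric(t(eys) %*% R2 %*% cm$ex) /
      FWHM_PER_SIGMA
    g[base + 5] <- as.numeric(t(cm$ey) %*% R2 %*% cm$ex)
  }
  list(value = f, gradient = g)
}

# Initial center guesses by greedy peak picking with subtraction: take
# the maximum of the (lightly smoothed) map, subtract a Gaussian of the
# working width scaled to that height, repeat. Subtraction exposes
# shoulders of merged lobes that plain local-maxima picking misses.
.greedyPeaks <- function(M, x, y, k, fwhmGuess) {
  n2 <- nrow(M); n1 <- ncol(M)
  if (n2 > 4 && n1 > 4) {
    kv <- dnorm(-2:2); kv <- kv / sum(kv)
    M <- apply(M, 2, function(col) as.numeric(stats::filter(col, kv,
                                                            sides = 2)))
    M <- t(apply(M, 1, function(row) as.numeric(stats::filter(row, kv,
                                                              sides = 2))))
    M[is.na(M)] <- 0
  }
  sx <- fwhmToSigma(fwhmGuess); sy <- sx
  picks <- matrix(0, k, 2)
  for (c in seq_len(k)) {
    idx <- which.max(M)
    i <- (idx - 1L) %% n2 + 1L; j <- (idx - 1L) %/% n2 + 1L
    picks[c, ] <- c(x[j], y[i])
    g <- M[i, j] * (exp(-(y - y[i])^2 / (2 * sy^2)) %o%
                      exp(-(x - x[j])^2 / (2 * sx^2)))
    M <- M - g
  }
  picks
}

# Noise floor: median absolute deviation of the grid's border pixels.
.noiseFloor <- function(I) {
  n2 <- nrow(I); n1 <- ncol(I)
  b <- c(I[1, ], I[n2, ], I[, 1], I[, n1])
  mad(b, center = 0)
}

.initialCenters <- function(D, x, y, k, constraints, fwhmGuess) {
  ig <- constraints@initialGuesses
  if (nrow(ig)) {
    if (nrow(ig) != k)
      stopf("got %d initial guesses for k = %d components", nrow(ig), k)
    return(ig)
  }
  .greedyPeaks(D, x, y, k, fwhmGuess)
}

#' Fit a constrained 2D Gaussian mixture to a cross-peak region
#'
#' Nonlinear least squares over the ROI pixels (masked pixels excluded)
#' with k axis-aligned 2D Gaussians. Centers are bounded within
#' `centerBound` ppm of their initial guesses (the local maxima of the
#' lightly smoothed ROI by default, or user-supplied positions), FWHMs
#' within `fwhmBounds`. A seeded multistart perturbs the initial guesses
#' and the best residual is kept. Fractional populations are the analytic
#' component integrals normalized to sum to one.
#'
#' @param spectrum a [Spectrum2D-class].
#' @param roi a [roiWindow()] containing the cross-peak.
#' @param k number of components (must lie in `constraints@kRange`).
#' @param constraints a [FitConstraints-class].
#' @param seed integer seed for the multistart jitter.
#' @param nStarts number of optimizer starts (>= 1).
#' @return a [MixtureFit-class]; non-convergence is flagged via
#'   `@converged`, never silent.
#' @export
fitMixture <- function(spectrum, roi, k, constraints = fitConstraints(),
                       seed = NULL, nStarts = 3L) {
  if (!k %in% constraints@kRange)
    stopf("k = %d outside the admissible range {%s}", k,
          paste(constraints@kRange, collapse = ", "))
  idx <- roiIndices(spectrum, roi)
  D <- spectrum@intensity[idx$rows, idx$cols, drop = FALSE]
  W <- spectrum@mask[idx$rows, idx$cols, drop = FALSE] * 1
  x <- ppmValues(spectrum@axis1)[idx$cols]
  y <- ppmValues(spectrum@axis2)[idx$rows]
  noise <- .noiseFloor(spectrum@intensity)
  scale <- max(D * W)
  if (!is.finite(scale) || scale <= 0)
    stopf("ROI contains no unmasked intensity to fit")
  degenerate <- scale < 5 * noise
  Dn <- D / scale
  applySeed(seed)
  fwGuess <- min(max(2.5, constraints@fwhmBounds[1]),
                 constraints@fwhmBounds[2])
  centers0 <- .initialCenters(Dn, x, y, k, constraints, fwGuess)
  lower <- numeric(0); upper <- numeric(0)
  for (c in seq_len(k)) {
    lower <- c(lower, centers0[c, 1] - constraints@centerBound,
               centers0[c, 2] - constraints@centerBound,
               constraints@fwhmBounds[1], constraints@fwhmBounds[1], 0)
    upper <- c(upper, centers0[c, 1] + constraints@centerBound,
               centers0[c, 2] + constraints@centerBound,
               constraints@fwhmBounds[2], constraints@fwhmBounds[2], 3)
  }
  fw0 <- mean(pmin(pmax(2, constraints@fwhmBounds[1]),
                   constraints@fwhmBounds[2]))
  cache <- new.env()
  fn <- function(p) {
    og <- .mixObjGrad(p, x, y, Dn, W, k)
    cache$p <- p; cache$g <- og$gradient
    og$value
  }
  gr <- function(p) {
    if (!identical(p, cache$p)) fn(p)
    cache$g
  }
  best <- NULL; startRss <- numeric(0)
  for (s in seq_len(nStarts)) {
    ctr <- centers0
    if (s > 1)
      ctr <- ctr + matrix(runif(2 * k, -0.5, 0.5) * constraints@centerBound,
                          k, 2)
    p0 <- numeric(0)
    for (c in seq_len(k)) {
      a0 <- Dn[which.min(abs(y - ctr[c, 2])), which.min(abs(x - ctr[c, 1]))]
      p0 <- c(p0, ctr[c, 1], ctr[c, 2], fw0, fw0, max(a0, 0.05))
    }
    p0 <- pmin(pmax(p0, lower), upper)
    opt <- tryCatch(
      optim(p0, fn, gr, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 400, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(opt)) next
    startRss <- c(startRss, opt$value)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stopf("all %d optimizer starts failed for this ROI", nStarts)
  p <- best$par
  cmp <- data.frame(
    center1 = p[seq(1, 5 * k, by = 5)],
    center2 = p[seq(2, 5 * k, by = 5)],
    fwhm1 = p[seq(3, 5 * k, by = 5)],
    fwhm2 = p[seq(4, 5 * k, by = 5)],
    amplitude = p[seq(5, 5 * k, by = 5)] * scale)
  cmp$integral <- gaussianIntegral2D(cmp$amplitude, cmp$fwhm1, cmp$fwhm2)
  tot <- sum(cmp$integral)
  cmp$fraction <- if (tot > 0) cmp$integral / tot else rep(NA_real_, k)
  ord <- order(cmp$integral, decreasing = TRUE)
  cmp <- cmp[ord, , drop = FALSE]
  rownames(cmp) <- NULL
  new("MixtureFit", components = cmp, residualNorm = best$value,
      kSelected = as.integer(k),
      converged = isTRUE(best$convergence == 0) && tot > 0,
      metadata = list(roi = roi, seed = seed, nStarts = nStarts,
                      startRss = startRss, noiseFloor = noise,
                      maxIntensity = scale, degenerate = degenerate,
                      initialCenters = centers0))
}

#' Choose the number of components by information criterion
#'
#' Fits every k in `constraints@kRange` and selects the k minimizing the
#' Bayesian information criterion `n*log(RSS/n) + 5k*log(n)` over the ROI
#' pixels. A flat-noise ROI (maximum below five times the border noise
#' floor) is flagged degenerate and `kSelected` is `NA`.
#'
#' @inheritParams fitMixture
#' @param criterion `"bic"` (default) or `"aic"`.
#' @return list with `kSelected`, `summary` (per-k data.frame of RSS and
#'   criterion values), `fits` (per-k [MixtureFit-class]) and `degenerate`.
#' @export
selectK <- function(spectrum, roi, constraints = fitConstraints(),
                    criterion = c("bic", "aic"), seed = NULL,
                    nStarts = 3L) {
  criterion <- match.arg(criterion)
  fits <- list(); rows <- list()
  idx <- roiIndices(spectrum, roi)
  npix <- sum(spectrum@mask[idx$rows, idx$cols])
  degenerate <- FALSE
  for (k in sort(constraints@kRange)) {
    fit <- fitMixture(spectrum, roi, k, constraints, seed = seed,
                      nStarts = nStarts)
    degenerate <- degenerate || isTRUE(fit@metadata$degenerate)
    pen <- if (criterion == "bic") 5 * k * log(npix) else 10 * k
    crit <- npix * log(fit@residualNorm / npix) + pen
    fits[[as.character(k)]] <- fit
    rows[[as.character(k)]] <- data.frame(k = k, rss = fit@residualNorm,
                                          criterion = crit,
                                          converged = fit@converged)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  kSel <- if (degenerate) NA_integer_ else
    summary$k[which.min(summary$criterion)]
  list(kSelected = kSel, summary = summary, fits = fits,
       degenerate = degenerate)
}

#' DiagonalPairResult: matched fits above and below the spectral diagonal
#'
#' @slot fitAbove,fitBelow [MixtureFit-class] objects; the below-diagonal
#'   fit is performed on the transposed spectrum so both live in the same
#'   coordinate frame.
#' @slot matched data.frame of matched components: centers (above frame),
#'   `fractionAbove`, `fractionBelow`, `fractionMean`, `fractionSd`.
#' @slot metadata provenance (residue, atoms, ROIs, matching distances).
#' @export
setClass("DiagonalPairResult",
  slots = c(fitAbove = "MixtureFit", fitBelow = "MixtureFit",
            matched = "data.frame", metadata = "list"))

setValidity("DiagonalPairResult", function(object) {
  if (object@fitAbove@kSelected != object@fitBelow@kSelected)
    "above- and below-diagonal fits must use the same number of Gaussians"
  else TRUE
})

setMethod("show", "DiagonalPairResult", function(object) {
  cat(sprintf("DiagonalPairResult: k = %d components\n",
              object@fitAbove@kSelected))
  m <- object@matched
  print(data.frame(center1 = round(m$center1, 2),
                   center2 = round(m$center2, 2),
                   fraction = sprintf("%.3f +/- %.3f", m$fractionMean,
                                      m$fractionSd)))
})

#' @describeIn DiagonalPairResult-class matched-component table accessor.
#' @param pair a [DiagonalPairResult-class].
#' @export
matchedComponents <- function(pair) pair@matched

#' Fit a cross-peak independently above and below the diagonal
#'
#' The two symmetry-related images of a homonuclear cross-peak are fit to
#' the same number of Gaussians: the above-diagonal ROI on the spectrum as
#' stored, and the below-diagonal image on the transposed spectrum (so an
#' exactly symmetric spectrum yields bitwise-identical fits). Components
#' are matched across the diagonal by nearest swapped-center proximity
#' (gate 1.5 ppm) and each matched population is reported as the mean +/-
#' the sample standard deviation of the two independent estimates,
#' `sd = |p_above - p_below| / sqrt(2)`.
#'
#' @inheritParams fitMixture
#' @param roiAbove [roiWindow()] of the above-diagonal cross-peak.
#' @param roiBelow optional [roiWindow()]; defaults to (and must equal) the
#'   axis-swapped image of `roiAbove`.
#' @param residue,atoms optional annotations propagated to classification
#'   and reporting.
#' @param matchGate maximum ppm distance for cross-diagonal matching.
#' @return a [DiagonalPairResult-class].
#' @export
fitDiagonalPair <- function(spectrum, roiAbove, roiBelow = NULL, k,
                            constraints = fitConstraints(), seed = NULL,
                            nStarts = 3L, residue = NA_character_,
                            atoms = NA_character_, matchGate = 1.5) {
  if (!isHomonuclear(spectrum))
    stopf("diagonal pairing requires homonuclear axes (got '%s' vs '%s')",
          spectrum@axis1@label, spectrum@axis2@label)
  if (is.null(roiBelow)) roiBelow <- swapRoi(roiAbove)
  expect <- swapRoi(roiAbove)
  if (max(abs(c(roiBelow$xlim - expect$xlim, roiBelow$ylim - expect$ylim)))
      > 1e-9)
    stopf("roiBelow must be the axis-swapped image of roiAbove")
  above <- fitMixture(spectrum, roiAbove, k, constraints, seed = seed,
                      nStarts = nStarts)
  below <- fitMixture(transposeSpectrum(spectrum), roiAbove, k, constraints,
                      seed = seed, nStarts = nStarts)
  ca <- above@components; cb <- below@components
  used <- logical(k); matchIdx <- integer(k); dist <- numeric(k)
  ordA <- order(ca$integral, decreasing = TRUE)
  for (i in ordA) {
    d <- sqrt((ca$center1[i] - cb$center1)^2 +
                (ca$center2[i] - cb$center2)^2)
    d[used] <- Inf
    j <- which.min(d)
    if (!is.finite(d[j]) || d[j] > matchGate)
      stopf(paste0("component at (%.2f, %.2f) has no below-diagonal ",
                   "counterpart within %.1f ppm (nearest at %.2f, %.2f; ",
                   "%.2f ppm away)"), ca$center1[i], ca$center2[i],
            matchGate, cb$center1[j], cb$center2[j], min(d))
    used[j] <- TRUE; matchIdx[i] <- j; dist[i] <- d[j]
  }
  pa <- ca$fraction; pb <- cb$fraction[matchIdx]
  matched <- data.frame(
    component = seq_len(k),
    center1 = ca$center1, center2 = ca$center2,
    fwhm1 = ca$fwhm1, fwhm2 = ca$fwhm2,
    fractionAbove = pa, fractionBelow = pb,
    fractionMean = (pa + pb) / 2,
    fractionSd = abs(pa - pb) / sqrt(2),
    matchDistance = dist)
  new("DiagonalPairResult", fitAbove = above, fitBelow = below,
      matched = matched,
      metadata = list(residue = residue, atoms = atoms, roiAbove = roiAbove,
                      roiBelow = roiBelow, seed = seed))
}

#' Exclude the near-diagonal band from fit weighting
#'
#' Pixels with |ppm1 - ppm2| below `minSeparation` are masked out of fits;
#' intensities are untouched and the mask is flagged in the metadata. Only
#' meaningful for homonuclear spectra.
#'
#' @param spectrum a homonuclear [Spectrum2D-class].
#' @param minSeparation band half-width in ppm (0 leaves the spectrum
#'   unchanged).
#' @return the spectrum with an updated mask.
#' @export
maskDiagonal <- function(spectrum, minSeparation) {
  if (!isHomonuclear(spectrum))
    stopf("no diagonal to mask: axes are heteronuclear ('%s' vs '%s')",
          spectrum@axis1@label, spectrum@axis2@label)
  stopifnot(minSeparation >= 0)
  if (minSeparation == 0) return(spectrum)
  x <- ppmValues(spectrum@axis1); y <- ppmValues(spectrum@axis2)
  band <- abs(outer(y, x, "-")) < minSeparation
  spectrum@mask <- spectrum@mask & !band
  spectrum@metadata$diagonal_mask_ppm <- minSeparation
  spectrum
}

#' Write / read a fit report as tab-separated text
#'
#' One row per component with centers, FWHMs, fraction (and, for diagonal
#' pairs, the fraction SD); a `class` column is `NA` until classification.
#'
#' @param fit a [MixtureFit-class] or [DiagonalPairResult-class].
#' @param path file path.
#' @return `writeFitReport` returns `path` invisibly; `readFitReport` a
#'   data.frame.
#' @export
writeFitReport <- function(fit, path) {
  if (is(fit, "DiagonalPairResult")) {
    m <- fit@matched
    df <- data.frame(component = m$component, center1_ppm = m$center1,
                     center2_ppm = m$center2, fwhm1_ppm = m$fwhm1,
                     fwhm2_ppm = m$fwhm2, fraction = m$fractionMean,
                     fraction_sd = m$fractionSd,
                     residue = fit@metadata$residue %||% NA,
                     atom1 = (fit@metadata$atoms %||% c(NA, NA))[1],
                     atom2 = (fit@metadata$atoms %||% c(NA, NA))[2],
                     class = NA_character_)
  } else {
    cmp <- fit@components
    df <- data.frame(component = seq_len(nrow(cmp)),
                     center1_ppm = cmp$center1, center2_ppm = cmp$center2,
                     fwhm1_ppm = cmp$fwhm1, fwhm2_ppm = cmp$fwhm2,
                     fraction = cmp$fraction, fraction_sd = NA_real_,
                     residue = NA_character_, atom1 = NA_character_,
                     atom2 = NA_character_, class = NA_character_)
  }
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFitReport
#' @export
readFitReport <- function(path) {
  read.table(path, header = TRUE, sep = "\t", na.strings = "NA",
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || all(is.na(a))) b else a
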