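test_that("a single synthetic Gaussian is recovered near-exactly", {
  s <- singleGaussianSpectrum(center = c(53, 18.5), fwhm = c(3, 3))
  fit <- fitMixture(s, fullRoi(s), k = 1, seed = 1)
  cmp <- fitComponents(fit)
  expect_true(fit@converged)
  expect_equal(cmp$center1, 53, tolerance = 0.05)
  expect_equal(cmp$center2, 18.5, tolerance = 0.05)
  expect_equal(cmp$fwhm1, 3, tolerance = 0.05)
  expect_equal(cmp$fraction, 1.0)
})

test_that("two equal Gaussians split 50/50 and fractions always sum to 1", {
  sp <- syntheticSpec(data.frame(
    center1 = c(49, 55), center2 = c(16, 22), fwhm1 = 3, fwhm2 = 3,
    fraction = c(0.5, 0.5)))
  s <- simulateCrosspeak(sp, ppmAxisCovering("13C-CA", 42, 62),
                         ppmAxisCovering("13C-CB", 9, 29))
  fit <- fitMixture(s, fullRoi(s), k = 2, seed = 2)
  expect_equal(sort(fractions(fit)), c(0.5, 0.5), tolerance = 0.02)
  expect_equal(sum(fractions(fit)), 1, tolerance = 1e-9)
})

test_that("the three-component fibril-like peak is recovered under noise", {
  sp <- syntheticSpec(data.frame(
    center1 = c(55.1, 52.3, 50.8), center2 = c(18.5, 18.9, 23.3),
    fwhm1 = 3.2, fwhm2 = 3.2, fraction = c(0.28, 0.34, 0.38)),
    metadata = list(residue = "A", atoms = c("CA", "CB")))
  s <- simulateFixture(sp, noiseSd = 0.02, seed = 31)   # SNR 50
  fit <- fitMixture(s, fullRoi(s), k = 3,
                    fitConstraints(initialGuesses = cbind(
                      c(55.1, 52.3, 50.8), c(18.5, 18.9, 23.3))),
                    seed = 31)
  got <- fitComponents(fit)
  ord <- order(got$center1, decreasing = TRUE)
  expect_equal(got$fraction[ord], c(0.28, 0.34, 0.38), tolerance = 0.03)
  expect_equal(got$center2[ord], c(18.5, 18.9, 23.3), tolerance = 0.2)
})

test_that("analytic component integrals match brute-force pixel sums", {
  set.seed(4)
  ax <- ppmAxisCovering("13C", 0, 40)  # wide grid, 0.1 ppm
  x <- ppmValues(ax)
  for (i in 1:10) {
    c1 <- runif(1, 15, 25); c2 <- runif(1, 15, 25)
    fw1 <- runif(1, 1.5, 6); fw2 <- runif(1, 1.5, 6)
    a <- runif(1, 0.5, 3)
    sg1 <- fw1 / 2.3548200450309493; sg2 <- fw2 / 2.3548200450309493
    G <- a * outer(exp(-(x - c2)^2 / (2 * sg2^2)),
                   exp(-(x - c1)^2 / (2 * sg1^2)))
    brute <- sum(G) * 0.01
    expect_equal(gaussianIntegral2D(a, fw1, fw2) / brute, 1,
                 tolerance = 0.005)
  }
})

test_that("BIC selects the generating component count", {
  one <- singleGaussianSpectrum(fwhm = c(3, 3), noiseSd = 0.01, seed = 5)
  sel1 <- selectK(one, fullRoi(one), fitConstraints(kRange = 1:3),
                  seed = 5)
  expect_equal(sel1$kSelected, 1L)

  sp3 <- syntheticSpec(data.frame(
    center1 = c(47, 53, 50), center2 = c(47, 53, 44),
    fwhm1 = 2.5, fwhm2 = 2.5, fraction = c(0.35, 0.35, 0.3)),
    noiseSd = 0.02)
  s3 <- simulateCrosspeak(sp3, ppmAxisCovering("13C", 38, 62),
                          ppmAxisCovering("13C", 38, 62), seed = 6)
  sel3 <- selectK(s3, fullRoi(s3), fitConstraints(kRange = 1:4), seed = 6)
  expect_equal(sel3$kSelected, 3L)
  expect_true(all(diff(sel3$summary$rss) <= 1e-8))  # nested fits improve
})

test_that("a flat-noise ROI is flagged degenerate", {
  ax <- ppmAxisCovering("13C", 40, 60)
  set.seed(8)
  flat <- spectrum2D(matrix(rnorm(length(ppmValues(ax))^2, sd = 1),
                            ax@n, ax@n), ax, ax)
  sel <- selectK(flat, roiWindow(c(45, 55), c(45, 55)),
                 fitConstraints(kRange = 1:2), seed = 8)
  expect_true(sel$degenerate)
  expect_true(is.na(sel$kSelected))
})

test_that("diagonal pairing is exact on symmetric spectra", {
  sp <- syntheticSpec(data.frame(
    center1 = c(47, 50), center2 = c(53, 56), fwhm1 = 2.5, fwhm2 = 2.5,
    fraction = c(0.6, 0.4)))
  ax <- testAxis(40, 62)
  s <- simulateFullSpectrum(list(sp), ax)
  expect_equal(intensityMatrix(s), t(intensityMatrix(s)))
  pair <- fitDiagonalPair(s, roiWindow(c(42, 54), c(48, 61)), k = 2,
                          seed = 10, residue = "A", atoms = c("CA", "CB"))
  m <- matchedComponents(pair)
  # identical numeric problems above and below: sd is exactly zero
  expect_identical(m$fractionAbove, m$fractionBelow)
  expect_identical(m$fractionSd, c(0, 0))
})

test_that("pair statistics follow the two-value mean/sd oracle", {
  # sd of two values a, b is |a - b|/sqrt(2); mean is (a + b)/2
  expect_equal(abs(0.40 - 0.36) / sqrt(2), 0.02828427, tolerance = 1e-7)
  # construct an asymmetric spectrum: 0.40/0.60 above, 0.36/0.64 below
  ax <- testAxis(40, 62)
  x <- ppmValues(ax)
  mk <- function(f1, c1 = c(47, 53), c2 = c(50, 56)) {
    .cg <- function(cx, cy, f) {
      sg <- 2.5 / 2.3548
      f / (2 * pi * sg^2) * outer(exp(-(x - cy)^2 / (2 * sg^2)),
                                  exp(-(x - cx)^2 / (2 * sg^2)))
    }
    .cg(c1[1], c1[2], f1) + .cg(c2[1], c2[2], 1 - f1)
  }
  above <- mk(0.40)
  below <- t(mk(0.36))
  s <- spectrum2D(above + below, ax, ax)
  pair <- fitDiagonalPair(s, roiWindow(c(42, 54), c(48, 61)), k = 2,
                          seed = 11)
  m <- matchedComponents(pair)
  i <- which.min(abs(m$center1 - 47))
  expect_equal(m$fractionMean[i], 0.38, tolerance = 0.005)
  expect_equal(m$fractionSd[i], 0.0283, tolerance = 0.003)
})

test_that("cross-diagonal matching errors on unmatched components", {
  ax <- testAxis(40, 62)
  x <- ppmValues(ax)
  sg <- 2 / 2.3548
  g <- function(cx, cy) outer(exp(-(x - cy)^2 / (2 * sg^2)),
                              exp(-(x - cx)^2 / (2 * sg^2)))
  # above-diagonal peak at (48, 58); the below-diagonal peak sits at
  # (54, 44), i.e. (44, 54) after the axis swap: 5.7 ppm off its partner
  s <- spectrum2D(g(48, 58) + g(54, 44), ax, ax)
  expect_error(
    fitDiagonalPair(s, roiWindow(c(43, 51), c(53, 61)), k = 1, seed = 1),
    "no below-diagonal counterpart")
})

test_that("heteronuclear spectra have no diagonal to mask or pair", {
  s <- singleGaussianSpectrum()   # axes 13C-CA vs 13C-CB share a family
  het <- s
  het@axis2@label <- "15N"
  expect_error(maskDiagonal(het, 2), "heteronuclear")
  expect_error(fitDiagonalPair(het, roiWindow(c(50, 56), c(15, 21)), k = 1),
               "homonuclear")
})

test_that("diagonal masking follows the Gaussian band-integral oracle", {
  ax <- testAxis(40, 60)
  onDiag <- syntheticSpec(data.frame(center1 = 50, center2 = 50,
                                     fwhm1 = 2, fwhm2 = 2, fraction = 1))
  s <- simulateCrosspeak(onDiag, ax, ax)
  expect_identical(fitMask(maskDiagonal(s, 0)), fitMask(s))
  masked <- maskDiagonal(s, 2)
  keptFrac <- sum(intensityMatrix(masked)[fitMask(masked)]) /
    sum(intensityMatrix(s))
  # oracle: X - Y ~ N(0, 2 sigma^2); P(|X - Y| < 2) masked
  sg <- 2 / 2.3548
  oracle <- 1 - (pnorm(2, 0, sqrt(2) * sg) - pnorm(-2, 0, sqrt(2) * sg))
  expect_lt(abs(keptFrac - oracle), 0.02)
  expect_gt(1 - keptFrac, 0.5)

  off <- syntheticSpec(data.frame(center1 = 47, center2 = 53, fwhm1 = 2,
                                  fwhm2 = 2, fraction = 1))
  so <- simulateCrosspeak(off, ax, ax)
  mo <- maskDiagonal(so, 2)
  lostFrac <- 1 - sum(intensityMatrix(mo)[fitMask(mo)]) /
    sum(intensityMatrix(so))
  # tail oracle: center 6 ppm from the diagonal
  oracleLost <- pnorm(2, 6, sqrt(2) * sg) - pnorm(-2, 6, sqrt(2) * sg)
  expect_equal(lostFrac, oracleLost, tolerance = 0.005)
  expect_lt(lostFrac, 0.01)
})

test_that("masked pixels are excluded from fitting", {
  ax <- testAxis(40, 60)
  sp <- syntheticSpec(data.frame(center1 = 46, center2 = 54, fwhm1 = 2.5,
                                 fwhm2 = 2.5, fraction = 1))
  s <- simulateCrosspeak(sp, ax, ax)
  # corrupt the diagonal band, then mask it: fit should still be clean
  bad <- abs(outer(ppmValues(ax), ppmValues(ax), "-")) < 1.5
  s@intensity[bad] <- s@intensity[bad] + 0.05
  fit0 <- fitMixture(s, fullRoi(s), k = 1, seed = 3)
  fitM <- fitMixture(maskDiagonal(s, 2), fullRoi(s), k = 1, seed = 3)
  expect_equal(fitComponents(fitM)$center1, 46, tolerance = 0.05)
  expect_lt(abs(fitComponents(fitM)$fwhm1 - 2.5),
            abs(fitComponents(fit0)$fwhm1 - 2.5) + 1e-9)
})

test_that("fit reports round-trip through TSV", {
  s <- singleGaussianSpectrum(fwhm = c(3, 3))
  fit <- fitMixture(s, fullRoi(s), k = 1, seed = 1)
  path <- tempfile(fileext = ".tsv")
  writeFitReport(fit, path)
  rep <- readFitReport(path)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$fraction, 1)
  expect_equal(rep$center1_ppm, fitComponents(fit)$center1)
})
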