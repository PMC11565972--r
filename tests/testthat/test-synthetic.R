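test_that("noiseless simulation peaks at the component center", {
  s <- singleGaussianSpectrum(center = c(53, 18.5), fwhm = c(3, 3))
  I <- intensityMatrix(s)
  pk <- which(I == max(I), arr.ind = TRUE)
  expect_equal(ppmValues(directAxis(s))[pk[1, "col"]], 53,
               tolerance = 0.051)
  expect_equal(ppmValues(indirectAxis(s))[pk[1, "row"]], 18.5,
               tolerance = 0.051)
  expect_equal(integrateSpectrum(s), 1, tolerance = 1e-3)
})

test_that("the monomer fixture is two-lobed and seeds control noise only", {
  fx <- crossPeakFixtures()$ala_monomer
  s1 <- simulateFixture(fx, noiseSd = 0.02, seed = 1)
  s2 <- simulateFixture(fx, noiseSd = 0.02, seed = 2)
  s1b <- simulateFixture(fx, noiseSd = 0.02, seed = 1)
  expect_false(identical(intensityMatrix(s1), intensityMatrix(s2)))
  expect_identical(intensityMatrix(s1), intensityMatrix(s1b))
  expect_identical(s1@metadata$ground_truth, s2@metadata$ground_truth)
  # two resolved lobes along the CA axis at the CB rows of the two centers
  s0 <- simulateFixture(fx)
  sl <- extractSlice(s0, "axis1", at = 18.9)
  peaks <- sl$ppm[sl$intensity > 0.5]
  expect_gt(diff(range(peaks)), 2)
})

test_that("components outside the axes are rejected", {
  sp <- syntheticSpec(data.frame(center1 = 80, center2 = 18, fwhm1 = 3,
                                 fwhm2 = 3, fraction = 1))
  expect_error(simulateCrosspeak(sp, ppmAxisCovering("13C", 45, 60),
                                 ppmAxisCovering("13C", 10, 26)),
               "outside the axes")
})

test_that("fixture set carries the twelve reported decompositions", {
  fx <- crossPeakFixtures()
  expect_setequal(names(fx), c(
    "ala_coil", "ala_urea", "ala_monomer", "ala_fibril",
    "gly_coil", "gly_urea", "gly_monomer", "gly_fibril",
    "leu_coil", "leu_urea", "leu_monomer", "leu_fibril"))
  kTruth <- c(ala_coil = 4, ala_urea = 1, ala_monomer = 2, ala_fibril = 3,
              gly_coil = 1, gly_urea = 1, gly_monomer = 3, gly_fibril = 3,
              leu_coil = 4, leu_urea = 1, leu_monomer = 2, leu_fibril = 3)
  for (nm in names(fx)) {
    gt <- groundTruth(fx[[nm]])
    expect_equal(nrow(gt), unname(kTruth[nm]), info = nm)
    expect_equal(sum(gt$fraction), 1, tolerance = 1e-9, info = nm)
  }
  # spot checks against the reported values
  expect_equal(groundTruth(fx$ala_fibril)$fraction,
               c(28, 34, 38) / 100, tolerance = 1e-9)
  expect_equal(groundTruth(fx$ala_urea)[, c("center1", "center2",
                                            "fwhm1", "fwhm2")],
               data.frame(center1 = 52.4, center2 = 18.5, fwhm1 = 4,
                          fwhm2 = 4))
  expect_equal(groundTruth(fx$leu_urea)$fwhm1, 3)
  expect_equal(groundTruth(fx$leu_urea)$fwhm2, 4)
  expect_equal(groundTruth(fx$gly_fibril)$center2,
               c(177.5, 173.7, 170.6))
})

test_that("noiseless fixture fits recover every generating parameter", {
  # round-trip at the solver tolerance: centers 0.05 ppm, fractions 0.01
  fx <- crossPeakFixtures()
  for (nm in c("ala_monomer", "gly_fibril", "leu_coil")) {
    truth <- groundTruth(fx[[nm]])
    s <- simulateFixture(fx[[nm]])
    fit <- fitMixture(s, fullRoi(s), k = nrow(truth),
                      fitConstraints(initialGuesses =
                        cbind(truth$center1, truth$center2)),
                      seed = 1)
    got <- fitComponents(fit)
    ord <- sapply(seq_len(nrow(truth)), function(i)
      which.min((got$center1 - truth$center1[i])^2 +
                  (got$center2 - truth$center2[i])^2))
    expect_equal(got$center1[ord], truth$center1, tolerance = 0.05,
                 info = nm)
    expect_equal(got$center2[ord], truth$center2, tolerance = 0.05,
                 info = nm)
    expect_equal(got$fraction[ord], truth$fraction, tolerance = 0.01,
                 info = nm)
  }
})

test_that("fraction-recovery error grows with the noise level", {
  fx <- crossPeakFixtures()$ala_monomer
  truth <- groundTruth(fx)
  err <- sapply(c(0.01, 0.05, 0.15), function(ns) {
    median(sapply(1:7, function(s) {
      sp <- simulateFixture(fx, noiseSd = ns, seed = 100 + s)
      fit <- fitMixture(sp, fullRoi(sp), k = 2,
                        fitConstraints(initialGuesses =
                          cbind(truth$center1, truth$center2)),
                        seed = s)
      max(abs(sort(fractions(fit)) - sort(truth$fraction)))
    }))
  })
  expect_true(all(diff(err) > 0))
})

test_that("symmetric full spectra are exactly transpose-symmetric", {
  ax <- testAxis(40, 62)
  sp <- syntheticSpec(data.frame(center1 = c(46, 49), center2 = c(54, 58),
                                 fwhm1 = c(2, 3), fwhm2 = c(3, 2),
                                 fraction = c(0.6, 0.4)))
  s <- simulateFullSpectrum(list(sp), ax,
                            diagonal = list(amplitude = 0.05, width = 1))
  expect_equal(intensityMatrix(s), t(intensityMatrix(s)),
               tolerance = 1e-12)
})

test_that("a diagonal-only spectrum is almost fully masked at 2 ppm", {
  ax <- testAxis(40, 62)
  s <- simulateFullSpectrum(list(), ax,
                            diagonal = list(amplitude = 1, width = 1))
  m <- maskDiagonal(s, 2)
  kept <- sum(intensityMatrix(m)[fitMask(m)]) / sum(intensityMatrix(m))
  expect_lt(kept, 0.05)
})

test_that("diagonal-pair estimates are unbiased on mirrored noisy spectra", {
  ax <- ppmAxisCovering("13C", 42, 62, 0.2)  # coarse grid for speed
  sp <- syntheticSpec(data.frame(center1 = c(46, 49), center2 = c(54, 58),
                                 fwhm1 = 2.5, fwhm2 = 2.5,
                                 fraction = c(0.6, 0.4)))
  nrep <- 40
  est <- sapply(seq_len(nrep), function(r) {
    s <- simulateFullSpectrum(list(sp), ax, noiseSd = 0.03,
                              seed = 5000 + r)
    pair <- fitDiagonalPair(s, roiWindow(c(43, 52), c(51, 61)), k = 2,
                            constraints = fitConstraints(initialGuesses =
                              rbind(c(46, 54), c(49, 58))),
                            seed = r)
    m <- matchedComponents(pair)
    m$fractionMean[which.min(abs(m$center1 - 46))]
  })
  se <- sd(est) / sqrt(nrep)
  expect_lt(abs(mean(est) - 0.6), 3 * se + 0.005)
})
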