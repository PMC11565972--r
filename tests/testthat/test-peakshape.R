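test_that("a single shift pair yields a single Gaussian of the kernel FWHM", {
  ax1 <- ppmAxisCovering("13C-CA", 45, 61)
  ax2 <- ppmAxisCovering("13C-CB", 10, 26)
  s <- buildCrosspeak(cbind(53.0, 18.0), ax1, ax2,
                      broadening = broadening(1.5, 1.5))
  I <- intensityMatrix(s)
  x <- ppmValues(directAxis(s)); y <- ppmValues(indirectAxis(s))
  pk <- which(I == max(I), arr.ind = TRUE)
  expect_equal(x[pk[1, "col"]], 53.0, tolerance = 0.051)
  expect_equal(y[pk[1, "row"]], 18.0, tolerance = 0.051)
  # closed-form oracle: unit-integral 2D Gaussian at (53, 18), FWHM 1.5
  sg <- 1.5 / (2 * sqrt(2 * log(2)))
  oracle <- outer(dnorm(y, 18, sg), dnorm(x, 53, sg))
  expect_lt(max(abs(I - oracle)) / max(oracle), 0.01)
  # integral equals the conformer count
  expect_equal(integrateSpectrum(s), 1, tolerance = 1e-3)
})

test_that("two resolved pairs give two equal-integral lobes (closed form)", {
  ax <- ppmAxisCovering("13C", 40, 60)
  s <- buildCrosspeak(rbind(c(47, 50), c(53, 50)), ax, ax,
                      broadening = broadening(1.5, 1.5))
  sg <- 1.5 / (2 * sqrt(2 * log(2)))
  x <- ppmValues(ax)
  oracle <- outer(dnorm(x, 50, sg), dnorm(x, 47, sg)) +
    outer(dnorm(x, 50, sg), dnorm(x, 53, sg))
  expect_lt(max(abs(intensityMatrix(s) - oracle)) / max(oracle), 0.01)
  left <- integrateSpectrum(s, roiWindow(c(40, 50), c(40, 60)))
  right <- integrateSpectrum(s, roiWindow(c(50.1, 60), c(40, 60)))
  expect_equal(left, right, tolerance = 0.01)
})

test_that("integral is proportional to conformer count and errors fire", {
  ax <- ppmAxisCovering("13C", 40, 60)
  sh <- cbind(runif(50, 45, 55), runif(50, 45, 55))
  s50 <- buildCrosspeak(sh, ax, ax)
  s25 <- buildCrosspeak(sh[1:25, ], ax, ax)
  expect_equal(integrateSpectrum(s50) / integrateSpectrum(s25), 2,
               tolerance = 0.02)
  expect_error(buildCrosspeak(cbind(100, 50), ax, ax), "outside the grid")
  expect_warning(
    buildCrosspeak(rbind(c(100, 50), c(50, 50)), ax, ax,
                   outOfRange = "clip"), "clipping")
  expect_error(buildCrosspeak(matrix(numeric(0), 0, 2), ax, ax),
               "at least one row")
})

test_that("axis-swapped build equals the transpose", {
  ax1 <- ppmAxisCovering("13C-CA", 45, 61)
  ax2 <- ppmAxisCovering("13C-CB", 10, 26)
  sh <- cbind(runif(40, 48, 58), runif(40, 14, 22))
  a <- buildCrosspeak(sh, ax1, ax2)
  b <- buildCrosspeak(sh[, 2:1], ax2, ax1)
  expect_equal(intensityMatrix(b), t(intensityMatrix(a)),
               tolerance = 1e-12)
})

test_that("normalization is exact, idempotent and scale invariant", {
  s <- singleGaussianSpectrum()
  n1 <- normalizeIntegral(s)
  expect_equal(integrateSpectrum(n1), 1, tolerance = 1e-9)
  expect_equal(intensityMatrix(normalizeIntegral(n1)),
               intensityMatrix(n1), tolerance = 1e-12)
  s10 <- s
  s10@intensity <- s@intensity * 10
  expect_equal(intensityMatrix(normalizeIntegral(s10)),
               intensityMatrix(n1), tolerance = 1e-12)
  zero <- spectrum2D(matrix(0, 5, 5), ppmAxis("13C", 0, 1, 5),
                     ppmAxis("13C", 0, 1, 5))
  expect_error(normalizeIntegral(zero), "zero total integral")
})

test_that("intensity matching computes the exact quotient factor", {
  ref <- singleGaussianSpectrum()
  roi <- roiWindow(c(48, 58), c(13, 24))
  same <- matchIntensity(ref, ref, roi)
  expect_equal(same$factor, 1.0, tolerance = 1e-12)
  twice <- ref; twice@intensity <- ref@intensity * 2
  expect_equal(matchIntensity(ref, twice, roi)$factor, 0.5,
               tolerance = 1e-12)
  # direct quotient: reference 10, target 5 -> factor 2, and the scaled
  # target's ROI integral matches the reference's to 1e-9 relative
  refInt <- integrateSpectrum(ref, roi)
  half <- ref; half@intensity <- ref@intensity * 0.5
  m <- matchIntensity(ref, half, roi)
  expect_equal(m$factor, 2.0, tolerance = 1e-12)
  expect_equal(integrateSpectrum(m$scaled, roi) / refInt, 1,
               tolerance = 1e-9)
  zero <- ref; zero@intensity <- ref@intensity * 0
  expect_error(matchIntensity(ref, zero, roi), "target ROI integral")
})

test_that("slices follow the Gaussian closed form and peak-normalize", {
  s <- singleGaussianSpectrum(center = c(53, 18.5), fwhm = c(3, 3))
  sl <- extractSlice(s, "axis1", at = 18.5)
  expect_equal(max(sl$intensity), 1)
  # slice through the center keeps the FWHM of the component
  half <- sl$ppm[sl$intensity >= 0.5]
  expect_equal(diff(range(half)), 3, tolerance = 0.15)
  # Gaussian closed form: the raw row at center + FWHM/2 is half the
  # center row, so its peak-normalized slice still peaks at the center col
  I <- intensityMatrix(s)
  y <- ppmValues(indirectAxis(s)); x <- ppmValues(directAxis(s))
  ratio <- I[which.min(abs(y - 20)), which.min(abs(x - 53))] /
    I[which.min(abs(y - 18.5)), which.min(abs(x - 53))]
  expect_equal(ratio, 0.5, tolerance = 0.02)
  sl2 <- extractSlice(s, "axis1", at = 20)
  expect_equal(sl2$ppm[which.max(sl2$intensity)], 53, tolerance = 0.051)
  expect_error(extractSlice(s, "axis1", at = 99), "outside axis")
})

test_that("broadening never increases a normalized spectrum's maximum", {
  ax <- ppmAxisCovering("13C", 40, 60)
  sh <- cbind(runif(30, 45, 55), runif(30, 45, 55))
  prev <- Inf
  for (fw in c(1, 1.5, 2.5, 4)) {
    s <- normalizeIntegral(buildCrosspeak(sh, ax, ax,
                                          broadening = broadening(fw)))
    expect_lte(max(intensityMatrix(s)), prev + 1e-12)
    prev <- max(intensityMatrix(s))
  }
})

test_that("descending axes are flipped to ascending storage", {
  desc <- ppmAxis("13C", 60, -0.5, 41)
  I <- matrix(seq_len(41 * 3), 3, 41)
  s <- spectrum2D(I, desc, ppmAxis("13C", 0, 1, 3))
  expect_gt(directAxis(s)@step, 0)
  expect_equal(ppmValues(directAxis(s))[1], 40)
  expect_equal(intensityMatrix(s)[, 1], I[, 41])
})

test_that("spectra round-trip through the portable text format", {
  s <- singleGaussianSpectrum()
  s <- maskDiagonal(spectrum2D(intensityMatrix(s)[1:60, 1:60],
                               ppmAxisCovering("13C", 45, 50.9),
                               ppmAxisCovering("13C", 10, 15.9),
                               metadata = list(note = "fixture")), 0.5)
  stem <- tempfile()
  writeSpectrum2D(s, stem)
  s2 <- readSpectrum2D(stem)
  expect_equal(intensityMatrix(s2), intensityMatrix(s), tolerance = 1e-9)
  expect_identical(fitMask(s2), fitMask(s))
  expect_equal(ppmValues(directAxis(s2)), ppmValues(directAxis(s)))
  expect_identical(s2@metadata$note, "fixture")
})
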