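# Shared test fixtures, built in code.

# small symmetric homonuclear axes around 50 ppm
testAxis <- function(from = 40, to = 60, step = 0.1, label = "13C") {
  ppmAxisCovering(label, from, to, step)
}

# a quick one-component spectrum
singleGaussianSpectrum <- function(center = c(53, 18.5), fwhm = c(3, 3),
                                   noiseSd = 0, seed = NULL) {
  sp <- syntheticSpec(data.frame(center1 = center[1], center2 = center[2],
                                 fwhm1 = fwhm[1], fwhm2 = fwhm[2],
                                 fraction = 1), noiseSd = noiseSd)
  simulateCrosspeak(sp, ppmAxisCovering("13C-CA", 45, 60),
                    ppmAxisCovering("13C-CB", 10, 26), seed = seed)
}

fullRoi <- function(spectrum) {
  roiWindow(range(ppmValues(directAxis(spectrum))),
            range(ppmValues(indirectAxis(spectrum))))
}

# tiny two-basin library for fast deterministic tests
toyLibrary <- function() {
  dihedralLibrary(data.frame(
    residue = "A",
    basin = c("alpha", "ppii_coil", "beta", "positive_phi"),
    phi0 = c(-63, -70, -130, 60), psi0 = c(-43, 145, 135, 45),
    sphi = c(10, 10, 10, 10), spsi = c(10, 10, 10, 10),
    weight = c(0.3, 0.4, 0.2, 0.1)))
}
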