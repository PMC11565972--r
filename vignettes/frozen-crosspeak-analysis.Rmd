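---
title: "Quantifying disordered-region ensembles from frozen-state 2D cross-peak shapes"
author: "idpeaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying disordered-region ensembles from frozen-state 2D cross-peak shapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpeaks)
```

## The measurement model

When a disordered polypeptide is frozen, conformational exchange stops and
every conformer contributes intensity at its own chemical shift. A 2D
homonuclear cross-peak (for example the alanine Calpha--Cbeta correlation of
a DARR spectrum) therefore becomes a population-weighted map of the backbone
conformational ensemble: helix-like conformers resonate near the helical
shift pair, extended conformers near the strand pair, and the peak shape as
a whole is the ensemble's shift distribution convolved with the residual
line width. `idpeaks` implements the full analysis built on that fact:

1. **Statistical-coil reference.** A host--guest peptide (poly-alanine with
   the residue of interest at the centre) is sampled from a coil library,
   shifts are predicted per conformer, and the predicted 2D peak shape is
   the reference against which experimental shapes are compared.
2. **Gaussian decomposition.** Cross-peaks are decomposed into one to four
   axis-aligned 2D Gaussians under "constrained peak motion" bounds, fitted
   independently above and below the spectral diagonal.
3. **Class populations.** Each fitted component is assigned to a
   conformational class (alpha-helix, random coil, beta-strand,
   positive-phi) through reference shift windows, and component integrals
   become class populations with a two-fit error bar.

## The coil library

The library (`defaultDihedralLibrary()`) represents each residue type's
backbone preferences as a mixture of wrapped bivariate Gaussians over
(phi, psi), one per Ramachandran basin:

```{r}
basinTable(defaultDihedralLibrary(), "A")
```

Basin centres are canonical centroids — alpha (-63, -43), beta (-130, 135),
polyproline-II/extended coil (-70, 145), positive-phi (60, 45) — and are
configuration, not fitted quantities. Basin *weights* are the calibration
knobs of the package: they were chosen once so that the complete chain
(sampling, shift prediction, broadening, constrained fitting,
classification) reproduces the reference statistical-coil decompositions
for alanine (16/60/15/8 % alpha/coil/beta/positive-phi), leucine
(8/64/21/7 %) and glycine (a single broad Gaussian at 44.7/174.2 ppm,
FWHM ~3 ppm), and then frozen. Two calibration details deserve note:

* The alanine weights are 15/62/15/8 rather than 16/60/15/8. Fitting four
  overlapping ~2.4 ppm Gaussians transfers a small, systematic amount of
  apparent population from the dominant coil component to its helical
  neighbour; the weights compensate so the *fitted* populations land on
  16/60/15/8. The calibration target is the decomposition a user obtains,
  not the latent sampling weights.
* The glycine weights (18/49/18/15) are deliberately more even than the
  alanine-like ones. Glycine's accessible Ramachandran area is much larger
  (including substantial positive-phi occupancy), and the even weights make
  its predicted Calpha--CO cross-peak collapse into one broad Gaussian
  rather than resolved sub-peaks, which is the observed statistical-coil
  behaviour for this residue.

Sampling treats residues independently (no nearest-neighbour dihedral
coupling): host--guest analysis only ever reads the central guest residue,
and inter-residue coupling is outside the model. The host--guest length
default is 11 with the guest central; the analysis is insensitive to this
choice because only the guest's dihedrals are consumed, and it is exposed
as a parameter (`hostLength`).

## The shift surface

`predictShift()` maps (phi, psi) to a Calpha/Cbeta/CO shift by blending
basin-specific anchor shifts with normalized periodic-Gaussian kernel
weights centred on the basin centroids. The surface is 360-degree periodic,
continuous, and convex in the anchors (every prediction lies within the
anchor range); with well-separated basins it equals each anchor at its
centroid. Anchors for Ala/Gly/Leu carry the statistical-coil basin shift
values the pipeline is calibrated to; Ser/Thr anchors and all
positive-phi values without a calibrated counterpart are configuration
constants in the style of secondary-shift compilations.

Two numerical choices matter here:

* **Kernel width, default 15 degrees.** Narrower kernels keep each sampled
  conformer's shift close to its own basin anchor, which minimises the
  skew that basin-boundary blending introduces into fitted populations.
  Widths of 20--25 degrees raise the apparent helical population of the
  alanine decomposition by 1--3 percentage points purely through blending
  leakage; 15 degrees keeps that distortion below the sampling noise.
* **Residual shift dispersion, default 1.8 ppm FWHM.** A four-anchor
  blending surface is locally flat inside each basin, so on its own it
  produces essentially zero within-basin shift variability — fitted
  components would have the bare 1.5 ppm broadening width, and glycine's
  cross-peak would be a cluster of narrow spikes instead of one broad
  peak. Residue-level shift predictors vary smoothly *within* basins; the
  pipeline models that missing variability as an additional Gaussian
  width composed in quadrature with the homogeneous 1.5 ppm line
  broadening (`coilCrossPeak(fwhm = 1.5, shiftDispersion = 1.8)`),
  giving an effective per-conformer kernel of ~2.3 ppm. With it, fitted
  statistical-coil components come out at ~2.4 ppm FWHM and the glycine
  single-Gaussian fit at ~3.0 ppm, matching the reference decompositions.
  The histogram-plus-1.5-ppm-broadening contract of `buildCrosspeak()`
  itself is unchanged; `shiftDispersion = 0` recovers it.

## Peak-shape construction

`buildCrosspeak()` bins per-conformer shift pairs onto a 0.1 ppm grid and
convolves with a separable Gaussian kernel (equivalent to summing one
kernel per conformer). The Riemann integral equals the conformer count up
to kernel mass truncated at the grid edge, which is negligible on the
default axes (random-coil anchor +/- 8 ppm). Axes are stored ascending;
descending input axes are flipped on construction. Out-of-grid shifts are
an error by default and can be clipped with a warning
(`outOfRange = "clip"`), which the coil pipeline uses since a 10,000-point
tail can graze the grid edge. `normalizeIntegral()` and
`matchIntensity()` implement unit-integral normalization and
reference-ROI intensity matching; `extractSlice()` produces the
peak-normalized 1D slices used for overlay comparisons.

## Constrained mixture decomposition

`fitMixture()` minimises the pixel least-squares misfit of k axis-aligned
2D Gaussians over an ROI with `optim(method = "L-BFGS-B")` and analytic
gradients. "Constrained peak motions" is operationalized as bounds:
centres may move at most `centerBound` (default 1.0 ppm) from their
initial guesses, FWHMs are confined to 0.5--8 ppm, amplitudes are
non-negative. Initial guesses default to greedy peak picking with
subtraction (take the maximum of the lightly smoothed ROI, subtract a
working-width Gaussian, repeat), which exposes shoulders of merged lobes;
user-supplied guesses — the analyst's expected peak positions — override
this, mirroring interactive peak-fitting practice. A seeded multistart
jitters the guesses and keeps the best residual; non-convergence is
flagged, never silent. Populations are analytic component integrals
(`amplitude * pi * fwhm1 * fwhm2 / (4 ln 2)`) normalized to sum to one.

Model-order selection (`selectK()`) is by BIC over the admissible k range,
with per-k residuals reported so a user can override; k can always be
forced, matching fixed per-peak component counts. A flat-noise ROI
(maximum under five times the border-pixel MAD noise floor) is flagged
degenerate. The fit is axis-aligned by design — the reported
(centre, FWHM) parameterization has no rotation term — and Lorentzian or
Voigt shapes are out of scope.

`fitDiagonalPair()` fits the two symmetry-related images of a homonuclear
cross-peak to the same number of Gaussians: the stored orientation for the
above-diagonal image and the transposed spectrum for the below-diagonal
one, so a perfectly symmetric spectrum yields bitwise-identical problems
and an exactly zero error bar. Components are matched across the diagonal
by nearest swapped centre with a 1.5 ppm gate (reference decompositions
are separated by at least that much in one dimension), and each matched
population is reported as mean +/- sample SD of the two independent
estimates, `|p_above - p_below| / sqrt(2)` — the n-1 convention for two
values. `maskDiagonal()` removes a |delta1 - delta2| band from the fit
weighting for peaks that merge with the diagonal ridge (the Ser/Thr
situation); intensities are untouched and the mask is recorded in
metadata.

## Classification and reporting

`classifyComponent()` computes, for each class window, the normalized
distance `max over atoms of |centre - mean| / sd` and assigns the minimal
class when that distance is at most 2 (inside the +/- 2 SD window on both
axes). The positive-phi class has an anchor point and proximity radius
(1.5 ppm) rather than a tabulated SD, and applies to components inside no
standard window. A component outside every window whose only violations
are excursions *beyond the beta-strand mean in the extended-shift
direction* is labelled beta with an `extremeBeta` flag — this is the
"highly extended strand" situation, where shifts sit past the edge of the
tabulated strand window — while any other out-of-window component is
`unclassified` with its nearest class recorded. Window means and SDs ship
as configuration (`defaultClassWindows()`, also in
`inst/extdata/class_windows.tsv`), aligned with the anchor table so that
statistical-coil components classify onto their generating basins.
`buildPopulationReport()` sums fractions per class within each condition,
combines the two-fit SDs in quadrature, and reports percentages that sum
to 100 per condition.

## The synthetic-data generator

`simulateCrosspeak()` renders a specification (component centres, FWHMs,
fractions) as a unit-integral sum of 2D Gaussians plus seeded Gaussian
pixel noise, keeping the generating table as ground truth in the spectrum
metadata. `simulateFullSpectrum()` mirrors every cross-peak across the
diagonal of a homonuclear grid, optionally adds a Gaussian diagonal ridge,
and applies one independent noise field so the two sides carry independent
realizations. `crossPeakFixtures()` packages twelve reference
decompositions (statistical coil, 8 M urea, frozen monomer in buffer and
fibril-flank conditions for Ala, Gly and Leu). What the generator emulates
is the *statistical* structure the analysis assumes — Gaussian components,
symmetric mirrored peaks, white pixel noise, a Gaussian ridge. It does not
emulate correlated (apodization-coloured) noise, asymmetric lineshapes,
spinning sidebands, cross-peak overlap from other residue types, or
baseline distortions; passing recovery tests therefore validates the
estimator under its own assumptions, not robustness to every artefact of
real spectra. Fixture noise defaults (1--5 % of the maximum) are choices,
as experimental noise levels are not tabulated.

## Problem sizes and numerical conventions

The packaged analyses use 10,000-conformer ensembles on 0.1 ppm grids
(about 160 x 160 pixels per cross-peak window), the scale at which the
statistical-coil populations are stable to a few tenths of a percentage
point between seeds; recovery simulations in the test-suite use 25-seed
medians at 5 % pixel noise and 100-replicate bias checks on 0.2 ppm grids.
Angles are IUPAC phi/psi in degrees stored in [-180, 180); FWHM relates to
the Gaussian sigma by `fwhm = 2 sqrt(2 ln 2) sigma`; fractions are kept as
proportions internally and reported as percentages. Ties in classification
cannot occur for generic inputs (distances are continuous); the
first-minimum convention applies to exact ties.

## Known limitations

* The shift surface is a four-anchor interpolation: it reproduces
  basin-level shift statistics but not sequence-context, ring-current or
  hydrogen-bond effects, and its within-basin variability is a single
  isotropic dispersion parameter rather than a learned gradient field.
* Populations from heavily overlapped components (separations well under
  one FWHM) are fundamentally ill-determined; the constrained fit reports
  a solution, and the diagonal-pair SD understates uncertainty in that
  regime because both fits share the same degeneracy.
* Serine/threonine support covers sampling, prediction and masking near
  the diagonal, but no calibrated acceptance surface exists for them:
  their anchors and windows are reference-compilation constants.
* The two-fit error bar captures noise and fit-start variability between
  the two diagonal images, not calibration error in the library, anchors
  or windows.
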