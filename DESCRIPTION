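Package: idpeaks
Title: Conformational Ensembles of Disordered Protein Regions from
    Frozen-State 2D NMR Cross-Peak Shapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies conformational ensembles of intrinsically disordered
    protein regions from frozen-state two-dimensional NMR cross-peak shapes.
    Provides a statistical-coil dihedral sampler for host-guest peptides, a
    smooth periodic backbone-dihedral to carbon chemical-shift surface,
    construction of line-broadened 2D cross-peak shapes from conformational
    ensembles, constrained decomposition of cross-peaks into one to four
    axis-aligned 2D Gaussians with identical component counts above and below
    the spectral diagonal, chemical-shift-window classification of fitted
    components into alpha-helix, random-coil, beta-strand and positive-phi
    conformational classes, and per-condition population reports with
    diagonal-pair error estimates. A synthetic-spectrum generator with known
    ground truth supports end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
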