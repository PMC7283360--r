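Package: saxsphase
Title: Shape Invariants, Phase Classification and Lamellar-Stack Modelling
    for Nucleoprotein SAXS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for one-dimensional small-angle X-ray
    scattering (SAXS) profiles of nucleoprotein assemblies such as HU-DNA
    complexes. Computes model-free shape invariants (Guinier radius of
    gyration, cross-sectional Rg, Porod volume, volume of correlation),
    classifies profiles as lamellar, filament or aggregate phases from
    low-q power laws and Bragg diffraction peaks, fits a lamellar-stack
    Caille intensity model to extract DNA repeat spacings, performs
    regularized indirect Fourier transforms to pair-distance distribution
    functions, builds coarse bead models of B-DNA duplexes, HU-decorated
    filaments and parallel-DNA bundles, computes their Debye-formula
    scattering profiles, and selects minimal weighted ensembles against
    data. Includes a seeded synthetic-data generator encoding a pH by
    ionic-strength phase diagram for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
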