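Package: mrvf
Title: MR Vascular Fingerprinting: Voxel-Scale Simulation, Dictionaries
    and Matching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates multi-echo GESFIDE MR signals from virtual voxels
    containing cylindrical blood vessels, builds fingerprint dictionaries
    over grids of blood volume fraction, vessel radius, blood oxygen
    saturation, water diffusion and vessel orientation, and matches
    pre/post-contrast echo volumes against those dictionaries to produce
    microvascular parametric maps. Also provides the analytic steady-state
    comparators (contrast-induced delta-R2/delta-R2*, steady-state blood
    volume fraction, vessel size index, and multiparametric quantitative
    BOLD oxygenation), NIfTI input/output, and a digital phantom generator
    with known microvascular ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    minpack.lm,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
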