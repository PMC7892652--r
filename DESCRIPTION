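Package: phantomAC
Title: Phantom-Specific MRI-Based Attenuation Correction for PET/MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for attenuation correction (AC)
    of PET/MRI phantom studies built from an MRI-visible polymer. Provides a
    parametric digital model of a cylindrical resolution phantom, a two-point
    Dixon MR and CT simulator, threshold/morphology segmentation of the Dixon
    images into water and housing-material mu-maps, construction of four
    competing AC maps (CT-based, phantom-specific MR, vendor-style soft-tissue
    MR, and a wall-less variant), an attenuated parallel-beam forward model
    with ordered-subsets expectation-maximization (OSEM) reconstruction, and a
    region-of-interest bias evaluation protocol against CT-based AC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    RNifti,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
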