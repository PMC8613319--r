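Package: phantoMAR
Title: Quantitative Metal Artifact Reduction Analysis for Hip Arthroplasty CT Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantitative analysis of metal artifact reduction (MAR)
    in computed tomography of total hip arthroplasty phantoms. Provides a seeded
    2-D CT physics simulator (parallel-beam forward projection, beam-hardening and
    photon-starvation corruption, filtered back projection, sinogram-inpainting MAR
    emulation and high-keV virtual monochromatic imaging emulation), standardized
    ROI-based image-quality measurement (mean HU, noise, SNR, CNR), pellet artifact
    categorization, normalized artifact deviation and relative metal artifact
    reduction metrics, and exact paired Wilcoxon signed-rank testing, orchestrated
    as a reproducible simulate-measure-categorize-compare pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
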