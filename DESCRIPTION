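Package: ktemap
Title: Joint k-Space and Echo-Time Reconstruction for Quantitative T2 Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs multi-echo T2-weighted MR images and the pixelwise T2
    map jointly from (possibly undersampled) Cartesian k-space data. The joint
    solver couples a k-space data-fidelity term with a mono-exponential
    echo-time decay self-consistency constraint and a plug-and-play image
    denoising prior, solved by the alternating direction method of multipliers
    (ADMM) with a weighted log-linear least-squares T2 update. Includes the
    conventional two-step fit, a compressed-sensing baseline with 1D total
    variation, a k-space-only ablation, a digital relaxometry vial phantom
    simulator, and ROI-based evaluation tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    rhdf5,
    EBImage,
    jsonlite,
    tibble,
    stats,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
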