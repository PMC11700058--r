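Package: osteotrack
Title: Longitudinal MicroCT Bone Remodelling, Morphometry, Raman and
    Bending Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies longitudinal bone remodelling from registered
    micro-computed tomography timepoints by voxel differencing, computes
    static trabecular and cortical morphometry (BV/TV, Tb.Th, Tb.N,
    Ct.Ar/Tt.Ar, TMD, section modulus), calibrates Hounsfield units and
    segments abdominal adipose tissue, preprocesses Raman spectra of
    embedded bone and derives seven compositional band-ratio parameters
    with line-scan distribution statistics, and extracts structural and
    material properties from three-point-bending load-displacement
    curves. Ships synthetic phantom, spectrum and curve generators with
    exact ground truth so every stage is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
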