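Package: vogq
Title: Single-Virion Quantification for Virus-on-Glass Fluorescence Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of virus-on-glass (VOG) single-virion
    fluorescence microscopy and companion infectivity readouts. Generates
    synthetic multi-channel image fields of diffraction-limited virions with
    exact ground truth and construct-dependent fluorophore stoichiometry
    (Gag-anchored vs Gag-Pol-anchored labeling), performs Richardson-Lucy
    deconvolution with a theoretical point-spread function, Z
    maximum-intensity projection, per-channel spot detection with sub-pixel
    centroids and mask-based features, reference-anchored nearest-neighbour
    colocalization at a 0.500 micrometer centroid threshold with a chance
    null, and flow-cytometry-style singlet gating, percent-positive
    computation, Kruskal-Wallis and Dunn rank comparisons, and p24-normalized
    luciferase summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    rlang,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
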