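Package: bromsi
Title: Bromine Isotope-Signature Screening for Mass Spectrometry Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for mapping brominated indole metabolites
    in gastrointestinal mass spectrometry imaging (MSI) data. Provides
    exact-mass chemistry and isotopic-distribution computation for molecular
    formulas and adduct ions, continuous-mode imzML input/output, spectral
    preprocessing (morphological TopHat baseline subtraction, total-ion-current
    preserving resampling, peak picking, quadratic external calibration against
    caesium iodide cluster references), probabilistic latent semantic analysis
    (pLSA) segmentation of the pixel-by-peak matrix into tissue-like regions,
    screening of peak lists for mono- and di-brominated isotope signatures with
    de-replication of lipid look-alikes, spatial co-localisation of candidate
    ion images, and annotation against a brominated-indole compound library.
    Includes a synthetic MSI phantom generator that emulates gut cross-section
    acquisitions with ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    xml2,
    yaml,
    jsonlite,
    png,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
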