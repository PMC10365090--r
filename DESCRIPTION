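Package: radiomix
Title: CT Radiomics and Radiogenomics Modelling of Immunotherapy Response
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end CT radiomics pipeline for predicting disease control
    under PD-1/PD-L1 checkpoint inhibition and HOT/COLD tumor immune status in
    non-small-cell lung cancer. Reads CT volumes and tumor segmentations
    (NIfTI-1 or a minimal DICOM series subset), resamples to an isotropic
    lattice, quantizes intensities with equal-probability thresholds, and
    extracts a pinned registry of 342 radiomic features (size, shape, moment
    invariants, skeleton and radial-distance descriptors, first-order
    statistics, GLCM/GLRLM/GLSZM/NGTDM texture matrices at seven gray-level
    counts, lacunarity, Gabor bank, Fourier rings, keypoint/gradient/LOSIB
    descriptors). Provides ReliefF and a relevancy-redundancy score for
    feature selection, a classifier grid (linear SVM, feed-forward MLP,
    capped-split tree ensemble) with stratified hold-out validation and an
    AUROC-centred metric panel, a synthetic cohort generator (imaging +
    2,559-gene transcriptome with a 27-gene HOT/COLD signature) and a
    command-line driver for the four prediction experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
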