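Package: hicprog
Title: Hi-C Analysis of Tumor Genome Architecture Across Disease Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for patient-derived Hi-C contact maps across
    cancer progression: iterative-correction balancing and observed/expected
    transforms; A/B compartment scoring with GC-based signing, saddle plots
    and bootstrapped compartment strength; insulation scores, TAD boundary
    calling, aggregate TAD analysis and Jaccard boundary similarity;
    Hi-C-coverage copy-number estimation with covariate regression and
    binary segmentation; translocation candidate detection in trans matrices
    via negative-binomial CNV normalisation, compartment removal and a
    corner-filter convolution; paired-end spatial chromatin analysis
    (PE-SCAn) over transcription-factor binding clusters; and TAD-boundary
    chromatin-feature enrichment tests. Includes a synthetic Hi-C generator
    that plants compartments, TADs, copy-number events, translocations and
    cluster-pair enrichment with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    MASS,
    mgcv,
    EBImage,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
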