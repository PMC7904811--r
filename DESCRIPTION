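Package: mirplat
Title: Cross-Platform Evaluation of Circulating miRNA Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating and comparing miRNA quantification
    platforms (qPCR, hybridization counting, small-RNA sequencing) on
    technical replicate runs. Implements replicate-CV statistics with a
    LOESS CV-versus-abundance trend and estimation of the lower limit of
    quantification (LLOQ) at a 50% CV cutoff, Lin's concordance
    correlation coefficient for inter-run reproducibility, sequencing
    depth subsampling with detection-saturation assessment,
    platform-specific normalization schemes (standard-curve absolute
    quantification, spike-in residual-Ct normalization, three-step
    hybridization-count normalization, reads-per-million), and
    cross-platform overlap and panel-content accounting. A synthetic
    multi-platform data generator with a shared ground truth supports
    end-to-end testing and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
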