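Package: csgcnreg
Title: Condition-Specific Co-Expression Networks with Regulatory Triangle Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs condition-specific gene co-expression networks
    (csGCNs) from multi-condition expression matrices by Gaussian-mixture
    clustering of each gene pair's 2-D expression scatter, per-cluster
    Spearman correlation with power filtering, proportion z-tests for
    condition association, and differential-cluster-expression and
    missingness bias filters. Integrates a tissue-specific gene regulatory
    network to extract transcription-factor triangle motifs (a TF
    regulating both endpoints of a condition-specific co-expression edge),
    scores regulatory edges by differential expression and the TF/TR
    expression-ratio t-test, and validates condition-specific gene sets by
    multilayer-perceptron sample classification. Ships a synthetic-data
    generator with planted ground truth so the whole pipeline is testable
    end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    igraph,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
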