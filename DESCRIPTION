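Package: slidenet
Title: Co-Expression Networks from Incomplete Expression Data via a
    Sliding Correlation Threshold
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs gene co-expression networks from expression
    matrices with many missing values. Pearson correlations are computed
    pairwise-complete together with the number of paired conditions per
    gene pair; a sliding significance threshold f(x) = alpha - 1/(eta +
    lambda*exp(-x/beta)) is fitted to top-percentage correlation
    quantiles binned by paired count, so that pairs observed under few
    shared conditions must clear a higher correlation bar. Selected
    edges form an undirected network that is then analysed for
    communities (Louvain/Leiden), k-cores, and degree, eigenvector,
    betweenness and closeness centralities. Includes a block-structured
    synthetic expression generator for calibration and testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    minpack.lm,
    jsonlite,
    yaml,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'conditions.R'
    'AllClasses.R'
    'correlation.R'
    'network.R'
    'pipeline.R'
    'preprocess.R'
    'slidenet-package.R'
    'synthetic.R'
    'threshold.R'
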