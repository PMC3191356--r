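Package: memconn
Title: Membrane-Connectivity Scoring of HER2 Immunohistochemistry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital analysis of HER2 immunohistochemistry on breast-cancer
    tissue-microarray spot images via a membrane-connectivity estimate:
    optical-density stain separation of DAB and hematoxylin, curvilinear
    structure enhancement, bimodal membrane segmentation, skeleton fragment
    analysis, and conversion of the continuous connectivity value into the
    ordinal HER2 score. Also provides the accompanying concordance toolkit
    (linearly weighted kappa with asymptotic confidence intervals, percent
    agreement, per-patient maximum-spot aggregation, FISH positivity tables,
    log-scale correlations) and synthetic spot-image and cohort generators
    with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    tiff,
    withr,
    ggplot2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
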