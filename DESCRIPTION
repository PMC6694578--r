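Package: lbdassoc
Title: Indirect Association Measures for Literature-Based Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for ranking hypothesis term pairs in literature-based
    discovery (LBD). Builds directed term co-occurrence matrices from
    concept streams with windowed counting, completes 2x2 contingency
    tables from four primitive cells, and scores term pairs that never
    directly co-occur with indirect association measures: minimum weight
    association (MWA), linking term association (LTA), shared B-to-C set
    association (SBC), and linking set association (LSA). Baselines
    include linking term count (LTC), direct co-occurrence cosine, and
    embedding cosine. Evaluation machinery covers intrinsic comparison
    against human relatedness gold standards (Spearman's rho, Fisher
    r-to-z) and extrinsic time-slicing link prediction with tie-penalised
    precision-recall and ROC curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
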