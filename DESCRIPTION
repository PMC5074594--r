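Package: mirkingdom
Title: Numerical Features and Kingdom Classification of pre-miRNA Hairpins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Extracts a canonical panel of 132 numerical features (sequence
    composition, secondary-structure triplet matching states, structural
    element counts, folding energies, and information entropies) from
    pre-miRNA hairpin records, screens features between two labelled cohorts
    with two-sample Kolmogorov-Smirnov and Welch t tests, selects compact
    feature subsets by correlation-based feature selection (CFS), and fits
    and evaluates logistic animal-versus-plant classifiers, including a
    published fixed-coefficient four-feature model. Ships a synthetic
    hairpin cohort generator so the whole pipeline can be exercised without
    external sequence databases or a thermodynamic folding engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
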