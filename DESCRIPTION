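Package: tidymr
Title: Tidy Two-Sample and Multivariable Mendelian Randomization from
    GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization workflow for
    GWAS summary statistics: instrument selection (genome-wide significance
    filtering, LD clumping, confounder and outcome-association exclusion,
    proxy search, instrument-strength statistics), allele harmonization
    with palindromic-SNP handling, causal-effect estimation by
    inverse-variance weighting, MR-Egger regression and the weighted
    median, a sensitivity battery (Cochran's Q and I-squared, MR-PRESSO
    global/outlier/distortion tests, leave-one-out, funnel data), and
    multivariable MR for direct effects conditional on co-exposures. A
    synthetic summary-statistics generator with known ground truth allows
    the full pipeline to be exercised and validated without external data.
    All user-facing functions take and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
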