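Package: popsegment
Title: Utilisation-Based Population Segmentation of Healthcare Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven segmentation of a GP-registered population from
    linked primary and secondary care utilisation records. Selects the
    number of segments by subsampled hierarchical clustering with the
    Calinski-Harabasz pseudo-F and Duda-Hart Je(2)/Je(1) stopping rules,
    fits k-means on standardised annual utilisation counts across seven
    care settings, classifies segments into high/low need and complexity
    from mean-utilisation ratios, and profiles segments with global and
    Bonferroni-adjusted pairwise statistical tests. Includes a seeded
    synthetic-cohort generator so the whole pipeline is testable without
    access to patient-level NHS data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
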