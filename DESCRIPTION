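Package: eigenmetab
Title: Eigengene Decomposition and Metabolite Time-Course Statistics for
    Staged Developmental Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of staged developmental omics series, built around
    singular value decomposition of a genes-by-timepoints expression matrix
    into eigengenes (shared temporal expression patterns), with
    eigenexpression fractions, normalized Shannon entropy of the singular
    value spectrum, per-pattern gene ranking, and an exact log-space
    hypergeometric test for over-representation of an annotated gene catalog
    among top-ranked genes. A companion set of tools handles GC-MS metabolite
    time courses: internal-standard normalization, baseline-relative scaling,
    Welch t-tests against the earliest stage, box-plot summaries, within-sample
    metabolite ratios, and nutrient-store assay statistics. Synthetic-data
    generators with recorded ground truth (planted temporal patterns, planted
    catalog enrichment, planted metabolite fold changes) make every stage of
    the pipeline testable end to end.
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
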