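Package: metaprogramr
Title: Meta-Program Discovery in Multi-Sample Single-Cell Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers recurrent transcriptional meta-programs across a cohort
    of single-cell (or single-nucleus) RNA-seq samples, such as tumor
    patient-derived organoids. Each sample is factorized by non-negative
    matrix factorization; the top-loading genes of every factor define a gene
    program; every program is scored on every pooled cell with a binned
    control-gene enrichment score; programs are clustered by Pearson
    correlation of their scores and a dendrogram cut, and each cluster is
    summarized by a consensus gene set (a meta-program) that is projected
    back onto cells. A seeded synthetic-cohort generator with planted shared
    and patient-private programs makes every stage testable against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
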