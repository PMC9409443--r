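Package: methexpr
Title: Association of Differential DNA Methylation with Differential Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy pipeline for associating whole-genome bisulfite methylation
    differences with gene expression changes in small two-pair case/control
    designs. Implements per-cytosine methylation frequencies with binomial
    likelihood-ratio (Wilks) confidence intervals, a logistic transform with a
    CI-length/6 standard-deviation rule, a two-sample regression-slope z
    statistic, gap-bounded segmentation of significant sites into hyper- and
    hypo-methylated regions, reconciliation of two sex-matched pairs into
    consensus regions, promoter/gene-body assignment, fold-change and p-value
    based differential-expression classes, and the methylation-by-expression
    cross-tabulation. Ships a synthetic-data generator with planted truth so
    the whole pipeline is testable without raw sequencing accessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
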