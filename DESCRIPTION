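Package: unideg
Title: Universal Differentially Expressed Gene Discovery from Relative
    Expression Orderings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of universally dysregulated genes in heterogeneous
    tumor cohorts. Identifies population-level differentially expressed
    genes by paired t-tests with cross-dataset concordance, detects
    significantly stable relative expression orderings (REOs) in normal
    reference compendia by exact binomial tests, calls per-sample
    differential expression either RankComp-style (iterative Fisher exact
    testing against stable REOs) or by direct paired tumor-normal
    comparison, estimates per-gene dysregulation frequencies with exact
    binomial confidence intervals, applies a dual-cohort frequency
    threshold to define universal DEGs, and performs downstream
    hypergeometric gene-set enrichment, protein-protein interaction
    neighborhood, and paired methylation analyses. Includes a synthetic
    cohort generator with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
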