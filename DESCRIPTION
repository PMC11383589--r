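Package: gepnet
Title: Gene Expression Program Networks from Multi-Sample Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts gene expression programs (GEPs) from multi-sample
    single-cell RNA count data by consensus non-negative matrix
    factorization with stability-based rank selection, builds cross-cell-type
    program correlation networks from per-sample program scores, detects
    program modules and tests their gene-set enrichment by permutation,
    relates programs, gene modules and biomarker channels to clinical
    disease-activity covariates, and transfers program signatures to
    independent cohorts through rank-AUC proxy scores.  Includes a synthetic
    multi-sample cohort generator with planted programs, module structure
    and a disease-activity covariate for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    mclust,
    pracma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
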