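Package: gllrm
Title: Graphical Log-Linear Rasch Models for Polytomous Scale Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Conditional maximum likelihood estimation of the Partial Credit
    (polytomous Rasch) model and of Graphical Log-linear Rasch Models with
    uniform local dependence and uniform differential item functioning (DIF),
    together with the full item-analysis toolkit used in Rasch-based scale
    validation: conditional likelihood ratio tests of homogeneity and global
    DIF, conditional infit/outfit item fit statistics, Kelderman likelihood
    ratio screening of local dependence and DIF, partial Goodman-Kruskal
    gamma effect sizes, a two-subscale unidimensionality test, Warm's
    weighted maximum likelihood person estimation, test information and
    targeting indices, Monte Carlo reliability adjusted for local dependence,
    person separation, DIF score-conversion tables, and a stepwise
    item-analysis pipeline. Includes a synthetic-data generator that emulates
    the response structure of the 14-item Perceived Stress Scale so that the
    whole validation workflow can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
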