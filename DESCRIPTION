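Package: placentaFcR
Title: Multimodal Analysis of Placental Fc Receptor Expression and Maternal-Fetal IgG Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cell-type-specific placental Fc receptor
    expression from multiplex immunohistochemistry area and cell-density
    tables, deriving serological transfer metrics (five-parameter logistic
    standard-curve quantification, cord:maternal ratios, IgG Fc glycoform
    summary motifs), unsupervised clustering of clinical covariates with
    cross-cohort latent-space projection, NIPALS partial least squares
    regression and discriminant analysis with outcome-aligned
    orthogonalization, VIP scores, repeated cross-validation and permutation
    testing, LASSO stability selection with co-correlate networks,
    covariate-controlled partial Pearson correlation networks, and
    gestational trajectory models (cubic polynomial peak estimation,
    exponential cord IgG accumulation). Includes a synthetic cohort
    generator with planted ground truth so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    minpack.lm,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    mixOmics,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
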