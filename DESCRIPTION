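Package: gldskit
Title: Estimating and Removing General Levels of Drug Sensitivity in
    Cell-Line Drug Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Cell lines in large pharmacogenomic screens differ in their
    general level of drug sensitivity (GLDS): some lines are sensitive, and
    others resistant, to many drugs regardless of mechanism. This latent
    axis confounds mutation-drug biomarker discovery. gldskit estimates
    GLDS and conditions it out: an iterative lasso-on-eigen-drugs matrix
    completion algorithm fills missing log(IC50) values; singular value
    decomposition summarizes the shared sensitivity axis; for each drug,
    principal components of mechanistically unrelated "negative control"
    drugs supply confounder covariates for linear-model association
    screens; and an expression-based signature provides proxy covariates
    when no large drug panel is available. A synthetic-screen generator
    with known ground truth and a simulation-based evaluation harness
    (type-I error, power, positive predictive value) complete the toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
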