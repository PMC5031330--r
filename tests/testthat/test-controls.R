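test_that("class exclusion alone keeps all unrelated-mechanism drugs", {
  toy <- toy5()
  ncs <- select_negative_controls("A", toy$annotation, toy$corr,
                                  k_corr = 0, min_controls = 1)
  expect_setequal(ncs$controls, c("D", "E"))
  expect_setequal(ncs$excluded_by_class, c("B", "C"))
  expect_length(ncs$excluded_by_correlation, 0)
})

test_that("correlation exclusion removes the top-ranked unrelated drugs", {
  toy <- toy5()
  # rank by corr with A: B (.9) > C (.8) > E (.5) > D (.2)
  ncs1 <- select_negative_controls("A", toy$annotation, toy$corr,
                                   k_corr = 1, min_controls = 1)
  expect_setequal(ncs1$controls, c("D", "E"))   # top-1 is B, already class-excluded
  ncs3 <- select_negative_controls("A", toy$annotation, toy$corr,
                                   k_corr = 3, min_controls = 1)
  expect_equal(ncs3$controls, "D")
  expect_equal(ncs3$excluded_by_correlation, "E")
  expect_error(select_negative_controls("A", toy$annotation, toy$corr,
                                        k_corr = 0, min_controls = 3),
               "reduce k_corr")
})

test_that("exclusion is monotone in k_corr and partitions the panel", {
  toy <- toy5()
  prev <- NULL
  for (k in 0:3) {
    ncs <- select_negative_controls("A", toy$annotation, toy$corr,
                                    k_corr = k, min_controls = 1)
    expect_false(ncs$target %in% ncs$controls)
    expect_setequal(c(ncs$controls, ncs$excluded_by_class,
                      ncs$excluded_by_correlation),
                    setdiff(names(toy$annotation), "A"))
    expect_length(intersect(ncs$controls,
                            c(ncs$excluded_by_class,
                              ncs$excluded_by_correlation)), 0)
    if (!is.null(prev)) expect_true(all(ncs$controls %in% prev))
    prev <- ncs$controls
  }
})

test_that("a unique-class target with k_corr = 0 keeps every other drug", {
  toy <- toy5()
  ncs <- select_negative_controls("D", toy$annotation, toy$corr,
                                  k_corr = 0, min_controls = 1)
  expect_setequal(ncs$controls, c("A", "B", "C", "E"))
})

test_that("multi-class labels are excluded on any case-folded match", {
  drugs <- c("A", "B", "C", "D")
  ann <- setNames(c("MEK inhibitor", "mek inhibitor, HSP90",
                    "HDAC inhibitor", "platinum"), drugs)
  corr <- diag(4); dimnames(corr) <- list(drugs, drugs)
  ncs <- select_negative_controls("A", ann, corr, k_corr = 0,
                                  min_controls = 1)
  expect_setequal(ncs$excluded_by_class, "B")
  expect_setequal(ncs$controls, c("C", "D"))
})

test_that("control covariates are order-invariant and reject bad inputs", {
  set.seed(14)
  X <- named_matrix(rnorm(20) %o% abs(rnorm(8)), 20, 8)  # rank 1
  ids <- colnames(X)[3:8]
  c1 <- control_covariates(X, ids, n_pcs = 1)
  c2 <- control_covariates(X, rev(ids), n_pcs = 1)
  expect_equal(c1$covariates, c2$covariates)
  # rank-1 submatrix: the single covariate is proportional to the latent vector
  u <- X[, 3]
  expect_gt(abs(cor(c1$covariates[, 1], u)), 1 - 1e-10)
  expect_error(control_covariates(X, ids, n_pcs = 7), "exceeds")
  expect_error(control_covariates(X, c(ids, "nope"), n_pcs = 2), "absent")
})

test_that("the target drug never enters its own covariate submatrix", {
  ds <- simulate_screen(sim_config(m = 60, n_drugs = 12, missing_fraction = 0,
                                   n_genes = 10, n_glds_genes = 0, seed = 5))
  covs <- covariates_for_all_drugs(ds$response, ds$response_full,
                                   ds$annotation, k_corr = 2,
                                   min_controls = 3, n_pcs = 3)
  for (d in names(covs)) {
    expect_false(d %in% covs[[d]]$provenance$controls)
  }
})

test_that("pairwise correlations flag duplicated drugs and respect the pair guard", {
  set.seed(15)
  m <- named_matrix(rnorm(80), 20, 4)
  m[, 2] <- m[, 1]                      # duplicated column
  pc <- pairwise_drug_correlations(m)
  expect_equal(pc$rho["d01", "d02"], 1)
  expect_lt(pc$p["d01", "d02"], 1e-12)
  expect_equal(pc$rho, t(pc$rho))
  # pairs sharing < 3 cell lines are NA
  m2 <- named_matrix(rnorm(40), 10, 4)
  m2[3:10, 1] <- NA; m2[1:2, 2] <- NA   # drugs 1 and 2 share 0 lines
  pc2 <- pairwise_drug_correlations(m2)
  expect_true(is.na(pc2$rho["d01", "d02"]))
  expect_true(is.na(pc2$q["d01", "d02"]))
})

test_that("independent drugs produce a calibrated significant fraction", {
  set.seed(16)
  m <- named_matrix(rnorm(200 * 30), 200, 30)
  pc <- pairwise_drug_correlations(m)
  expect_lte(pc$summary$n_significant / pc$summary$n_pairs, 0.05)
})

test_that("a strong shared axis makes nearly all significant pairs positive", {
  ds <- simulate_screen(sim_config(m = 150, n_drugs = 20,
                                   glds_variance_share = 0.7,
                                   missing_fraction = 0.1, n_genes = 10,
                                   n_glds_genes = 0, seed = 17))
  pc <- pairwise_drug_correlations(ds$response)
  expect_gt(pc$summary$n_significant, 0)
  expect_gt(pc$summary$positive_fraction, 0.9)
})
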