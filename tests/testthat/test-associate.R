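test_that("a pure mutation effect is estimated exactly", {
  g <- rep(c(0, 1), each = 10)
  y <- 2 * g + rnorm(20, sd = 1e-8)
  res <- test_association(y, g)
  expect_equal(res$effect, 2, tolerance = 1e-6)
  expect_lt(res$p, 1e-10)
  expect_equal(res$n_mut, 10)
  expect_equal(res$n_wt, 10)
})

test_that("group-size guard returns an untested row, never an error", {
  y <- rnorm(20)
  expect_false(test_association(y, rep(0, 20))$tested)
  expect_true(is.na(test_association(y, rep(0, 20))$p))
  g <- c(rep(1, 2), rep(0, 18))   # 2 mutants < default min_group
  expect_false(test_association(y, g)$tested)
  expect_true(test_association(y, g, min_group = 2)$tested)
})

test_that("with zero covariates the effect equals the two-group mean difference", {
  set.seed(21)
  for (i in 1:5) {
    g <- rbinom(40, 1, 0.3)
    if (sum(g) < 3) next
    y <- rnorm(40)
    res <- test_association(y, g)
    expect_equal(res$effect, mean(y[g == 1]) - mean(y[g == 0]),
                 tolerance = 1e-12)
  }
})

test_that("covariates orthogonal to y and g leave the coefficient unchanged", {
  set.seed(22)
  g <- rbinom(60, 1, 0.3)
  y <- rnorm(60) + 0.8 * g
  C <- matrix(rnorm(60 * 3), 60)
  C_orth <- residuals(lm(C ~ cbind(1, g, y) - 1))   # orthogonal to 1, g, y
  base <- test_association(y, g)
  adj <- test_association(y, g, covariates = C_orth)
  expect_equal(adj$effect, base$effect, tolerance = 1e-8)
})

test_that("collinear covariates are dropped by the rank-revealing fit", {
  set.seed(23)
  g <- rbinom(50, 1, 0.4)
  y <- rnorm(50) + g
  C <- cbind(a = rnorm(50))
  C2 <- cbind(C, b = C[, 1])   # duplicated covariate
  expect_equal(test_association(y, g, C2)$effect,
               test_association(y, g, C)$effect, tolerance = 1e-12)
})

test_that("bh_fdr reproduces the hand-computed step-up and handles edge cases", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.2, NA, 0.01)
  q <- bh_fdr(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_fdr(c(0.2, 0.01)))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("screens are ordered deterministically and BH-corrected screen-wide", {
  ds <- simulate_screen(sim_config(m = 60, n_drugs = 6, n_confounded = 2,
                                   n_specific = 2, n_null = 4,
                                   missing_fraction = 0.1, n_genes = 10,
                                   n_glds_genes = 0, seed = 31))
  tab <- run_screen(ds$response, ds$mutations, "uncorrected")
  expect_equal(nrow(tab), 6 * 8)
  expect_equal(tab$drug, rep(colnames(ds$response$values), each = 8))
  expect_equal(tab$gene, rep(colnames(ds$mutations$calls), 6))
  ok <- !is.na(tab$p)
  expect_equal(tab$q[ok], bh_fdr(tab$p)[ok])
})

test_that("tissue mode with a single tissue equals the uncorrected screen", {
  ds <- simulate_screen(sim_config(m = 50, n_drugs = 5, n_tissues = 1,
                                   missing_fraction = 0, n_genes = 10,
                                   n_glds_genes = 0, seed = 32))
  t_uncorr <- run_screen(ds$response, ds$mutations, "uncorrected")
  t_tissue <- run_screen(ds$response, ds$mutations, "tissue",
                         tissue = ds$tissue)
  expect_equal(t_tissue$effect, t_uncorr$effect)
  expect_equal(t_tissue$p, t_uncorr$p)
})

test_that("glds mode demands covariates for every drug", {
  ds <- simulate_screen(sim_config(m = 50, n_drugs = 4, missing_fraction = 0,
                                   n_genes = 10, n_glds_genes = 0, seed = 33))
  covs <- list()   # nothing supplied
  expect_error(run_screen(ds$response, ds$mutations, "glds",
                          covariates = covs), "drug_01")
})

test_that("elastic net finds a strong specific effect and stays quiet under the null", {
  cfg <- sim_config(m = 150, n_drugs = 6, n_confounded = 0, n_specific = 1,
                    specific_beta = 1.5, n_null = 8, missing_fraction = 0,
                    glds_variance_share = 0.3, n_genes = 10,
                    n_glds_genes = 0, seed = 34)
  ds <- simulate_screen(cfg)
  truth <- ds$mutation_truth[ds$mutation_truth$truth == "specific", ]
  res <- elasticnet_screen(ds$response, ds$mutations, seed = 1)
  hit <- res[res$drug == truth$drug, ]
  expect_true(nrow(hit) > 0)
  top <- hit$gene[which.max(abs(hit$weight))]
  expect_equal(top, truth$gene)
  expect_gt(hit$weight[hit$gene == truth$gene], 0)

  # pure-null screens select (almost) nothing, across seeds
  n_sel <- vapply(1:3, function(s) {
    dn <- simulate_screen(sim_config(m = 80, n_drugs = 4, n_confounded = 0,
                                     n_specific = 0, n_null = 10,
                                     glds_variance_share = 0,
                                     missing_fraction = 0, n_genes = 10,
                                     n_glds_genes = 0, seed = 40 + s))
    nrow(elasticnet_screen(dn$response, dn$mutations, seed = s))
  }, numeric(1))
  expect_lte(median(n_sel), 1)
})

test_that("concordance counts discovery hits validated with matching sign", {
  disc <- data.frame(gene = c("g1", "g2", "g3", "g4", "g5"),
                     drug = "dA",
                     effect = c(1, -1, 1, 1, 1),
                     p = c(1e-5, 1e-5, 1e-4, 1e-4, 0.5),
                     q = c(0.01, 0.01, 0.02, 0.02, 0.9))
  val <- disc
  val$p <- c(0.01, 0.01, 0.5, 0.01, 0.01)  # g3 fails p, g4 flips sign
  val$effect <- c(1, -1, 1, -1, 1)
  out <- concordance(disc, val, q_disc = 0.05, p_val = 0.05)
  expect_equal(out$n_hits, 4L)
  expect_equal(out$n_validated, 2L)
  expect_equal(out$ppv, 0.5)
  # identical tables validate perfectly
  out2 <- concordance(disc, disc)
  expect_equal(out2$ppv, 1)
  # empty discovery set: NA, logged
  disc0 <- disc; disc0$q <- 0.9
  expect_message(out3 <- concordance(disc0, val), "no discovery hits")
  expect_true(is.na(out3$ppv))
})
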