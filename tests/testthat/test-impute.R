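test_that("rows are ordered ascending by missing count with stable ties", {
  m <- named_matrix(rnorm(12), 3, 4)
  m[1, 1:2] <- NA   # row 1: 2 missing
  m[3, 3] <- NA     # row 3: 1 missing
  x <- drug_response_matrix(m)
  ord <- order_rows_by_missingness(x)
  expect_equal(ord$permutation, c(2L, 3L, 1L))
  expect_equal(rownames(ord$matrix$values), rownames(m)[c(2, 3, 1)])

  # no missing: identity permutation
  x2 <- drug_response_matrix(named_matrix(rnorm(12), 3, 4))
  expect_equal(order_rows_by_missingness(x2)$permutation, 1:3)

  # ties keep original relative order
  m3 <- named_matrix(rnorm(16), 4, 4)
  m3[2, 1] <- NA; m3[4, 2] <- NA
  ord3 <- order_rows_by_missingness(drug_response_matrix(m3))
  expect_equal(ord3$permutation, c(1L, 3L, 2L, 4L))
})

test_that("initialization fills missing entries with per-drug observed means", {
  m <- named_matrix(c(2, 4, NA, 1, 2, 3), 3, 2)
  init <- initialize_missing(drug_response_matrix(m))
  expect_equal(init[3, 1], 3)         # mean of {2, 4}
  expect_equal(init[, 2], m[, 2])     # observed untouched
  # fully observed matrix is returned unchanged
  full <- named_matrix(rnorm(12), 4, 3)
  expect_identical(initialize_missing(drug_response_matrix(full)), full)
})

test_that("impute_pass recovers a rank-1 entry exactly and never touches observed values", {
  X <- make_rank1(15, 8, seed = 3)
  Xm <- X; Xm[4, 6] <- NA
  drm <- drug_response_matrix(Xm)
  cur <- initialize_missing(drm)
  out <- impute_pass(cur, drm, impute_config(seed = 1))
  expect_lt(abs(out[4, 6] - X[4, 6]), 1e-6)   # closed-form rank-1 oracle
  expect_identical(out[drm$mask], X[drm$mask])
  # rows with all drugs observed are unchanged
  expect_identical(out[1, ], cur[1, ])
})

test_that("with the penalty forced to 0 impute_pass matches an OLS eigen-drug oracle", {
  set.seed(11)
  X <- named_matrix(rnorm(24), 6, 4)
  Xm <- X
  miss <- cbind(c(1, 3, 5), c(2, 4, 1))   # one missing entry in three rows
  Xm[miss] <- NA
  drm <- drug_response_matrix(Xm)
  cur <- initialize_missing(drm)
  out <- impute_pass(cur, drm, impute_config(lambda = 0))
  # oracle: sweep incomplete rows in ascending index order, mirroring the
  # algorithm's sequential updates; for each, take the eigen-drugs of the
  # other rows (centered) and solve the exactly determined 3x3 system on
  # the observed drugs
  oracle <- cur
  for (k in order(miss[, 1])) {
    i <- miss[k, 1]; j <- miss[k, 2]
    Xo <- oracle[-i, , drop = FALSE]
    mu <- colMeans(Xo)
    V <- svd(sweep(Xo, 2, mu))$v[, 1:3]
    obs <- setdiff(1:4, j)
    beta <- solve(V[obs, ], oracle[i, obs] - mu[obs])
    oracle[i, j] <- mu[j] + drop(V[j, , drop = FALSE] %*% beta)
  }
  expect_lt(max(abs(out - oracle)), 1e-8)
})

test_that("complete() recovers a noiseless rank-1 matrix and reports diagnostics", {
  X <- make_rank1(20, 10, seed = 21)
  drm <- mask_entries(X, 0.1, seed = 2)
  cmp <- complete(drm, impute_config())
  expect_true(cmp$converged)
  expect_equal(cmp$n_iterations, length(cmp$a_trajectory))
  expect_lt(max(abs(cmp$values[!drm$mask] - X[!drm$mask])), 1e-3)
  # observed entries pass through bit-equal, in the original row order
  expect_identical(cmp$values[drm$mask], drm$values[drm$mask])
  expect_identical(rownames(cmp$values), rownames(X))
  # convergence statistic honored
  tr <- cmp$a_trajectory
  expect_lt(abs(tr[length(tr)] - tr[length(tr) - 1]) / sum(!drm$mask), 1e-3)
})

test_that("complete() with no missing entries is the identity with 0 iterations", {
  x <- drug_response_matrix(named_matrix(rnorm(30), 6, 5))
  cmp <- complete(x)
  expect_identical(cmp$values, x$values)
  expect_equal(cmp$n_iterations, 0L)
  expect_true(cmp$converged)
})

test_that("imputation error grows with missingness (monotone information)", {
  rmse <- function(frac) {
    mean(vapply(1:3, function(s) {
      cfg <- sim_config(m = 60, n_drugs = 16, noise_sd = 0.3,
                        missing_fraction = frac, n_genes = 10,
                        n_glds_genes = 0, seed = 70 + s)
      ds <- simulate_screen(cfg)
      cmp <- suppressWarnings(
        complete(ds$response, impute_config(max_iter = 2, seed = s)))
      hid <- !ds$response$mask
      sqrt(mean((cmp$values[hid] - ds$response_full[hid])^2))
    }, numeric(1)))
  }
  expect_lte(rmse(0.1), rmse(0.4))
})

test_that("cross-validated imputation machinery is sound", {
  cfg <- sim_config(m = 40, n_drugs = 10, noise_sd = 0.3,
                    missing_fraction = 0.1, n_genes = 10, n_glds_genes = 0,
                    seed = 31)
  ds <- simulate_screen(cfg)
  # a truth oracle scores R^2 = 1 through the 8-fold machinery
  cv_oracle <- cross_validate_imputation(
    ds$response, folds = 8, seed = 1,
    imputer = function(Xm) ds$response_full)
  expect_equal(cv_oracle$pooled_r2, 1)
  expect_equal(cv_oracle$n_heldout, sum(ds$response$mask))
  # the column-mean baseline scores below the real imputer
  colmean_imputer <- function(Xm) initialize_missing(Xm)
  cv_base <- cross_validate_imputation(ds$response, folds = 4, seed = 1,
                                       imputer = colmean_imputer)
  cv_real <- cross_validate_imputation(
    ds$response, folds = 4, seed = 1,
    imputer = function(Xm) suppressWarnings(
      complete(Xm, impute_config(max_iter = 2, seed = 1))$values))
  expect_lt(cv_base$pooled_r2, cv_real$pooled_r2)
})
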