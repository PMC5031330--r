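#' Configuration for iterative matrix completion
#'
#' @param tol Convergence tolerance: the iteration stops when the change in
#'   the update statistic `A` (sum of absolute entry changes between
#'   successive matrices), per missing entry, falls below `tol`.
#' @param max_iter Iteration cap; non-convergence at the cap returns with
#'   `converged = FALSE` and a warning, never an error.
#' @param cv_folds_lambda Folds for the internal cross-validation that
#'   selects each row-fit's lasso penalty (the minimum-CV-error penalty is
#'   used).
#' @param lambda Optional fixed penalty overriding cross-validation; `0`
#'   fits ordinary least squares on the eigen-drugs. Default `NULL` = CV.
#' @param approximate If `TRUE`, use one shared SVD per pass (row i
#'   included) instead of the exact leave-row-out SVD per row. Off by
#'   default; a documented speed escape hatch for large matrices.
#' @param seed Integer seed driving the deterministic CV fold assignment.
#' @return An `impute_config` list.
#' @export
impute_config <- function(tol = 1e-3, max_iter = 100, cv_folds_lambda = 5,
                          lambda = NULL, approximate = FALSE, seed = 1) {
  if (tol <= 0) stop_glds("tol must be positive")
  if (max_iter < 1) stop_glds("max_iter must be >= 1")
  structure(as.list(environment()), class = "impute_config")
}

#' Order rows by their number of missing values (ascending)
#'
#' Rows with the fewest missing entries are imputed first. Ties keep the
#' original relative order (stable sort), so the permutation is
#' deterministic.
#'
#' @param X A [drug_response_matrix()].
#' @return List with `matrix` (row-permuted [drug_response_matrix()]) and
#'   `permutation` (integer vector such that
#'   `matrix$values[order(permutation), ]` restores the input order — i.e.
#'   `permutation[k]` is the input row index placed at output row `k`).
#' @export
order_rows_by_missingness <- function(X) {
  stopifnot(inherits(X, "drug_response_matrix"))
  perm <- order(rowSums(!X$mask))  # order() is stable
  list(matrix = drug_response_matrix(X$values[perm, , drop = FALSE]),
       permutation = perm)
}

#' Initialize missing entries with per-drug means
#'
#' @param X A [drug_response_matrix()].
#' @return Dense numeric matrix: observed entries untouched, missing entries
#'   set to the mean of the observed entries of their drug column.
#' @export
initialize_missing <- function(X) {
  stopifnot(inherits(X, "drug_response_matrix"))
  v <- X$values
  obs <- colSums(X$mask)
  if (any(obs < 2)) {
    stop_glds("column(s) with fewer than 2 observed entries: ",
              paste(colnames(v)[obs < 2], collapse = ", "))
  }
  mu <- colMeans(v, na.rm = TRUE)
  idx <- which(!X$mask, arr.ind = TRUE)
  v[idx] <- mu[idx[, 2]]
  v
}

# Lasso (or OLS) regression of one centered row profile on eigen-drug
# loadings; returns predictions at the missing drug positions.
fit_row_on_components <- function(V, y_obs, obs, miss, config, row_tag) {
  n_obs <- length(y_obs)
  P <- V[obs, , drop = FALSE]
  if (!is.null(config$lambda) && config$lambda == 0) {
    # unpenalized variant: cap the component count at the number of
    # observed drugs so the least-squares system is determined
    k <- min(ncol(V), n_obs)
    fit <- stats::lm.fit(P[, seq_len(k), drop = FALSE], y_obs)
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    return(drop(V[miss, seq_len(k), drop = FALSE] %*% beta))
  }
  if (n_obs < 4 || ncol(P) < 2) {
    # too few observations for a CV'd lasso: project on the leading
    # eigen-drug by least squares
    b1 <- sum(P[, 1] * y_obs) / sum(P[, 1]^2)
    return(V[miss, 1] * b1)
  }
  # glmnet path extended to ~0 so CV may select an effectively
  # unpenalized fit when the data are noiseless
  lmax <- max(abs(crossprod(P, y_obs))) / n_obs
  if (lmax <= 0) return(rep(0, length(miss)))
  lam_path <- lmax * 10^seq(0, -8, length.out = 60)
  if (!is.null(config$lambda)) {
    co <- glmnet::glmnet(P, y_obs, alpha = 1, lambda = config$lambda,
                         intercept = FALSE, standardize = FALSE)
    beta <- as.numeric(co$beta)
  } else {
    nf <- max(3L, min(config$cv_folds_lambda, n_obs))
    foldid <- with_rng(derive_seed(config$seed, "fold", row_tag),
                       sample(rep_len(seq_len(nf), n_obs)))
    cv <- cv.glmnet_quiet(P, y_obs, lambda = lam_path, foldid = foldid,
                          alpha = 1, intercept = FALSE, standardize = FALSE,
                          grouped = n_obs >= 3L * nf)
    beta <- as.numeric(stats::coef(cv$glmnet.fit, s = cv$lambda.min))[-1]
  }
  drop(V[miss, , drop = FALSE] %*% beta)
}

cv.glmnet_quiet <- function(..., grouped) {
  withCallingHandlers(
    glmnet::cv.glmnet(..., grouped = grouped),
    warning = function(w) {
      if (grepl("grouped|dangerous|Option grouped", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' One sweep of the iterative completion algorithm
#'
#' For each cell line `i` with missing drugs: extract the eigen-drugs
#' (right singular vectors) of the column-centered matrix formed from all
#' rows except `i`; regress cell line `i`'s centered values at its observed
#' drugs on those eigen-drug loadings with an L1 penalty chosen by internal
#' cross-validation; predict the values at its missing drugs from the
#' fitted coefficients. Observed positions are never altered. Rows with
#' fewer than 2 observed drugs fall back to column means (logged).
#'
#' @param X_current Dense matrix, consistent with `X` at observed positions.
#' @param X The original [drug_response_matrix()] (supplies the mask).
#' @param config An [impute_config()].
#' @return Updated dense matrix.
#' @export
impute_pass <- function(X_current, X, config = impute_config()) {
  stopifnot(inherits(X, "drug_response_matrix"))
  m <- nrow(X_current); n <- ncol(X_current)
  rows <- which(rowSums(!X$mask) > 0)
  if (!length(rows)) return(X_current)
  out <- X_current

  shared <- NULL
  if (isTRUE(config$approximate)) {
    mu_all <- colMeans(X_current)
    sv <- svd(sweep(X_current, 2, mu_all))
    keep <- sv$d > max(sv$d[1], 1) * 1e-10
    shared <- list(mu = mu_all, V = sv$v[, keep, drop = FALSE])
  }

  for (i in rows) {
    obs <- which(X$mask[i, ])
    miss <- which(!X$mask[i, ])
    if (length(obs) < 2) {
      mu_cols <- colMeans(X$values[, miss, drop = FALSE], na.rm = TRUE)
      out[i, miss] <- mu_cols
      message(sprintf("impute_pass: row %s has < 2 observed drugs; column-mean fallback",
                      rownames(X_current)[i] %||% i))
      next
    }
    if (is.null(shared)) {
      Xm <- out[-i, , drop = FALSE]
      mu <- colMeans(Xm)
      sv <- svd(sweep(Xm, 2, mu))
      keep <- sv$d > max(sv$d[1], 1) * 1e-10
      V <- sv$v[, keep, drop = FALSE]
    } else {
      mu <- shared$mu
      V <- shared$V
    }
    pred <- fit_row_on_components(V, out[i, obs] - mu[obs], obs, miss,
                                  config, row_tag = i)
    out[i, miss] <- mu[miss] + pred
  }
  out
}

#' Iteratively complete a drug-response matrix
#'
#' Orders rows by missingness, initializes missing entries with per-drug
#' means, then repeats [impute_pass()] until the update statistic
#' `A = sum(|X' - X_prev|)` stabilizes: the iteration stops when
#' `|A_t - A_{t-1}|` per missing entry drops below `config$tol`, or at
#' `config$max_iter`.
#'
#' @param X A [drug_response_matrix()].
#' @param config An [impute_config()].
#' @return A `completed_matrix`: list with `values` (dense matrix in the
#'   original row order, exactly equal to the input at observed positions),
#'   `imputed_mask` (`TRUE` = value was imputed), `a_trajectory`
#'   (per-iteration `A`), `n_iterations`, `converged`.
#' @export
complete <- function(X, config = impute_config()) {
  stopifnot(inherits(X, "drug_response_matrix"))
  n_missing <- sum(!X$mask)
  if (n_missing == 0) {
    return(structure(list(values = X$values, imputed_mask = !X$mask,
                          a_trajectory = numeric(0), n_iterations = 0L,
                          converged = TRUE),
                     class = "completed_matrix"))
  }
  ord <- order_rows_by_missingness(X)
  Xo <- ord$matrix
  cur <- initialize_missing(Xo)
  a_traj <- numeric(0)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    nxt <- impute_pass(cur, Xo, config)
    a <- sum(abs(nxt - cur))
    a_traj <- c(a_traj, a)
    cur <- nxt
    if (it >= 2 && abs(a_traj[it] - a_traj[it - 1]) / n_missing < config$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("complete(): not converged after %d iterations (|dA|/missing = %.3g)",
                    length(a_traj),
                    if (length(a_traj) >= 2)
                      abs(diff(utils::tail(a_traj, 2))) / n_missing else NA),
            call. = FALSE)
  }
  # restore the original row order
  inv <- order(ord$permutation)
  structure(list(values = cur[inv, , drop = FALSE],
                 imputed_mask = !X$mask,
                 a_trajectory = a_traj,
                 n_iterations = length(a_traj),
                 converged = converged),
            class = "completed_matrix")
}

#' @export
print.completed_matrix <- function(x, ...) {
  cat(sprintf("completed_matrix: %d x %d, %d imputed entries, %d iterations (%s)\n",
              nrow(x$values), ncol(x$values), sum(x$imputed_mask),
              x$n_iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Cross-validate imputation accuracy on observed entries
#'
#' Partitions the observed entries into folds, masks each fold in turn,
#' re-imputes, and compares held-out values with their imputations. The
#' default of eight folds matches the standard evaluation protocol for this
#' algorithm. The fold assignment is reshuffled (bounded retries) if a draw
#' would leave some drug column with fewer than 2 observed entries.
#'
#' @param X A [drug_response_matrix()].
#' @param folds Fold count (>= 2); default 8.
#' @param config An [impute_config()] passed to the default imputer.
#' @param seed Integer seed for the fold assignment.
#' @param imputer Function `(X) -> dense matrix` (or `completed_matrix`).
#'   Defaults to [complete()] under `config`; injectable so the machinery
#'   can be validated against a truth oracle.
#' @return List with `pooled_r2` (squared Pearson correlation of held-out
#'   vs imputed values), `per_fold_r2`, `n_heldout`, and the held-out
#'   `pairs` data frame.
#' @export
cross_validate_imputation <- function(X, folds = 8, config = impute_config(),
                                      seed = 1, imputer = NULL) {
  stopifnot(inherits(X, "drug_response_matrix"))
  if (folds < 2) stop_glds("folds must be >= 2")
  if (is.null(imputer)) {
    imputer <- function(Xm) complete(Xm, config)$values
  }
  obs_idx <- which(X$mask)
  fold_of <- NULL
  for (attempt in seq_len(25)) {
    cand <- with_rng(derive_seed(seed, "cvfold", attempt),
                     sample(rep_len(seq_len(folds), length(obs_idx))))
    ok <- TRUE
    cols <- ((obs_idx - 1L) %/% nrow(X$values)) + 1L
    for (k in seq_len(folds)) {
      left <- table(factor(cols[cand != k], levels = seq_len(ncol(X$values))))
      if (any(left < 2)) { ok <- FALSE; break }
    }
    if (ok) { fold_of <- cand; break }
  }
  if (is.null(fold_of)) {
    stop_glds("could not build a fold assignment keeping 2 observed entries per column")
  }
  held <- numeric(0); imp <- numeric(0); fold_lab <- integer(0)
  for (k in seq_len(folds)) {
    v <- X$values
    hold <- obs_idx[fold_of == k]
    v[hold] <- NA_real_
    comp <- imputer(drug_response_matrix(v))
    if (inherits(comp, "completed_matrix")) comp <- comp$values
    held <- c(held, X$values[hold])
    imp <- c(imp, comp[hold])
    fold_lab <- c(fold_lab, rep(k, length(hold)))
  }
  per_fold <- vapply(seq_len(folds), function(k) {
    stats::cor(held[fold_lab == k], imp[fold_lab == k])^2
  }, numeric(1))
  list(pooled_r2 = stats::cor(held, imp)^2,
       per_fold_r2 = per_fold,
       n_heldout = length(held),
       pairs = data.frame(fold = fold_lab, measured = held, imputed = imp))
}
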