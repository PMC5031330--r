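# Column-centered SVD with a deterministic sign convention: each component
# is oriented so its Spearman correlation with `reference` is >= 0; exact
# ties fall back to a positive loading sum.
centered_svd <- function(M, k, reference) {
  if (!all(is.finite(M))) {
    stop_glds("matrix contains non-finite entries; impute before decomposing")
  }
  if (k < 1 || k > min(dim(M))) {
    stop_glds("k must lie in [1, min(m, n)]")
  }
  mu <- colMeans(M)
  sv <- svd(sweep(M, 2, mu))
  varexp <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], nrow = k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    rho <- spearman(scores[, j], reference)
    flip <- if (is.na(rho) || rho == 0) sum(loadings[, j]) < 0 else rho < 0
    if (flip) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  dimnames(scores) <- list(rownames(M), sprintf("PC%d", seq_len(k)))
  dimnames(loadings) <- list(colnames(M), sprintf("PC%d", seq_len(k)))
  list(scores = scores, loadings = loadings,
       variance_explained = varexp[seq_len(k)], center = mu)
}

#' Summarize GLDS by singular value decomposition
#'
#' Column-centers the completed response matrix (drugs share the log-IC50
#' scale, so columns are centered but not scaled) and extracts the first
#' `k` principal components. PC1 is the dominant shared-sensitivity axis.
#' Each component's sign is fixed so that its Spearman correlation with the
#' per-cell-line median IC50 is non-negative: PC1 is a *resistance* axis
#' (high score = generally resistant), making the interpretation
#' deterministic.
#'
#' @param X_completed Dense numeric matrix (e.g. `complete(X)$values`) or a
#'   `completed_matrix`.
#' @param k Number of components, `1 <= k <= min(m, n)`.
#' @return A `glds_components` object: `scores` (cell line x k), `loadings`
#'   (drug x k, unit-norm columns), `variance_explained` (length-k
#'   fractions of total variance), `k`, `center` (column means).
#' @export
glds_decompose <- function(X_completed, k = 10) {
  if (inherits(X_completed, "completed_matrix")) {
    X_completed <- X_completed$values
  }
  med <- apply(X_completed, 1, stats::median)
  out <- centered_svd(X_completed, k, reference = med)
  structure(c(out, list(k = as.integer(k))), class = "glds_components")
}

#' @export
print.glds_components <- function(x, ...) {
  cat(sprintf("glds_components: %d cell lines, %d drugs, k = %d (PC1 %.1f%% of variance)\n",
              nrow(x$scores), nrow(x$loadings), x$k,
              100 * x$variance_explained[1]))
  invisible(x)
}

#' Median drug sensitivity per cell line
#'
#' The simple, highly interpretable alternative to PC1: the per-cell-line
#' median log-IC50 over available drugs.
#'
#' @param X A [drug_response_matrix()] (medians over observed entries) or a
#'   dense matrix (medians over all entries).
#' @return Named numeric vector, one value per cell line.
#' @export
median_sensitivity <- function(X) {
  v <- if (inherits(X, "drug_response_matrix")) X$values else X
  n_avail <- rowSums(!is.na(v))
  if (any(n_avail == 0)) {
    stop_glds("cell line(s) with no available values: ",
              paste(rownames(v)[n_avail == 0], collapse = ", "))
  }
  apply(v, 1, stats::median, na.rm = TRUE)
}

#' Correlate every drug's response with a component score vector
#'
#' Per-drug Spearman correlation between observed log-IC50 values and a
#' per-cell-line score vector (typically PC1), with BH-FDR across drugs.
#' Drugs with fewer than 3 observed entries yield an `NA` row.
#'
#' @param X A [drug_response_matrix()] (or dense matrix).
#' @param scores Numeric score vector aligned to the cell lines of `X`.
#' @return Data frame: `drug`, `n`, `rho`, `p`, `q`.
#' @export
correlate_drugs_with_component <- function(X, scores) {
  v <- if (inherits(X, "drug_response_matrix")) X$values else X
  if (length(scores) != nrow(v)) {
    stop_glds("scores must align to the cell lines of X")
  }
  res <- lapply(seq_len(ncol(v)), function(j) {
    ok <- !is.na(v[, j]) & !is.na(scores)
    n <- sum(ok)
    if (n < 3) {
      message("correlate_drugs_with_component: drug ", colnames(v)[j],
              " has < 3 observed entries; NA row")
      return(data.frame(drug = colnames(v)[j], n = n,
                        rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(v[ok, j], scores[ok],
                                           method = "spearman",
                                           exact = FALSE))
    data.frame(drug = colnames(v)[j], n = n,
               rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Variance in a component explained by tissue of origin
#'
#' Adjusted R-squared of a one-way linear model of the scores on tissue
#' encoded as a factor; quantifies how much of the shared sensitivity axis
#' is mere tissue structure.
#'
#' @param scores Numeric vector of component scores.
#' @param tissue Tissue labels aligned to `scores` (character/factor). If
#'   `scores` has names and `tissue` is named, they are matched by name.
#' @return Adjusted R-squared (scalar).
#' @export
tissue_variance_explained <- function(scores, tissue) {
  if (!is.null(names(scores)) && !is.null(names(tissue))) {
    tissue <- tissue[names(scores)]
  }
  if (length(tissue) != length(scores)) {
    stop_glds("tissue labels must align to scores")
  }
  tf <- factor(tissue)
  if (nlevels(tf) < 2) stop_glds("need at least 2 tissues")
  summary(stats::lm(scores ~ tf))$adj.r.squared
}
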