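#' Pairwise drug-drug correlations on observed entries
#'
#' Correlates every drug pair over the cell lines where both drugs were
#' observed (pairs with fewer than 3 shared observations are `NA`).
#' P values use the standard t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`; BH-FDR is computed over the
#' unique pairs. The summary reports how many pairs reach q < 0.05 and what
#' fraction of those have a positive coefficient — on real screens the
#' positive fraction is overwhelming, the first fingerprint of a shared
#' sensitivity axis.
#'
#' @param X A [drug_response_matrix()] (or dense matrix).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List with `rho`, `p`, `q`, `n` (symmetric matrices) and
#'   `summary` (`n_pairs`, `n_significant`, `positive_fraction`).
#' @export
pairwise_drug_correlations <- function(X, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  v <- if (inherits(X, "drug_response_matrix")) X$values else X
  n_drug <- ncol(v)
  npair_mat <- crossprod(!is.na(v))
  rho <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs",
                                     method = method))
  rho[npair_mat < 3] <- NA_real_
  diag(rho) <- 1
  df <- npair_mat - 2
  df[npair_mat < 3] <- NA_integer_
  r2 <- pmin(rho^2, 1 - 1e-15)
  tstat <- rho * sqrt(df / (1 - r2))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  p[npair_mat < 3] <- NA_real_
  diag(p) <- NA_real_
  ut <- upper.tri(p)
  q <- matrix(NA_real_, n_drug, n_drug, dimnames = dimnames(p))
  q[ut] <- bh_fdr(p[ut])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  sig <- !is.na(q[ut]) & q[ut] < 0.05
  list(rho = rho, p = p, q = q, n = npair_mat,
       summary = list(
         n_pairs = sum(ut),
         n_significant = sum(sig),
         positive_fraction = if (any(sig)) mean(rho[ut][sig] > 0) else NA_real_))
}

#' Select negative-control drugs for a target drug
#'
#' Two-step exclusion: (1) remove every drug sharing the target's
#' mechanism class (case-folded; comma-separated multi-class labels are
#' excluded on any match — conservative, to avoid absorbing drug-specific
#' signal); (2) remove any remaining drug ranked within the top `k_corr`
#' correlations with the target (signed coefficient, descending; ties and
#' `NA`s ranked last, ties broken by drug id). The survivors are the
#' negative controls from which GLDS is estimated for this target.
#'
#' @param target Target drug id.
#' @param annotation Named character vector: drug id -> mechanism class.
#'   Every drug in `corr` must be annotated.
#' @param corr Drug x drug correlation matrix (e.g.
#'   `pairwise_drug_correlations(X)$rho`).
#' @param k_corr How many top-correlated drugs to exclude (default 20, the
#'   convention for a ~140-drug panel; scale it to the panel at hand).
#' @param min_controls Minimum surviving control count (default
#'   `max(30, 3 * 10)`, enough drugs for stable PCs); fewer is an error
#'   advising a smaller `k_corr` or more drugs.
#' @return A `negative_control_set`: `target`, `controls`,
#'   `excluded_by_class`, `excluded_by_correlation`, `k_corr`.
#' @export
select_negative_controls <- function(target, annotation, corr,
                                     k_corr = 20, min_controls = 30) {
  drugs <- colnames(corr)
  if (is.null(drugs)) stop_glds("corr must carry drug ids as dimnames")
  if (!target %in% drugs) stop_glds("target drug ", target, " not in corr")
  missing_ann <- setdiff(drugs, names(annotation))
  if (length(missing_ann)) {
    stop_glds("unannotated drug(s): ", paste(missing_ann, collapse = ", "))
  }
  classes_of <- function(d) {
    trimws(tolower(strsplit(annotation[[d]], ",", fixed = TRUE)[[1]]))
  }
  tgt_classes <- classes_of(target)
  others <- setdiff(drugs, target)
  shares_class <- vapply(others, function(d) {
    any(classes_of(d) %in% tgt_classes)
  }, logical(1))
  excluded_by_class <- others[shares_class]
  remaining <- others[!shares_class]

  excluded_by_correlation <- character(0)
  if (k_corr > 0) {
    rho <- corr[target, others]
    ord <- others[order(-rho, others, na.last = TRUE)]
    top <- ord[seq_len(min(k_corr, length(ord)))]
    excluded_by_correlation <- intersect(remaining, top)
    remaining <- setdiff(remaining, excluded_by_correlation)
  }
  if (length(remaining) < min_controls) {
    stop_glds(sprintf(
      "only %d control drug(s) survive for %s (need >= %d); reduce k_corr or add drugs",
      length(remaining), target, min_controls))
  }
  structure(list(target = target,
                 controls = remaining,
                 excluded_by_class = excluded_by_class,
                 excluded_by_correlation = excluded_by_correlation,
                 k_corr = k_corr),
            class = "negative_control_set")
}

#' @export
print.negative_control_set <- function(x, ...) {
  cat(sprintf("negative_control_set for %s: %d controls (%d excluded by class, %d by correlation, k_corr = %d)\n",
              x$target, length(x$controls), length(x$excluded_by_class),
              length(x$excluded_by_correlation), x$k_corr))
  invisible(x)
}

#' GLDS covariates from a target drug's negative controls
#'
#' Applies the column-centered SVD of [glds_decompose()] to the
#' negative-control submatrix of the completed response matrix and returns
#' the first `n_pcs` score columns — the per-drug GLDS covariates for the
#' corrected association screen. Invariant to the ordering of the control
#' drugs.
#'
#' @param X_completed Dense completed matrix (or `completed_matrix`).
#' @param controls A `negative_control_set` (or character vector of drug
#'   ids).
#' @param n_pcs Number of covariate columns (default 10).
#' @return A `glds_covariates` object: `target`, `covariates`
#'   (cell line x n_pcs matrix), `provenance` (the control set).
#' @export
control_covariates <- function(X_completed, controls, n_pcs = 10) {
  if (inherits(X_completed, "completed_matrix")) {
    X_completed <- X_completed$values
  }
  set <- if (inherits(controls, "negative_control_set")) controls
         else structure(list(target = NA_character_, controls = controls,
                             excluded_by_class = character(0),
                             excluded_by_correlation = character(0),
                             k_corr = NA_integer_),
                        class = "negative_control_set")
  ids <- sort_ids(set$controls)
  absent <- setdiff(ids, colnames(X_completed))
  if (length(absent)) {
    stop_glds("control drug(s) absent from matrix: ",
              paste(absent, collapse = ", "))
  }
  if (n_pcs > length(ids)) {
    stop_glds(sprintf("n_pcs = %d exceeds the %d available control drugs",
                      n_pcs, length(ids)))
  }
  stopifnot(!set$target %in% ids)
  dec <- glds_decompose(X_completed[, ids, drop = FALSE], k = n_pcs)
  cov <- dec$scores
  colnames(cov) <- sprintf("GLDS_PC%d", seq_len(n_pcs))
  structure(list(target = set$target, covariates = cov, provenance = set),
            class = "glds_covariates")
}

#' Build GLDS covariates for every drug of a panel
#'
#' Convenience wrapper running [select_negative_controls()] and
#' [control_covariates()] for each drug column.
#'
#' @param X A [drug_response_matrix()] (observed entries drive the
#'   correlation-based exclusion).
#' @param X_completed Dense completed matrix supplying the covariate PCs.
#' @param annotation Drug id -> mechanism class.
#' @param k_corr,min_controls,n_pcs Passed through.
#' @param method Correlation method for the exclusion ranking.
#' @return Named list of `glds_covariates`, one per drug.
#' @export
covariates_for_all_drugs <- function(X, X_completed, annotation,
                                     k_corr = 20, min_controls = 30,
                                     n_pcs = 10,
                                     method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (inherits(X_completed, "completed_matrix")) {
    X_completed <- X_completed$values
  }
  corr <- pairwise_drug_correlations(X, method = method)$rho
  drugs <- colnames(X_completed)
  out <- lapply(drugs, function(d) {
    ncs <- select_negative_controls(d, annotation, corr,
                                    k_corr = k_corr,
                                    min_controls = min_controls)
    control_covariates(X_completed, ncs, n_pcs = n_pcs)
  })
  stats::setNames(out, drugs)
}
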