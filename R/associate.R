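#' Benjamini-Hochberg FDR q values
#'
#' NA-preserving step-up adjustment: `NA` p values pass through and do not
#' count toward the number of tests.
#'
#' @param p Numeric vector of p values in `[0, 1]` (`NA` allowed).
#' @return q values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_glds("p values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Test one mutation-drug association
#'
#' Ordinary-least-squares fit of the response on an intercept, the binary
#' mutation indicator and optional covariates; the effect is the mutation
#' coefficient (log-IC50 units, positive = mutation confers resistance)
#' with a two-sided t-test p value. Cell lines with missing response (or
#' covariates) are dropped; if either genotype group then has fewer than
#' `min_group` members the pair is returned untested (`NA` p), not an
#' error. Aliased (collinear) covariates are dropped by the rank-revealing
#' fit.
#'
#' @param y Per-cell-line response vector (`NA` = unscreened).
#' @param g Binary mutation vector aligned to `y`.
#' @param covariates Optional numeric matrix aligned to `y`.
#' @param min_group Minimum mutant and wild-type group size (default 3).
#' @return One-row data frame: `effect`, `p`, `n_mut`, `n_wt`, `tested`.
#' @export
test_association <- function(y, g, covariates = NULL, min_group = 3) {
  if (length(g) != length(y)) stop_glds("y and g must align")
  keep <- !is.na(y) & !is.na(g)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(y)) {
      stop_glds("covariates must align to y")
    }
    keep <- keep & stats::complete.cases(covariates)
  }
  yk <- y[keep]; gk <- g[keep]
  n_mut <- sum(gk == 1); n_wt <- sum(gk == 0)
  untested <- data.frame(effect = NA_real_, p = NA_real_,
                         n_mut = n_mut, n_wt = n_wt, tested = FALSE)
  if (n_mut < min_group || n_wt < min_group) return(untested)
  design <- if (is.null(covariates)) {
    data.frame(y = yk, g = gk)
  } else {
    data.frame(y = yk, g = gk, covariates[keep, , drop = FALSE])
  }
  fit <- stats::lm(y ~ ., data = design)
  sm <- summary(fit)$coefficients
  if (!"g" %in% rownames(sm)) return(untested)  # g aliased with covariates
  data.frame(effect = sm["g", "Estimate"], p = sm["g", "Pr(>|t|)"],
             n_mut = n_mut, n_wt = n_wt, tested = TRUE)
}

#' Run a mutation-drug association screen
#'
#' Tests every (gene, drug) pair with [test_association()] under one of
#' four models: `uncorrected` (no covariates), `glds` (the drug's
#' negative-control PC covariates), `tissue` (tissue-of-origin indicator
#' covariates, reference = most frequent tissue), or
#' `expression_signature` (signature PC covariates shared across drugs).
#' Only observed response entries enter each regression. BH-FDR is
#' computed over all tested pairs of the screen; rows are ordered by drug,
#' then gene.
#'
#' @param X A [drug_response_matrix()] (or dense matrix).
#' @param M A [mutation_matrix()] aligned to the same cell lines.
#' @param mode One of `"uncorrected"`, `"glds"`, `"tissue"`,
#'   `"expression_signature"`.
#' @param covariates For `mode = "glds"`: named list of `glds_covariates`
#'   (or matrices), one per drug, as from [covariates_for_all_drugs()].
#' @param tissue For `mode = "tissue"`: named tissue labels.
#' @param signature_covariates For `mode = "expression_signature"`: a
#'   cell line x PC matrix from [signature_covariates()].
#' @param min_group Minimum group size per tested pair.
#' @return Data frame (`association_table`): `gene`, `drug`, `model`,
#'   `effect`, `p`, `q`, `n_mut`, `n_wt`.
#' @export
run_screen <- function(X, M,
                       mode = c("uncorrected", "glds", "tissue",
                                "expression_signature"),
                       covariates = NULL, tissue = NULL,
                       signature_covariates = NULL, min_group = 3) {
  mode <- match.arg(mode)
  v <- if (inherits(X, "drug_response_matrix")) X$values else X
  calls <- if (inherits(M, "mutation_matrix")) M$calls else M
  stopifnot(identical(rownames(v), rownames(calls)))

  tissue_cov <- NULL
  if (mode == "tissue") {
    if (is.null(tissue)) stop_glds("tissue mode needs tissue labels")
    tl <- tissue[rownames(v)]
    lev <- names(sort(table(tl), decreasing = TRUE))
    tf <- factor(tl, levels = lev)
    tissue_cov <- if (nlevels(tf) >= 2) {
      stats::model.matrix(~ tf)[, -1, drop = FALSE]
    } else NULL  # one tissue: degenerate, equals uncorrected
  }
  if (mode == "expression_signature") {
    if (is.null(signature_covariates)) {
      stop_glds("expression_signature mode needs signature covariates")
    }
    signature_covariates <- as.matrix(signature_covariates)
    signature_covariates <- signature_covariates[rownames(v), , drop = FALSE]
  }

  rows <- vector("list", ncol(v) * ncol(calls))
  idx <- 1L
  for (j in seq_len(ncol(v))) {
    drug <- colnames(v)[j]
    covs <- switch(mode,
      uncorrected = NULL,
      glds = {
        cj <- covariates[[drug]]
        if (is.null(cj)) stop_glds("no GLDS covariates supplied for drug ", drug)
        cm <- if (inherits(cj, "glds_covariates")) cj$covariates else as.matrix(cj)
        cm[rownames(v), , drop = FALSE]
      },
      tissue = tissue_cov,
      expression_signature = signature_covariates)
    for (gidx in seq_len(ncol(calls))) {
      res <- test_association(v[, j], calls[, gidx], covs,
                              min_group = min_group)
      rows[[idx]] <- data.frame(gene = colnames(calls)[gidx], drug = drug,
                                model = mode, effect = res$effect, p = res$p,
                                n_mut = res$n_mut, n_wt = res$n_wt)
      idx <- idx + 1L
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[, c("gene", "drug", "model", "effect", "p", "q",
                 "n_mut", "n_wt")]
  rownames(out) <- NULL
  out
}

#' Elastic-net biomarker screen
#'
#' Per drug, an elastic-net fit (`alpha = 0.5`) of the observed response on
#' all mutation indicators plus the drug's GLDS covariates; the GLDS
#' covariates are unpenalized (they are nuisance adjustments, not candidate
#' biomarkers). The penalty is chosen by internal cross-validation with a
#' deterministic fold assignment from `seed`. Returns the mutations with
#' nonzero weights.
#'
#' @param X A [drug_response_matrix()] (or dense matrix).
#' @param M A [mutation_matrix()].
#' @param covariates Optional named list of per-drug GLDS covariates.
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @param seed Integer seed for CV folds.
#' @param nfolds CV fold count (default 5).
#' @return Data frame: `drug`, `gene`, `weight` (nonzero mutation weights
#'   only).
#' @export
elasticnet_screen <- function(X, M, covariates = NULL, alpha = 0.5,
                              seed = 1, nfolds = 5) {
  v <- if (inherits(X, "drug_response_matrix")) X$values else X
  calls <- if (inherits(M, "mutation_matrix")) M$calls else M
  stopifnot(identical(rownames(v), rownames(calls)))
  out <- list()
  for (j in seq_len(ncol(v))) {
    drug <- colnames(v)[j]
    obs <- !is.na(v[, j])
    covs <- NULL
    if (!is.null(covariates)) {
      cj <- covariates[[drug]]
      if (is.null(cj)) stop_glds("no GLDS covariates supplied for drug ", drug)
      covs <- if (inherits(cj, "glds_covariates")) cj$covariates else as.matrix(cj)
      covs <- covs[rownames(v), , drop = FALSE]
    }
    design <- cbind(calls, covs)[obs, , drop = FALSE]
    pf <- c(rep(1, ncol(calls)), rep(0, if (is.null(covs)) 0 else ncol(covs)))
    y <- v[obs, j]
    if (length(y) < nfolds + 3 || stats::var(y) == 0) next
    foldid <- with_rng(derive_seed(seed, "enet", j),
                       sample(rep_len(seq_len(nfolds), length(y))))
    cv <- cv.glmnet_quiet(design, y, alpha = alpha, penalty.factor = pf,
                          foldid = foldid, grouped = length(y) >= 3L * nfolds)
    # one-SE rule: parsimonious selection, near-empty under the null
    b <- as.numeric(stats::coef(cv$glmnet.fit, s = cv$lambda.1se))[-1]
    bm <- b[seq_len(ncol(calls))]
    nz <- which(bm != 0)
    if (length(nz)) {
      out[[drug]] <- data.frame(drug = drug, gene = colnames(calls)[nz],
                                weight = bm[nz])
    }
  }
  if (!length(out)) {
    return(data.frame(drug = character(0), gene = character(0),
                      weight = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-study concordance of association hits
#'
#' Among discovery-phase hits (q below `q_disc`), the fraction validated in
#' an independent screen at nominal significance (`p` below `p_val`) with
#' the same effect sign — the positive predictive value used to compare
#' corrected and uncorrected screens across studies.
#'
#' @param discovery,validation Association tables from [run_screen()]
#'   sharing a (gene, drug) universe.
#' @param q_disc Discovery FDR threshold (default 0.05).
#' @param p_val Validation nominal p threshold (default 0.05).
#' @return List: `ppv` (proportion; `NA` if no discovery hits), `n_hits`,
#'   `n_validated`, `hits` (merged data frame of the discovery hits).
#' @export
concordance <- function(discovery, validation, q_disc = 0.05, p_val = 0.05) {
  key <- function(d) paste(d$gene, d$drug, sep = "\r")
  merged <- merge(discovery, validation, by = c("gene", "drug"),
                  suffixes = c(".disc", ".val"))
  hits <- merged[!is.na(merged$q.disc) & merged$q.disc < q_disc, ]
  if (!nrow(hits)) {
    message("concordance: no discovery hits at q < ", q_disc)
    return(list(ppv = NA_real_, n_hits = 0L, n_validated = 0L, hits = hits))
  }
  validated <- !is.na(hits$p.val) & hits$p.val < p_val &
    sign(hits$effect.val) == sign(hits$effect.disc)
  list(ppv = mean(validated),
       n_hits = nrow(hits),
       n_validated = sum(validated),
       hits = cbind(hits, validated = validated))
}
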