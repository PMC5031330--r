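# Pair-level truth labels for an association table: a row is a true effect
# only if its gene is a specific-effect gene tested against its designated
# drug; confounded-null genes are null for every drug.
pair_truth <- function(tab, mutation_truth) {
  tr <- mutation_truth[match(tab$gene, mutation_truth$gene), ]
  lab <- ifelse(tr$truth == "confounded_null", "confounded_null", "null")
  eff <- tr$truth == "specific" & !is.na(tr$drug) & tr$drug == tab$drug
  lab[eff] <- "effect"
  lab
}

#' Power at a matched empirical false-discovery rate
#'
#' Orders tested pairs by p value and finds the largest hit prefix whose
#' realized FDR (false pairs / prefix size, using truth labels) does not
#' exceed `target_fdr`; power is the fraction of all true-effect pairs
#' inside that prefix. Comparing modes at matched *realized* FDR avoids
#' distortion from differing null calibration.
#'
#' @param tab Association table from [run_screen()].
#' @param mutation_truth Truth table from [simulate_screen()].
#' @param target_fdr Realized FDR to match (default 0.05).
#' @return List: `power`, `n_hits`, `n_true`, `realized_fdr`.
#' @export
matched_fdr_power <- function(tab, mutation_truth, target_fdr = 0.05) {
  lab <- pair_truth(tab, mutation_truth)
  ok <- !is.na(tab$p)
  p <- tab$p[ok]; is_true <- lab[ok] == "effect"
  n_true <- sum(lab == "effect")
  if (!length(p) || n_true == 0) {
    return(list(power = NA_real_, n_hits = 0L, n_true = n_true,
                realized_fdr = NA_real_))
  }
  ord <- order(p)
  cum_fp <- cumsum(!is_true[ord])
  fdr_at <- cum_fp / seq_along(ord)
  k <- suppressWarnings(max(which(fdr_at <= target_fdr)))
  if (!is.finite(k) || k < 1) {
    return(list(power = 0, n_hits = 0L, n_true = n_true, realized_fdr = 0))
  }
  list(power = sum(is_true[ord][seq_len(k)]) / n_true,
       n_hits = as.integer(k),
       n_true = n_true,
       realized_fdr = fdr_at[k])
}

#' Simulation-based evaluation of the correction pipeline
#'
#' For each replicate: simulate a screen, complete the response matrix if
#' it has missing entries, build per-drug negative-control GLDS covariates
#' (and, if requested, the expression-signature covariates), run the
#' association screen under each mode, and score the results against the
#' simulation ground truth — type-I error at `alpha` on confounded-null
#' and pure-null pairs, q < `fdr` hit counts split by truth label, and
#' power at matched realized FDR. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()]; replicate `r` uses a child seed of
#'   `config$seed`.
#' @param replicates Number of independent replicate screens.
#' @param modes Subset of `c("uncorrected", "glds", "tissue",
#'   "expression_signature")`.
#' @param alpha Nominal level for type-I error rates (default 0.05).
#' @param fdr FDR threshold for hit counts and the matched-power target
#'   (default 0.05).
#' @param k_corr,min_controls,n_pcs Negative-control parameters, scaled to
#'   the simulated panel (defaults: `k_corr = 5`, `min_controls = 20`,
#'   `n_pcs = 10` for a 60-drug panel).
#' @param top_n Genes per PC for the signature derivation.
#' @param impute_cfg An [impute_config()] used when the simulated screen
#'   has missing entries.
#' @return An `evaluation_report`: `per_replicate` (data frame of
#'   per-mode, per-replicate metrics), `summary` (means and Monte-Carlo
#'   standard errors across replicates), `pooled` (rates pooled over all
#'   tests), `config`, `seeds`.
#' @export
run_evaluation <- function(config, replicates = 5,
                           modes = c("uncorrected", "glds"),
                           alpha = 0.05, fdr = 0.05,
                           k_corr = 5, min_controls = 20, n_pcs = 10,
                           top_n = 50,
                           impute_cfg = impute_config(max_iter = 4)) {
  stopifnot(inherits(config, "sim_config"), replicates >= 1)
  modes <- match.arg(modes, c("uncorrected", "glds", "tissue",
                              "expression_signature"), several.ok = TRUE)
  seeds <- vapply(seq_len(replicates), function(r)
    derive_seed(config$seed, "rep", r), integer(1))
  per_rep <- list()
  counts <- list()
  impute_rows <- list()

  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- seeds[r]
    ds <- simulate_screen(cfg)
    has_missing <- any(!ds$response$mask)
    if (has_missing) {
      comp <- complete(ds$response, impute_cfg)
      completed <- comp$values
      hidden <- !ds$response$mask
      truth_v <- ds$response_full[hidden]
      base <- initialize_missing(ds$response)[hidden]
      impute_rows[[r]] <- data.frame(
        replicate = r,
        imputation_r2 = stats::cor(truth_v, completed[hidden])^2,
        baseline_r2 = stats::cor(truth_v, base)^2,
        n_masked = sum(hidden))
      response_for_screen <- ds$response
    } else {
      completed <- ds$response_full
      response_for_screen <- ds$response
    }

    covs <- NULL
    if (any(modes %in% c("glds", "expression_signature"))) {
      covs <- covariates_for_all_drugs(ds$response, completed,
                                       ds$annotation, k_corr = k_corr,
                                       min_controls = min_controls,
                                       n_pcs = n_pcs)
    }
    sig_cov <- NULL
    if ("expression_signature" %in% modes) {
      sig <- signature_from_covariates(ds$expression, covs, top_n = top_n)
      sig_cov <- signature_covariates(ds$expression, sig, n_pcs = n_pcs)
    }

    for (mode in modes) {
      tab <- run_screen(response_for_screen, ds$mutations, mode = mode,
                        covariates = covs, tissue = ds$tissue,
                        signature_covariates = sig_cov)
      lab <- pair_truth(tab, ds$mutation_truth)
      tested <- !is.na(tab$p)
      rate <- function(cls) {
        n <- sum(tested & lab == cls)
        if (!n) NA_real_ else sum(tested & lab == cls & tab$p < alpha) / n
      }
      hits <- function(cls) sum(tested & lab == cls & !is.na(tab$q) &
                                  tab$q < fdr)
      pw <- matched_fdr_power(tab, ds$mutation_truth, target_fdr = fdr)
      per_rep[[length(per_rep) + 1L]] <- data.frame(
        replicate = r, mode = mode,
        typeI_confounded = rate("confounded_null"),
        typeI_null = rate("null"),
        hits_confounded = hits("confounded_null"),
        hits_null = hits("null"),
        hits_effect = hits("effect"),
        power_matched_fdr = pw$power,
        n_tested = sum(tested))
      counts[[length(counts) + 1L]] <- data.frame(
        mode = mode,
        rej_confounded = sum(tested & lab == "confounded_null" &
                               tab$p < alpha),
        n_confounded = sum(tested & lab == "confounded_null"),
        rej_null = sum(tested & lab == "null" & tab$p < alpha),
        n_null = sum(tested & lab == "null"))
    }
  }

  per_replicate <- do.call(rbind, per_rep)
  agg <- do.call(rbind, lapply(split(per_replicate, per_replicate$mode),
    function(d) {
      num <- d[, setdiff(names(d), c("replicate", "mode"))]
      data.frame(mode = d$mode[1],
                 t(colMeans(num, na.rm = TRUE)),
                 se_typeI_confounded = stats::sd(d$typeI_confounded) /
                   sqrt(nrow(d)),
                 se_power = stats::sd(d$power_matched_fdr) / sqrt(nrow(d)))
    }))
  cts <- do.call(rbind, counts)
  pooled <- do.call(rbind, lapply(split(cts, cts$mode), function(d) {
    data.frame(mode = d$mode[1],
               typeI_confounded = sum(d$rej_confounded) / sum(d$n_confounded),
               n_confounded_tests = sum(d$n_confounded),
               typeI_null = sum(d$rej_null) / sum(d$n_null),
               n_null_tests = sum(d$n_null))
  }))
  rownames(agg) <- rownames(pooled) <- NULL
  structure(list(per_replicate = per_replicate,
                 summary = agg,
                 pooled = pooled,
                 imputation = if (length(impute_rows))
                   do.call(rbind, impute_rows) else NULL,
                 config = config, seeds = seeds,
                 alpha = alpha, fdr = fdr),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %d replicate(s), modes: %s\n",
              length(x$seeds), paste(unique(x$summary$mode), collapse = ", ")))
  print(x$pooled)
  invisible(x)
}
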