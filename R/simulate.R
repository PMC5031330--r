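#' Configuration for a synthetic drug screen
#'
#' Defines the generative model for a cell-line x drug screen with a known
#' general-level-of-drug-sensitivity (GLDS) axis. Drug response is
#' \deqn{X_{ij} = l_j f_i + \sum_{r>1} w_{jr} z_{ir} + c_{\,class(j),i} +
#'   t_{\,tissue(i),j} + \epsilon_{ij}}
#' where `f` is the latent GLDS factor (standard normal across cell lines),
#' the factor-1 drug loadings `l_j` are all positive (GLDS acts as shared
#' resistance/sensitivity) and are rescaled so the population variance share
#' of factor 1 equals `glds_variance_share` exactly, factors 2..k_latent are
#' mechanism-independent secondary axes, `c` are drug-class shared effects,
#' `t` are tissue-by-drug offsets and `epsilon` is iid Gaussian noise.
#'
#' Mutated genes come in three truth classes: *confounded-null* genes whose
#' mutation probability is logistic in the GLDS factor but which have no
#' drug-specific effect (the in-silico analogue of a spurious biomarker),
#' *specific-effect* genes mutated independently of GLDS that shift one
#' designated drug's response by `specific_beta`, and *pure-null* genes.
#' Expression contains `n_glds_genes` genes loading on the GLDS factor with
#' magnitude `expr_loading_sd` (random sign) plus unit Gaussian noise, and
#' pure-noise genes.
#'
#' @param m Cell-line count.
#' @param n_drugs Drug count.
#' @param k_latent Number of latent sensitivity factors (factor 1 = GLDS).
#' @param glds_variance_share Fraction of drug-response variance carried by
#'   factor 1, in `[0, 1)`.
#' @param n_classes Number of drug mechanism classes (drugs assigned
#'   cyclically).
#' @param class_effect_sd SD of the within-class shared effect.
#' @param factor_sd SD of loadings of factors 2..k_latent.
#' @param noise_sd Residual noise SD (log-IC50 units).
#' @param missing_fraction MCAR missingness fraction, in `[0, 1)`.
#' @param n_tissues,tissue_effect_sd Tissue count and SD of the
#'   tissue-by-drug offsets.
#' @param n_confounded,confounded_intercept,confounded_slope Confounded-null
#'   gene count and the logistic model `P(mut) = plogis(a + b f)`. The
#'   default (a = -1.4, b = 2) separates mutant and wild-type GLDS means by
#'   more than one SD at a ~25% mutation frequency.
#' @param n_specific,specific_beta Specific-effect gene count and their
#'   effect (log-IC50 units, positive = resistance) on one designated drug
#'   each (drugs assigned cyclically).
#' @param n_null Pure-null gene count.
#' @param mutation_freq Mutation frequency of specific and null genes.
#' @param n_genes,n_glds_genes,expr_loading_sd Expression gene counts and
#'   the planted loading magnitude of the GLDS-linked genes.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(m = 200, n_drugs = 60, k_latent = 3,
                       glds_variance_share = 0.6,
                       n_classes = 6, class_effect_sd = 0.3,
                       factor_sd = 0.3, noise_sd = 0.5,
                       missing_fraction = 0.2,
                       n_tissues = 8, tissue_effect_sd = 0.2,
                       n_confounded = 4, confounded_intercept = -1.4,
                       confounded_slope = 2,
                       n_specific = 4, specific_beta = 1,
                       n_null = 12, mutation_freq = 0.15,
                       n_genes = 18000, n_glds_genes = 20,
                       expr_loading_sd = 1, seed = 1) {
  cfg <- as.list(environment())
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop_glds("missing_fraction must be in [0, 1)")
  }
  if (glds_variance_share < 0 || glds_variance_share >= 1) {
    stop_glds("glds_variance_share must be in [0, 1)")
  }
  if (m < 4 || n_drugs < 2 || k_latent < 1 || n_classes < 1 || n_tissues < 1) {
    stop_glds("infeasible config: counts must be positive (m >= 4, n_drugs >= 2)")
  }
  if (n_glds_genes > n_genes) {
    stop_glds("infeasible config: n_glds_genes > n_genes")
  }
  structure(cfg, class = "sim_config")
}

#' Mask entries of a complete response matrix completely at random
#'
#' Masks exactly `round(fraction * m * n)` entries, chosen uniformly without
#' replacement, under the guard that every drug column keeps at least 2
#' observed entries (offending draws are repaired by reassigning masked
#' cells to columns with spare capacity).
#'
#' @param values Complete numeric matrix with dimnames.
#' @param fraction Fraction of entries to mask, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A [drug_response_matrix()].
#' @export
mask_entries <- function(values, fraction, seed = 1) {
  if (fraction < 0 || fraction >= 1) stop_glds("fraction must be in [0, 1)")
  m <- nrow(values); n <- ncol(values)
  n_mask <- round(fraction * m * n)
  if (n_mask > n * (m - 2L)) {
    stop_glds("fraction ", fraction,
              " infeasible: cannot keep 2 observed entries per column")
  }
  if (n_mask == 0) return(drug_response_matrix(values))
  with_rng(derive_seed(seed, "mask"), {
    masked <- matrix(FALSE, m, n)
    masked[sample.int(m * n, n_mask)] <- TRUE
    # repair columns left with < 2 observed entries
    repeat {
      obs_per_col <- m - colSums(masked)
      off <- which(obs_per_col < 2L)
      if (!length(off)) break
      col <- off[1]
      from <- which(masked[, col])
      unmask <- sample(from, 1L)
      masked[unmask, col] <- FALSE
      roomy <- which(obs_per_col > 2L)
      tgt_col <- roomy[sample.int(length(roomy), 1L)]
      free <- which(!masked[, tgt_col])
      masked[free[sample.int(length(free), 1L)], tgt_col] <- TRUE
    }
    out <- values
    out[masked] <- NA_real_
    drug_response_matrix(out)
  })
}

#' Generate a synthetic screen with known GLDS ground truth
#'
#' Draws a complete response matrix from the model described in
#' [sim_config()], applies MCAR masking, and generates mutation, expression
#' and tissue tables with per-gene truth labels. Bit-reproducible from the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_screen` list: `response` (masked
#'   [drug_response_matrix()]), `response_full` (pre-masking matrix),
#'   `glds_factor` (named true latent scores), `mutations`
#'   ([mutation_matrix()]), `mutation_truth` (data frame: gene, truth in
#'   \{confounded_null, specific, null\}, beta, target drug), `expression`
#'   ([expression_matrix()]), `glds_genes` (planted gene ids), `tissue`
#'   (named labels), `annotation` (drug id -> mechanism class), `config`.
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  cl_ids <- sprintf("CL%03d", seq_len(cf$m))
  drug_ids <- sprintf("drug_%02d", seq_len(cf$n_drugs))
  classes <- sprintf("class_%d", rep_len(seq_len(cf$n_classes), cf$n_drugs))
  annotation <- stats::setNames(classes, drug_ids)
  tissues <- sprintf("tissue_%02d", rep_len(seq_len(cf$n_tissues), cf$m))

  with_rng(derive_seed(cf$seed, "screen"), {
    f <- stats::rnorm(cf$m)
    tissue <- stats::setNames(sample(tissues), cl_ids)

    # residual variance budget per entry, excluding factor 1
    rest_var <- (cf$k_latent - 1) * cf$factor_sd^2 + cf$class_effect_sd^2 +
      cf$tissue_effect_sd^2 + cf$noise_sd^2
    l_raw <- abs(stats::rnorm(cf$n_drugs, mean = 1, sd = 0.25))
    if (cf$glds_variance_share > 0) {
      target <- cf$glds_variance_share / (1 - cf$glds_variance_share) * rest_var
      l <- l_raw * sqrt(target / mean(l_raw^2))
    } else {
      l <- rep(0, cf$n_drugs)
    }

    X <- outer(f, l)
    if (cf$k_latent > 1) {
      Z <- matrix(stats::rnorm(cf$m * (cf$k_latent - 1)), cf$m)
      W <- matrix(stats::rnorm(cf$n_drugs * (cf$k_latent - 1),
                               sd = cf$factor_sd), cf$n_drugs)
      X <- X + Z %*% t(W)
    }
    if (cf$class_effect_sd > 0) {
      H <- matrix(stats::rnorm(cf$m * cf$n_classes, sd = cf$class_effect_sd),
                  cf$m, cf$n_classes,
                  dimnames = list(NULL, sprintf("class_%d", seq_len(cf$n_classes))))
      X <- X + H[, classes]
    }
    if (cf$tissue_effect_sd > 0) {
      Teff <- matrix(stats::rnorm(cf$n_tissues * cf$n_drugs,
                                  sd = cf$tissue_effect_sd),
                     cf$n_tissues, cf$n_drugs,
                     dimnames = list(sprintf("tissue_%02d", seq_len(cf$n_tissues)),
                                     NULL))
      X <- X + Teff[tissue, ]
    }
    X <- X + matrix(stats::rnorm(cf$m * cf$n_drugs, sd = cf$noise_sd), cf$m)
    dimnames(X) <- list(cl_ids, drug_ids)

    # mutations with truth labels
    genes <- character(0); truth <- character(0)
    beta <- numeric(0); tgt <- character(0)
    calls <- NULL
    if (cf$n_confounded > 0) {
      p <- stats::plogis(cf$confounded_intercept + cf$confounded_slope * f)
      cc <- vapply(seq_len(cf$n_confounded),
                   function(g) stats::rbinom(cf$m, 1L, p), integer(cf$m))
      calls <- cbind(calls, cc)
      genes <- c(genes, sprintf("g_conf_%02d", seq_len(cf$n_confounded)))
      truth <- c(truth, rep("confounded_null", cf$n_confounded))
      beta <- c(beta, rep(0, cf$n_confounded))
      tgt <- c(tgt, rep(NA_character_, cf$n_confounded))
    }
    if (cf$n_specific > 0) {
      sp_drugs <- drug_ids[rep_len(seq_len(cf$n_drugs), cf$n_specific)]
      for (g in seq_len(cf$n_specific)) {
        mut <- stats::rbinom(cf$m, 1L, cf$mutation_freq)
        X[, sp_drugs[g]] <- X[, sp_drugs[g]] + cf$specific_beta * mut
        calls <- cbind(calls, mut)
      }
      genes <- c(genes, sprintf("g_spec_%02d", seq_len(cf$n_specific)))
      truth <- c(truth, rep("specific", cf$n_specific))
      beta <- c(beta, rep(cf$specific_beta, cf$n_specific))
      tgt <- c(tgt, sp_drugs)
    }
    if (cf$n_null > 0) {
      nn <- vapply(seq_len(cf$n_null),
                   function(g) stats::rbinom(cf$m, 1L, cf$mutation_freq),
                   integer(cf$m))
      calls <- cbind(calls, nn)
      genes <- c(genes, sprintf("g_null_%02d", seq_len(cf$n_null)))
      truth <- c(truth, rep("null", cf$n_null))
      beta <- c(beta, rep(0, cf$n_null))
      tgt <- c(tgt, rep(NA_character_, cf$n_null))
    }
    dimnames(calls) <- list(cl_ids, genes)
    mutation_truth <- data.frame(gene = genes, truth = truth, beta = beta,
                                 drug = tgt, stringsAsFactors = FALSE)

    # expression: planted GLDS-linked genes plus pure noise genes
    expr_ids <- sprintf("EXP%04d", seq_len(cf$n_genes))
    glds_genes <- expr_ids[seq_len(cf$n_glds_genes)]
    E <- matrix(stats::rnorm(cf$m * cf$n_genes), cf$m, cf$n_genes,
                dimnames = list(cl_ids, expr_ids))
    if (cf$n_glds_genes > 0) {
      lam <- sample(c(-1, 1), cf$n_glds_genes, replace = TRUE) *
        cf$expr_loading_sd
      E[, glds_genes] <- E[, glds_genes] + outer(f, lam)
    }

    response <- mask_entries(X, cf$missing_fraction,
                             seed = derive_seed(cf$seed, "maskstep"))

    structure(list(
      response = response,
      response_full = X,
      glds_factor = stats::setNames(f, cl_ids),
      mutations = mutation_matrix(calls),
      mutation_truth = mutation_truth,
      expression = expression_matrix(E),
      glds_genes = glds_genes,
      tissue = tissue,
      annotation = annotation,
      config = cf
    ), class = "synthetic_screen")
  })
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat(sprintf(
    "synthetic_screen: %d cell lines x %d drugs (%.0f%% missing), %d genes mutated, %d expression genes\n",
    nrow(x$response_full), ncol(x$response_full),
    100 * mean(!x$response$mask), ncol(x$mutations$calls),
    ncol(x$expression$values)))
  invisible(x)
}
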