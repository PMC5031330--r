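#' Rank expression genes against one drug's GLDS covariates
#'
#' For each of the drug's GLDS PCs, genes are ranked by absolute Spearman
#' correlation between their expression and the PC scores; the `top_n`
#' genes per PC are taken and the per-PC lists unioned (so at most
#' `top_n * n_pcs` genes per drug). Absolute correlation is used because
#' both resistance- and sensitivity-associated genes are informative
#' proxies. Ties at the `top_n` boundary are broken by gene id. Genes
#' flagged zero-variance are excluded (logged).
#'
#' @param expression An [expression_matrix()].
#' @param covs A `glds_covariates` object (or cell line x PC matrix)
#'   aligned to the expression cell lines.
#' @param top_n Genes kept per PC (default 50).
#' @param absolute Rank by `|rho|` (default) or signed `rho`.
#' @return Character vector of selected gene ids with attribute
#'   `"provenance"`: a data frame (gene, pc, rho) of every (gene, PC)
#'   selection.
#' @export
rank_genes_per_drug <- function(expression, covs, top_n = 50,
                                absolute = TRUE) {
  E <- if (inherits(expression, "expression_matrix")) expression$values
       else expression
  cm <- if (inherits(covs, "glds_covariates")) covs$covariates
        else as.matrix(covs)
  stopifnot(identical(rownames(E), rownames(cm)))
  zv <- if (inherits(expression, "expression_matrix"))
    expression$zero_variance else character(0)
  if (length(zv)) {
    message("rank_genes_per_drug: excluding ", length(zv),
            " zero-variance gene(s)")
    E <- E[, setdiff(colnames(E), zv), drop = FALSE]
  }
  # Spearman = Pearson on ranks; one matrix product per drug
  Er <- apply(E, 2, rank)
  top_genes_from_ranks(Er, cm, top_n = top_n, absolute = absolute)
}

# Shared core: Er = rank-transformed expression (cell line x gene),
# cm = covariate matrix for one drug.
top_genes_from_ranks <- function(Er, cm, top_n, absolute = TRUE) {
  Cr <- apply(cm, 2, rank)
  rho <- stats::cor(Er, Cr)
  prov <- list()
  for (k in seq_len(ncol(rho))) {
    score <- if (absolute) abs(rho[, k]) else rho[, k]
    ord <- order(-score, colnames(Er))
    top <- ord[seq_len(min(top_n, length(ord)))]
    prov[[k]] <- data.frame(gene = colnames(Er)[top],
                            pc = colnames(cm)[k] %||% sprintf("PC%d", k),
                            rho = rho[top, k])
  }
  prov <- do.call(rbind, prov)
  genes <- sort_ids(unique(prov$gene))
  attr(genes, "provenance") <- prov
  genes
}

#' Derive the GLDS signature from per-drug covariates in one step
#'
#' Convenience wrapper equivalent to calling [rank_genes_per_drug()] for
#' every drug and intersecting with [derive_signature()], but
#' rank-transforming the expression matrix only once.
#'
#' @param expression An [expression_matrix()].
#' @param covariates Named list of `glds_covariates` (or matrices), one
#'   per drug.
#' @param top_n Genes kept per PC (default 50).
#' @param absolute Rank by `|rho|` (default) or signed `rho`.
#' @return A `signature_gene_set` (see [derive_signature()]).
#' @export
signature_from_covariates <- function(expression, covariates, top_n = 50,
                                      absolute = TRUE) {
  E <- if (inherits(expression, "expression_matrix")) expression$values
       else expression
  zv <- if (inherits(expression, "expression_matrix"))
    expression$zero_variance else character(0)
  if (length(zv)) E <- E[, setdiff(colnames(E), zv), drop = FALSE]
  Er <- apply(E, 2, rank)
  lists <- lapply(covariates, function(cv) {
    cm <- if (inherits(cv, "glds_covariates")) cv$covariates
          else as.matrix(cv)
    top_genes_from_ranks(Er, cm, top_n = top_n, absolute = absolute)
  })
  derive_signature(lists)
}

#' Derive the GLDS expression signature
#'
#' Intersects the per-drug gene lists: a gene enters the signature only if
#' it was selected for *every* drug — i.e. it tracks the shared sensitivity
#' axis no matter which drug's negative controls defined it. Invariant to
#' drug ordering and idempotent.
#'
#' @param per_drug_lists List (>= 2 elements) of character vectors from
#'   [rank_genes_per_drug()].
#' @return A `signature_gene_set`: `genes` (sorted ids), `selection_count`
#'   (= number of drugs, for every member), `n_drugs`.
#' @export
derive_signature <- function(per_drug_lists) {
  if (length(per_drug_lists) < 2) {
    stop_glds("derive_signature needs lists from at least 2 drugs")
  }
  lists <- lapply(per_drug_lists, unique)
  counts <- table(unlist(lists))
  n_drugs <- length(lists)
  genes <- sort_ids(names(counts)[counts == n_drugs])
  if (!length(genes)) {
    top <- utils::head(sort(counts, decreasing = TRUE), 10)
    stop_glds("empty signature: no gene selected for all ", n_drugs,
              " drugs; increase top_n. Highest selection counts: ",
              paste(sprintf("%s=%d", names(top), top), collapse = ", "))
  }
  structure(list(genes = genes,
                 selection_count = stats::setNames(
                   rep(n_drugs, length(genes)), genes),
                 n_drugs = n_drugs),
            class = "signature_gene_set")
}

#' @export
print.signature_gene_set <- function(x, ...) {
  cat(sprintf("signature_gene_set: %d genes selected for all %d drugs\n",
              length(x$genes), x$n_drugs))
  invisible(x)
}

#' Expression-based GLDS proxy covariates
#'
#' Principal-component scores (column-centered SVD) of the signature-gene
#' expression submatrix; usable as confounder covariates when no large
#' drug panel is available. Component signs are oriented against the mean
#' expression of the gene set.
#'
#' @param expression An [expression_matrix()].
#' @param genes A `signature_gene_set` or character vector of gene ids.
#'   Genes absent from the expression matrix are dropped with a warning;
#'   fewer than `n_pcs` available genes is an error.
#' @param n_pcs Number of covariate columns (default 10).
#' @return Cell line x `n_pcs` numeric matrix (columns `SIG_PC1`...).
#' @export
signature_covariates <- function(expression, genes, n_pcs = 10) {
  E <- if (inherits(expression, "expression_matrix")) expression$values
       else expression
  ids <- if (inherits(genes, "signature_gene_set")) genes$genes else genes
  present <- intersect(ids, colnames(E))
  if (length(present) < length(ids)) {
    warning(sprintf("signature_covariates: %d signature gene(s) absent from expression",
                    length(ids) - length(present)), call. = FALSE)
  }
  if (length(present) < n_pcs) {
    stop_glds(sprintf("only %d signature genes available; need >= n_pcs = %d",
                      length(present), n_pcs))
  }
  sub <- E[, sort_ids(present), drop = FALSE]
  dec <- centered_svd(sub, k = n_pcs, reference = rowMeans(sub))
  cov <- dec$scores
  colnames(cov) <- sprintf("SIG_PC%d", seq_len(n_pcs))
  cov
}
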