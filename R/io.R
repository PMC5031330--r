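#' Drug-response matrix with explicit missingness
#'
#' Container for a cell-line x drug matrix of natural-log IC50 values.
#' Missing entries (drug-cell pairs never screened) are carried as `NA` in
#' `values` and as `FALSE` in `mask`. Every drug column must retain at least
#' two observed entries, the minimum needed to initialize imputation from
#' column means.
#'
#' @param values Numeric matrix, rows = cell lines, columns = drugs, with
#'   unique non-empty dimnames. `NA` marks a missing (unscreened) entry.
#' @return An object of class `drug_response_matrix`: a list with elements
#'   `values` (numeric matrix, `NA` at missing positions) and `mask`
#'   (logical matrix, `TRUE` = observed).
#' @export
drug_response_matrix <- function(values) {
  check_ids(values)
  if (!is.numeric(values)) {
    stop_glds("response matrix must be numeric")
  }
  mask <- !is.na(values)
  low <- colSums(mask) < 2L
  if (any(low)) {
    stop_glds("drug column(s) with fewer than 2 observed entries: ",
              paste(colnames(values)[low], collapse = ", "))
  }
  structure(list(values = values, mask = mask),
            class = "drug_response_matrix")
}

#' @export
print.drug_response_matrix <- function(x, ...) {
  cat(sprintf("drug_response_matrix: %d cell lines x %d drugs, %.1f%% missing\n",
              nrow(x$values), ncol(x$values),
              100 * mean(!x$mask)))
  invisible(x)
}

#' @export
dim.drug_response_matrix <- function(x) dim(x$values)

#' Binary mutation-call matrix
#'
#' Cell-line x gene matrix of aberration calls (1 = mutation/fusion present).
#' Unknown calls are imputed to 0 with a warning; values other than 0/1 are
#' rejected.
#'
#' @param calls Numeric/integer matrix of 0/1 calls with unique dimnames.
#' @return Object of class `mutation_matrix` with element `calls`.
#' @export
mutation_matrix <- function(calls) {
  check_ids(calls)
  if (anyNA(calls)) {
    warning(sprintf("mutation matrix: %d unknown call(s) imputed to 0",
                    sum(is.na(calls))), call. = FALSE)
    calls[is.na(calls)] <- 0
  }
  ok <- calls == 0 | calls == 1
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop_glds(sprintf(
      "mutation matrix must be binary; value %s at (%s, %s)",
      format(calls[bad[1], bad[2]]),
      rownames(calls)[bad[1]], colnames(calls)[bad[2]]))
  }
  storage.mode(calls) <- "integer"
  structure(list(calls = calls), class = "mutation_matrix")
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("mutation_matrix: %d cell lines x %d genes, %.1f%% mutated\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(x$calls)))
  invisible(x)
}

#' Log2 expression matrix
#'
#' Cell-line x gene matrix of normalized log2 expression. Values must be
#' finite; genes with zero variance are flagged (they cannot be ranked by
#' correlation and are skipped by the signature module).
#'
#' @param values Numeric matrix with unique dimnames.
#' @return Object of class `expression_matrix` with elements `values` and
#'   `zero_variance` (character vector of flat gene ids).
#' @export
expression_matrix <- function(values) {
  check_ids(values)
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop_glds(sprintf("expression matrix must be finite; offending entry (%s, %s)",
                      rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  ss <- colSums(sweep(values, 2, colMeans(values))^2)  # vectorized: genes can be many
  structure(list(values = values,
                 zero_variance = colnames(values)[ss == 0]),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cell lines x %d genes (%d zero-variance)\n",
              nrow(x$values), ncol(x$values), length(x$zero_variance)))
  invisible(x)
}

check_ids <- function(m) {
  if (!is.matrix(m)) stop_glds("expected a matrix")
  rid <- rownames(m); cid <- colnames(m)
  if (is.null(rid) || is.null(cid) || !length(rid) || !length(cid) ||
      any(!nzchar(rid)) || any(!nzchar(cid))) {
    stop_glds("matrix must carry non-empty row and column ids")
  }
  if (anyDuplicated(rid)) {
    stop_glds("duplicated row id(s): ",
              paste(unique(rid[duplicated(rid)]), collapse = ", "))
  }
  if (anyDuplicated(cid)) {
    stop_glds("duplicated column id(s): ",
              paste(unique(cid[duplicated(cid)]), collapse = ", "))
  }
  invisible(TRUE)
}

sniff_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a typed matrix from delimited text
#'
#' First row = drug/gene ids, first column = cell-line ids; `NA` or empty
#' cells are missing. The delimiter is sniffed from the extension
#' (`.csv` = comma, otherwise tab) unless given.
#'
#' @param path File path.
#' @param kind One of `"response"`, `"mutation"`, `"expression"`.
#' @param sep Optional delimiter override.
#' @param log_transform If `TRUE`, apply `log()` to a response matrix
#'   supplied on the raw IC50 scale. Default `FALSE`: inputs are assumed to
#'   be natural-log IC50 already and are never transformed silently.
#' @return A [drug_response_matrix()], [mutation_matrix()] or
#'   [expression_matrix()].
#' @export
read_matrix <- function(path, kind = c("response", "mutation", "expression"),
                        sep = NULL, log_transform = FALSE) {
  kind <- match.arg(kind)
  sep <- sniff_sep(path, sep)
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", na.strings = c("NA", ""),
                           fileEncoding = "UTF-8")
  rid <- raw[[1]]
  if (anyDuplicated(rid)) {
    stop_glds("duplicated row id(s) in ", path, ": ",
              paste(unique(rid[duplicated(rid)]), collapse = ", "))
  }
  hdr <- colnames(raw)[-1]
  if (anyDuplicated(hdr)) {   # data-frame subsetting would silently repair
    stop_glds("duplicated column id(s) in ", path, ": ",
              paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  }
  body <- as.matrix(raw[, -1, drop = FALSE])
  rownames(body) <- rid
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = dimnames(body)))
  bad <- !is.na(body) & is.na(num)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop_glds(sprintf("non-numeric value %s at row '%s', column '%s' in %s",
                      dQuote(body[w[1], w[2]]), rownames(body)[w[1]],
                      colnames(body)[w[2]], path))
  }
  message(sprintf("read %s matrix %s: %d x %d, %.1f%% missing",
                  kind, basename(path), nrow(num), ncol(num),
                  100 * mean(is.na(num))))
  switch(kind,
    response = {
      if (log_transform) num <- log(num)
      drug_response_matrix(num)
    },
    mutation = mutation_matrix(num),
    expression = expression_matrix(num))
}

#' Write a typed matrix to delimited text
#'
#' Inverse of [read_matrix()]: round-trips values, missingness mask and ids.
#'
#' @param x A typed matrix object (or plain matrix).
#' @param path Output path; delimiter sniffed from extension.
#' @param sep Optional delimiter override.
#' @export
write_matrix <- function(x, path, sep = NULL) {
  sep <- sniff_sep(path, sep)
  m <- if (inherits(x, "drug_response_matrix")) x$values
       else if (inherits(x, "mutation_matrix")) x$calls
       else if (inherits(x, "expression_matrix")) x$values
       else x
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a two-column annotation table
#'
#' @param path Two-column delimited file (id, label), with a header row.
#' @param sep Optional delimiter override.
#' @return Named character vector: id -> label.
#' @export
read_annotation <- function(path, sep = NULL) {
  sep <- sniff_sep(path, sep)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop_glds("annotation table needs two columns: ", path)
  if (anyDuplicated(df[[1]])) {
    stop_glds("duplicated id(s) in ", path, ": ",
              paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  }
  stats::setNames(df[[2]], df[[1]])
}

#' Write a two-column annotation table
#' @param x Named character vector.
#' @param path Output path.
#' @param header Character vector of length 2 with column names.
#' @param sep Optional delimiter override.
#' @export
write_annotation <- function(x, path, header = c("id", "label"), sep = NULL) {
  sep <- sniff_sep(path, sep)
  df <- stats::setNames(data.frame(names(x), unname(x)), header)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Restrict matrices and label vectors to shared cell lines
#'
#' Intersects row ids (or names, for label vectors) across all inputs and
#' returns every object restricted to the shared cell lines in a common,
#' lexicographically sorted order. Idempotent and order-independent in its
#' inputs.
#'
#' @param ... Typed matrices, plain matrices, or named vectors keyed by
#'   cell-line id.
#' @return A list of the inputs, aligned; names preserved if arguments are
#'   named.
#' @export
align_cell_lines <- function(...) {
  objs <- list(...)
  if (length(objs) < 2) stop_glds("align_cell_lines needs at least two objects")
  ids <- lapply(objs, obj_row_ids)
  shared <- Reduce(intersect, ids)
  if (length(shared) < 2) {
    stop_glds("fewer than 2 shared cell-line ids across inputs")
  }
  shared <- sort_ids(shared)
  dropped <- unique(unlist(lapply(ids, setdiff, shared)))
  if (length(dropped)) {
    message(sprintf("align_cell_lines: dropped %d unshared cell line(s)",
                    length(dropped)))
  }
  lapply(objs, restrict_rows, ids = shared)
}

restrict_rows <- function(x, ids) {
  if (inherits(x, "drug_response_matrix")) {
    drug_response_matrix(x$values[ids, , drop = FALSE])
  } else if (inherits(x, "mutation_matrix")) {
    mutation_matrix(x$calls[ids, , drop = FALSE])
  } else if (inherits(x, "expression_matrix")) {
    expression_matrix(x$values[ids, , drop = FALSE])
  } else if (is.matrix(x)) {
    x[ids, , drop = FALSE]
  } else {
    x[ids]
  }
}
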