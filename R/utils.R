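# Internal helpers shared across modules.

# Derive a child seed from a base seed and a stream of integer/string tags.
# Keeps every derived seed inside the 32-bit signed range.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(p) {
    if (is.character(p)) utf8ToInt(paste(p, collapse = "")) else p
  })))
  x <- 0
  for (p in parts) x <- (x * 69069 + as.numeric(p) + 1) %% 2147483629
  as.integer(x)
}

# Evaluate code under a local RNG state; global .Random.seed is untouched.
with_rng <- function(seed, code) {
  withr::with_seed(as.integer(seed %% 2147483629), code)
}

# Deterministic lexicographic sort, independent of the session locale.
sort_ids <- function(x) sort(x, method = "radix")

# Spearman correlation between two vectors (complete pairs).
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(NA_real_)
  stats::cor(rank(x[ok]), rank(y[ok]))
}

# row/col id accessors working for matrices and named vectors
obj_row_ids <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) rownames(x)
  else if (inherits(x, c("drug_response_matrix", "mutation_matrix",
                         "expression_matrix"))) rownames(x$values %||% x$calls)
  else names(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_glds <- function(...) stop(..., call. = FALSE)
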