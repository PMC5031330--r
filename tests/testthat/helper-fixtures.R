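# Shared fixtures and independent oracles, built in code at test time.

named_matrix <- function(data, m, n, prefix = c("cl", "d")) {
  matrix(data, m, n, dimnames = list(sprintf("%s%02d", prefix[1], seq_len(m)),
                                     sprintf("%s%02d", prefix[2], seq_len(n))))
}

# Noiseless rank-1 response matrix: X = u v' with positive drug loadings.
make_rank1 <- function(m, n, seed = 1) {
  set.seed(seed)
  u <- rnorm(m)
  v <- abs(rnorm(n)) + 0.5
  named_matrix(outer(u, v), m, n)
}

# Five-drug toy panel for negative-control bookkeeping: classes and a
# correlation matrix with a hand-chosen ranking relative to target A.
toy5 <- function() {
  drugs <- c("A", "B", "C", "D", "E")
  ann <- setNames(c("MEK inhibitor", "MEK inhibitor", "MEK inhibitor",
                    "HDAC inhibitor", "platinum"), drugs)
  corr <- diag(5)
  dimnames(corr) <- list(drugs, drugs)
  # correlations of A with the others: B > C > E > D
  corr["A", c("B", "C", "D", "E")] <- c(0.9, 0.8, 0.2, 0.5)
  corr[, "A"] <- corr["A", ]
  list(annotation = ann, corr = corr)
}

# Brute-force Benjamini-Hochberg step-up, written from the definition:
# q_(i) = min over j >= i of m * p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Masked-entry R2 against a known truth matrix.
masked_r2 <- function(truth, est, mask_missing) {
  cor(truth[mask_missing], est[mask_missing])^2
}
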