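# Independent oracles used to cross-check the package's decompositions.

# Amari index: permutation/scale-invariant distance between P = W A and a
# scaled permutation matrix; 0 iff P is a scaled permutation.
amari_index <- function(P) {
  P <- abs(P)
  n <- nrow(P)
  rows <- sum(rowSums(P / apply(P, 1, max)) - 1)
  cols <- sum(colSums(t(t(P) / apply(P, 2, max))) - 1)
  (rows + cols) / (2 * n * (n - 1))
}

# Best-matching absolute correlation between estimated and true sources:
# greedy assignment over the |cor| matrix.
matched_abs_cor <- function(est, truth) {
  cc <- abs(cor(est, truth))
  out <- numeric(ncol(truth))
  for (k in seq_len(ncol(truth))) {
    i <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    out[k] <- cc[i[1], i[2]]
    cc[i[1], ] <- -1
    cc[, i[2]] <- -1
  }
  out
}

# Explained-variance ratios via a covariance eigendecomposition, written
# independently of the package's prcomp-based route.
eigen_explained_var <- function(x) {
  ev <- eigen(cov(x), symmetric = TRUE, only.values = TRUE)$values
  ev / sum(ev)
}
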