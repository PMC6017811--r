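# Shared fixture builders; everything is generated in code.

make_aln <- function(seqs, ids = sprintf("s%d", seq_along(seqs)),
                     labels = NULL) {
  fs_alignment(ids, seqs, labels = labels)
}

random_alignment <- function(n_seq, n_col, gap_prob = 0.1) {
  alpha <- c("A", "C", "D", "E", "G", "K", "L", "R", "X", "-")
  prob <- c(rep((1 - gap_prob) / 9, 9), gap_prob)
  seqs <- vapply(seq_len(n_seq), function(i) {
    paste(sample(alpha, n_col, replace = TRUE, prob = prob), collapse = "")
  }, character(1L))
  # avoid all-gap sequences confusing nothing; ids unique
  make_aln(seqs, ids = sprintf("rec_%02d", seq_len(n_seq)))
}

# brute-force PCA oracle: eigendecomposition of the sample covariance
pca_oracle <- function(x, k) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  loadings <- ev$vectors[, seq_len(k), drop = FALSE]
  scores <- xc %*% loadings
  list(scores = scores, loadings = loadings,
       evf = ev$values / sum(ev$values))
}

# exact one-sided Fisher p by enumeration over binomial coefficients,
# independent of phyper
fisher_oracle <- function(a, b, c_, d) {
  r1 <- a + b
  c1 <- a + c_
  n <- a + b + c_ + d
  amin <- max(0L, r1 + c1 - n)
  amax <- min(r1, c1)
  support <- amin:amax
  w <- choose(c1, support) * choose(n - c1, r1 - support)
  sum(w[support >= a]) / sum(w)
}
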