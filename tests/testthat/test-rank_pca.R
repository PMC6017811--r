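test_that("rank encoding follows occurrence with alphabetical tie-break", {
  # most frequent symbol -> rank 1
  aln <- make_aln(c("A", "A", "C"))
  expect_equal(as.vector(rank_encode(aln)$values), c(1L, 1L, 2L))

  # tie: A before C alphabetically, so A = 1, C = 2
  aln2 <- make_aln(c("C", "A"))
  expect_equal(as.vector(rank_encode(aln2)$values), c(2L, 1L))

  # conserved column is constant
  aln3 <- make_aln(c("G", "G", "G"))
  expect_equal(as.vector(rank_encode(aln3)$values), c(1L, 1L, 1L))

  expect_error(rank_encode(make_aln("ACD")), "precondition")
})

test_that("gap policies place gaps as a symbol or at the worst rank", {
  aln <- make_aln(c("A-", "--", "AA"))
  sym <- rank_encode(aln, "gap_as_symbol")
  # col 1: A x2, - x1 -> A=1, -=2
  expect_equal(sym$values[, 1], c(s1 = 1L, s2 = 2L, s3 = 1L))
  worst <- rank_encode(aln, "gap_worst_rank")
  # col 1: only A observed (rank 1), gaps get max rank + 1 = 2
  expect_equal(worst$values[, 1], c(s1 = 1L, s2 = 2L, s3 = 1L))
  # col 2: A observed once -> A=1, gaps 2
  expect_equal(worst$values[, 2], c(s1 = 2L, s2 = 2L, s3 = 1L))
})

test_that("rank entries are bounded by the distinct symbols of their column", {
  set.seed(9)
  for (i in 1:5) {
    aln <- random_alignment(7, 20)
    rm_ <- rank_encode(aln)
    for (j in seq_len(aln$n_cols)) {
      n_distinct <- length(unique(substr(aln$seqs, j, j)))
      expect_true(all(rm_$values[, j] >= 1L & rm_$values[, j] <= n_distinct))
    }
  }
})

test_that("rank encoding is equivariant under sequence permutation", {
  set.seed(21)
  aln <- random_alignment(8, 30)
  perm <- sample(8)
  aln_p <- fs_alignment(aln$ids[perm], aln$seqs[perm])
  rm1 <- rank_encode(aln)
  rm2 <- rank_encode(aln_p)
  expect_equal(rm2$values, rm1$values[perm, ])
})

test_that("PCA matches a brute-force covariance eigendecomposition", {
  set.seed(33)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    p <- sample(3:30, 1)
    x <- matrix(sample.int(6, n * p, replace = TRUE), n, p)
    rownames(x) <- sprintf("r%d", seq_len(n))
    if (all(apply(x, 2, function(v) length(unique(v)) == 1))) next
    k <- min(n - 1L, p, 3L)
    res <- run_pca(x, k)
    ora <- pca_oracle(x, k)
    for (j in seq_len(k)) {
      # compare up to sign
      s <- sign(sum(res$loadings[, j] * ora$loadings[, j]))
      expect_equal(res$loadings[, j], s * ora$loadings[, j],
                   tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(unname(res$scores[, j]), s * unname(ora$scores[, j]),
                   tolerance = 1e-8)
    }
    expect_equal(res$explained_variance_fraction, ora$evf[seq_len(k)],
                 tolerance = 1e-8)
  }
})

test_that("PCA satisfies variance bookkeeping and determinism contracts", {
  set.seed(7)
  x <- matrix(rnorm(10 * 6), 10, 6)
  rownames(x) <- letters[1:10]
  res <- run_pca(x, k = 5)
  # loadings have unit norm and explained variance is non-increasing
  expect_equal(colSums(res$loadings^2), rep(1, 5), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_true(all(diff(res$explained_variance_fraction) <= 1e-12))
  expect_lte(sum(res$explained_variance_fraction), 1 + 1e-12)
  # sign convention: largest-|loading| entry positive
  for (j in 1:5) {
    expect_gt(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
  }
  # full-rank reconstruction
  res_full <- run_pca(x, k = 6)
  xc <- scale(x, center = TRUE, scale = FALSE)
  expect_equal(res_full$scores %*% t(res_full$loadings), xc,
               ignore_attr = TRUE, tolerance = 1e-10)
  # total variance identity at full rank: component variances (scores)
  # partition the total column variance, and the fractions sum to 1
  expect_equal(sum(res_full$explained_variance_fraction), 1,
               tolerance = 1e-12)
  expect_equal(sum(apply(res_full$scores, 2, var)),
               sum(apply(xc, 2, var)), tolerance = 1e-10)
})

test_that("single informative column concentrates all variance on PC1", {
  x <- cbind(c(1, 1, 2, 2), 3, 7)
  rownames(x) <- letters[1:4]
  res <- run_pca(x, k = 1)
  expect_equal(res$explained_variance_fraction[1], 1.0)
  expect_equal(abs(res$loadings[1, 1]), 1, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("duplicate rows receive identical scores", {
  set.seed(5)
  x <- matrix(sample.int(5, 4 * 3, replace = TRUE), 4, 3)
  x <- rbind(x, x[2, ])
  rownames(x) <- sprintf("r%d", 1:5)
  res <- run_pca(x, k = 2)
  expect_equal(res$scores[2, ], res$scores[5, ], ignore_attr = TRUE)
})

test_that("PCA rejects invalid k and constant matrices", {
  x <- matrix(1:12, 4, 3); rownames(x) <- letters[1:4]
  expect_error(run_pca(x, k = 10), "parameter error")
  xc <- matrix(2, 4, 3); rownames(xc) <- letters[1:4]
  expect_error(run_pca(xc, 1), "degenerate")
})

test_that("silhouette separates distinct clusters and is null under shuffling", {
  scores <- rbind(c(0, 0), c(0, 1), c(10, 10), c(10, 11))
  rownames(scores) <- c("a", "b", "c", "d")
  res <- structure(list(scores = scores, k = 2L), class = "fs_pca")
  labels <- c(a = "F1", b = "F1", c = "F2", d = "F2")
  expect_gt(family_separation(res, labels, 1:2), 0.9)

  # permuted labels on well-separated data: near-zero mean silhouette
  set.seed(99)
  pts <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 8), 20, 2))
  rownames(pts) <- sprintf("p%d", 1:40)
  res2 <- structure(list(scores = pts, k = 2L), class = "fs_pca")
  true_lab <- setNames(rep(c("A", "B"), each = 20), rownames(pts))
  sils <- replicate(100, {
    family_separation(res2, setNames(sample(true_lab), names(true_lab)), 1:2)
  })
  expect_lt(abs(mean(sils)), 0.2)

  # degenerate: identical points
  same <- matrix(1, 4, 2, dimnames = list(c("a", "b", "c", "d"), NULL))
  res3 <- structure(list(scores = same, k = 2L), class = "fs_pca")
  expect_error(family_separation(res3, labels, 1:2), "degenerate")

  # singleton family excluded with warning; < 2 usable -> error
  lab_single <- c(a = "F1", b = "F1", c = "F2")
  expect_warning(
    expect_error(family_separation(res, lab_single, 1:2), "precondition"),
    "single member")
})
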