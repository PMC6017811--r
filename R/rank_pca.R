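#' Rank-encode an alignment by per-column symbol occurrence
#'
#' Each aligned residue is replaced by the occurrence rank of its symbol
#' within its column: the most frequent symbol gets rank 1, the next rank 2,
#' and so on. Symbols with equal occurrence are ranked by ascending
#' alphabetical order of the one-letter code. The resulting integer matrix is
#' the substrate of [run_pca()].
#'
#' @param aln An [fs_alignment] with at least 2 sequences.
#' @param gap_policy `"gap_as_symbol"` lets `-` participate in ranking like
#'   any residue (default); `"gap_worst_rank"` always assigns gaps
#'   (max observed rank) + 1 in their column.
#' @return An object of class `fs_rank_matrix`: `values` (n_seq x n_col
#'   integer matrix with `row_ids`), `gap_policy`, and `rank_direction`
#'   (`"most_frequent_first"`).
#' @export
rank_encode <- function(aln, gap_policy = c("gap_as_symbol", "gap_worst_rank")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(aln, "fs_alignment"))
  n <- length(aln$ids)
  if (n < 2L) {
    stop("precondition error: rank encoding needs at least 2 sequences",
         call. = FALSE)
  }
  chars <- matrix(unlist(strsplit(aln$seqs, "", fixed = TRUE)),
                  nrow = n, byrow = TRUE)
  values <- matrix(0L, nrow = n, ncol = aln$n_cols)
  for (j in seq_len(aln$n_cols)) {
    col <- chars[, j]
    if (gap_policy == "gap_worst_rank") {
      obs <- col[col != "-"]
      if (length(obs) == 0L) {
        # all-gap column: no residue observed, gaps get rank 1
        values[, j] <- 1L
        next
      }
      tab <- table(obs)
      # order: occurrence descending, then alphabetical ascending
      ord <- order(-as.integer(tab), names(tab))
      ranks <- stats::setNames(seq_along(ord), names(tab)[ord])
      v <- ranks[col]
      v[col == "-"] <- length(ranks) + 1L
      values[, j] <- as.integer(v)
    } else {
      tab <- table(col)
      ord <- order(-as.integer(tab), names(tab))
      ranks <- stats::setNames(seq_along(ord), names(tab)[ord])
      values[, j] <- as.integer(ranks[col])
    }
  }
  rownames(values) <- aln$ids
  structure(
    list(values = values, row_ids = aln$ids, gap_policy = gap_policy,
         rank_direction = "most_frequent_first"),
    class = "fs_rank_matrix"
  )
}

#' Principal component analysis of a rank matrix
#'
#' Columns are mean-centered (no variance scaling) and the top-k right
#' singular directions extracted. The sign of each component is fixed so that
#' its largest-magnitude loading is positive, making results deterministic.
#'
#' @param rm An `fs_rank_matrix` from [rank_encode()], or a plain numeric
#'   matrix with row names.
#' @param k Number of components; must satisfy
#'   `k <= min(n_sequences - 1, n_columns)`.
#' @return An object of class `fs_pca`: `scores` (n_seq x k), `loadings`
#'   (n_col x k, unit-norm columns), `explained_variance_fraction` (length k),
#'   `column_means`, `k`.
#' @export
run_pca <- function(rm, k = 2L) {
  x <- if (inherits(rm, "fs_rank_matrix")) rm$values else as.matrix(rm)
  n <- nrow(x)
  p <- ncol(x)
  kmax <- min(n - 1L, p)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > kmax) {
    stop("parameter error: k must be in 1..", kmax, call. = FALSE)
  }
  if (all(apply(x, 2L, function(v) length(unique(v)) == 1L))) {
    stop("degenerate-input error: all columns constant, nothing to analyze",
         call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  evf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      scores = pc$x[, seq_len(k), drop = FALSE],
      loadings = pc$rotation[, seq_len(k), drop = FALSE],
      explained_variance_fraction = evf[seq_len(k)],
      column_means = pc$center,
      k = as.integer(k)
    ),
    class = "fs_pca"
  )
}

#' @export
print.fs_pca <- function(x, ...) {
  cat("fs_pca: ", nrow(x$scores), " samples, ", nrow(x$loadings),
      " columns, k = ", x$k, "\n", sep = "")
  cat("explained variance fraction:",
      paste(sprintf("%.3f", x$explained_variance_fraction), collapse = " "),
      "\n")
  invisible(x)
}

#' Quantify family separation in a PCA score subspace
#'
#' Mean silhouette width of the labeled sequences, using Euclidean distance
#' in the selected component subspace. Values near 1 indicate tight,
#' well-separated family clusters; values near 0 indicate no structure.
#'
#' @param res An `fs_pca` from [run_pca()].
#' @param labels Named character vector id -> family; ids must match the
#'   score rows. Sequences labeled `"unlabeled"` are ignored.
#' @param components Integer vector of component indices (default `1:2`).
#' @return Mean silhouette coefficient in `[-1, 1]`.
#' @export
family_separation <- function(res, labels, components = 1:2) {
  stopifnot(inherits(res, "fs_pca"))
  if (any(components > res$k)) {
    stop("parameter error: component index exceeds k = ", res$k,
         call. = FALSE)
  }
  labels <- labels[labels != "unlabeled"]
  ids <- intersect(rownames(res$scores), names(labels))
  labels <- labels[ids]
  sizes <- table(labels)
  singles <- names(sizes)[sizes < 2L]
  if (length(singles) > 0L) {
    warning("excluding families with a single member: ",
            paste(singles, collapse = ", "))
    labels <- labels[!labels %in% singles]
    ids <- names(labels)
  }
  if (length(unique(labels)) < 2L) {
    stop("precondition error: need >= 2 families with >= 2 members each",
         call. = FALSE)
  }
  pts <- res$scores[ids, components, drop = FALSE]
  d <- stats::dist(pts)
  if (all(d == 0)) {
    stop("degenerate-input error: all points identical", call. = FALSE)
  }
  sil <- cluster::silhouette(as.integer(factor(labels)), d)
  mean(sil[, "sil_width"])
}

#' Write PCA scores, loadings and explained variance as TSV
#'
#' @param res An `fs_pca`.
#' @param labels Optional named family labels merged into the score table.
#' @param scores_path,loadings_path,variance_path Output paths (`NULL`
#'   skips that table).
#' @return Invisibly, a list of the data frames written.
#' @export
write_pca_tables <- function(res, labels = NULL, scores_path = NULL,
                             loadings_path = NULL, variance_path = NULL) {
  stopifnot(inherits(res, "fs_pca"))
  pcn <- paste0("PC", seq_len(res$k))
  sc <- data.frame(id = rownames(res$scores), stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    sc$family <- ifelse(sc$id %in% names(labels), labels[sc$id], "unlabeled")
  }
  sc <- cbind(sc, stats::setNames(as.data.frame(res$scores), pcn))
  ld <- cbind(data.frame(column = seq_len(nrow(res$loadings))),
              stats::setNames(as.data.frame(res$loadings), pcn))
  ev <- data.frame(component = pcn,
                   explained_variance_fraction =
                     res$explained_variance_fraction)
  out <- list(scores = sc, loadings = ld, explained_variance = ev)
  wr <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(scores_path)) wr(sc, scores_path)
  if (!is.null(loadings_path)) wr(ld, loadings_path)
  if (!is.null(variance_path)) wr(ev, variance_path)
  invisible(out)
}
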