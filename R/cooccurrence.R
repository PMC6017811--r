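#' Read a gene presence/absence matrix
#'
#' @param path TSV with genomes as rows (first column `genome` or row
#'   names) and genes as columns, cells in {0, 1}.
#' @return An object of class `fs_pam`: logical genomes x genes matrix.
#' @export
read_pam <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if ("genome" %in% names(tab)) {
    rownames(tab) <- tab$genome
    tab$genome <- NULL
  }
  m <- as.matrix(tab)
  if (!all(m %in% c(0, 1))) {
    stop("input error: presence/absence cells must be 0 or 1", call. = FALSE)
  }
  presence_absence(m)
}

#' Construct a presence/absence matrix
#'
#' @param m Numeric or logical matrix, genomes as rows, genes as columns,
#'   with unique dimnames.
#' @return An `fs_pam` object (logical matrix).
#' @export
presence_absence <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) == 0L || ncol(m) == 0L) {
    stop("precondition error: empty presence/absence matrix", call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("precondition error: genome and gene names required", call. = FALSE)
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("precondition error: genome and gene names must be unique",
         call. = FALSE)
  }
  storage.mode(m) <- "logical"
  structure(m, class = c("fs_pam", class(m)))
}

#' 2x2 co-occurrence contingency table for two genes
#'
#' @param pam An `fs_pam`.
#' @param gene_a,gene_b Gene (column) names.
#' @return Named integer vector `(a_and_b, a_not_b, b_not_a, neither)`
#'   summing to the number of genomes.
#' @export
contingency <- function(pam, gene_a, gene_b) {
  stopifnot(inherits(pam, "fs_pam"))
  for (g in c(gene_a, gene_b)) {
    if (!g %in% colnames(pam)) {
      stop("key error: unknown gene '", g, "'", call. = FALSE)
    }
  }
  a <- pam[, gene_a]
  b <- pam[, gene_b]
  c(a_and_b = sum(a & b), a_not_b = sum(a & !b),
    b_not_a = sum(!a & b), neither = sum(!a & !b))
}

#' Nestedness flag and exact co-occurrence test
#'
#' `is_nested` is `TRUE` when gene A never occurs without gene B (the
#' `a_not_b` cell is zero) — the pattern where a gene is confined to genomes
#' carrying, say, the proteasome subunit genes. The p-value is the exact
#' hypergeometric tail for positive association (one-sided by default, the
#' directional claim); `alternative = "two.sided"` delegates to
#' [stats::fisher.test()].
#'
#' @param table Length-4 count vector as returned by [contingency()]:
#'   `(a_and_b, a_not_b, b_not_a, neither)`.
#' @param alternative `"greater"` (positive association, default) or
#'   `"two.sided"`.
#' @return List with `is_nested` and `fisher_p`.
#' @export
nestedness_and_test <- function(table, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  table <- as.integer(table)
  if (length(table) != 4L || any(table < 0L) || sum(table) < 1L) {
    stop("precondition error: need 4 non-negative counts, total >= 1",
         call. = FALSE)
  }
  a <- table[1L]; b <- table[2L]; c_ <- table[3L]; d <- table[4L]
  n <- a + b + c_ + d
  if (alternative == "greater") {
    # upper hypergeometric tail: P(X >= a) with margins fixed
    p <- stats::phyper(a - 1L, m = a + c_, n = b + d, k = a + b,
                       lower.tail = FALSE)
  } else {
    p <- stats::fisher.test(matrix(table, nrow = 2L, byrow = TRUE),
                            alternative = "two.sided")$p.value
  }
  list(is_nested = (b == 0L), fisher_p = p)
}
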