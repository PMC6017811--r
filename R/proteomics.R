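#' Construct an LFQ intensity table
#'
#' @param intensities Proteins x samples matrix of non-negative intensities
#'   (0 = missing), with unique protein row names and sample column names.
#' @param group Named character vector sample -> condition label (two
#'   conditions, e.g. `wt` / `knockout`), covering all samples.
#' @return Object of class `fs_lfq_table`.
#' @export
lfq_table <- function(intensities, group) {
  m <- as.matrix(intensities)
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop("precondition error: unique protein ids required as row names",
         call. = FALSE)
  }
  if (is.null(colnames(m))) {
    stop("precondition error: sample names required as column names",
         call. = FALSE)
  }
  if (any(m < 0)) {
    stop("precondition error: negative intensity", call. = FALSE)
  }
  group <- group[colnames(m)]
  if (anyNA(group)) {
    stop("design error: every sample needs a group assignment", call. = FALSE)
  }
  lv <- unique(group)
  if (length(lv) != 2L) {
    stop("design error: exactly two groups required, got ",
         length(lv), call. = FALSE)
  }
  if (any(table(group) < 2L)) {
    stop("design error: each group needs >= 2 samples", call. = FALSE)
  }
  structure(list(intensities = m, group = group), class = "fs_lfq_table")
}

# vectorised Welch / Student two-sample t on rows of two matrices
row_t_test <- function(x, y, var_equal = FALSE) {
  nx <- rowSums(!is.na(x))
  ny <- rowSums(!is.na(y))
  mx <- rowMeans(x, na.rm = TRUE)
  my <- rowMeans(y, na.rm = TRUE)
  vx <- rowSums((x - mx)^2, na.rm = TRUE) / (nx - 1L)
  vy <- rowSums((y - my)^2, na.rm = TRUE) / (ny - 1L)
  if (var_equal) {
    sp2 <- ((nx - 1L) * vx + (ny - 1L) * vy) / (nx + ny - 2L)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2L
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1L) + (vy / ny)^2 / (ny - 1L))
  }
  tstat <- (mx - my) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # exact separation: zero variance but non-zero difference
  sep <- se == 0 & (mx - my) != 0
  p[sep] <- 0
  p[se == 0 & (mx - my) == 0] <- 1
  list(diff = mx - my, p = p, df = df, t = tstat)
}

#' Differential analysis of replicate LFQ intensities
#'
#' Per-protein log2 fold change (knockout over wt group means) and two-sided
#' p-value from a two-sample t-test on log2-transformed intensities. Zero
#' intensities are treated as missing; a protein with fewer than 2 observed
#' values in either group is reported with `p = NA` and category
#' `unchanged`. Positive `log2_fc` means higher in the knockout group.
#'
#' @param tab An [fs_lfq_table][lfq_table].
#' @param test `"welch_t"` (default) or `"student_t"`.
#' @param log_transform Log2-transform intensities before testing
#'   (default TRUE; set FALSE if the table already holds log2 values, fold
#'   changes are then computed from differences of means).
#' @param missing_policy `"drop"` (default) drops zeros per protein;
#'   `"impute_min"` replaces them by half the smallest positive intensity
#'   in the table.
#' @param reference Group label of the reference (wt) condition; defaults
#'   to the first group label encountered.
#' @param fc_threshold,p_threshold Volcano thresholds applied to categorise
#'   each protein (defaults 1.5 and 0.05).
#' @param adjust `"none"` (default, raw p filtering) or `"BH"` for
#'   Benjamini-Hochberg adjusted p-values.
#' @return data.frame of class `fs_lfq_result`: `protein`, `log2_fc`,
#'   `p_value`, `category`.
#' @export
lfq_differential <- function(tab, test = c("welch_t", "student_t"),
                             log_transform = TRUE,
                             missing_policy = c("drop", "impute_min"),
                             reference = NULL,
                             fc_threshold = 1.5, p_threshold = 0.05,
                             adjust = c("none", "BH")) {
  test <- match.arg(test)
  missing_policy <- match.arg(missing_policy)
  adjust <- match.arg(adjust)
  stopifnot(inherits(tab, "fs_lfq_table"))
  m <- tab$intensities
  lv <- unique(tab$group)
  if (is.null(reference)) reference <- lv[1L]
  if (!reference %in% lv) {
    stop("design error: reference group '", reference, "' not in design",
         call. = FALSE)
  }
  other <- setdiff(lv, reference)
  if (log_transform) {
    m[m == 0] <- NA
    if (missing_policy == "impute_min") {
      m[is.na(m)] <- min(m, na.rm = TRUE) / 2
    }
    m <- log2(m)
  }
  x <- m[, tab$group == other, drop = FALSE]     # knockout
  y <- m[, tab$group == reference, drop = FALSE] # wt
  res <- row_t_test(x, y, var_equal = (test == "student_t"))
  p <- res$p
  too_few <- rowSums(!is.na(x)) < 2L | rowSums(!is.na(y)) < 2L
  p[too_few] <- NA
  log2_fc <- res$diff
  log2_fc[too_few] <- NA
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    protein = rownames(m),
    log2_fc = unname(log2_fc),
    p_value = unname(p),
    stringsAsFactors = FALSE
  )
  out$category <- classify_volcano_rows(out$log2_fc, out$p_value,
                                        fc_threshold, p_threshold)
  class(out) <- c("fs_lfq_result", class(out))
  out
}

classify_volcano_rows <- function(log2_fc, p_value, fc_threshold = 1.5,
                                  p_threshold = 0.05) {
  lfc <- log2(fc_threshold)
  cat <- rep("unchanged", length(log2_fc))
  ok <- !is.na(p_value) & !is.na(log2_fc) & p_value < p_threshold
  cat[ok & log2_fc >= lfc] <- "accumulated"
  cat[ok & log2_fc <= -lfc] <- "depleted"
  factor(cat, levels = c("accumulated", "depleted", "unchanged"))
}

#' Volcano classification counts
#'
#' Counts proteins as `accumulated` (log2 fold change >= log2(fc_threshold),
#' inclusive, and p strictly below p_threshold), `depleted` (mirror) or
#' `unchanged` (everything else, including proteins whose p-value could not
#' be computed).
#'
#' @param results An `fs_lfq_result` from [lfq_differential()], or any
#'   data.frame with `log2_fc` and `p_value`.
#' @param fc_threshold Fold-change threshold (default 1.5).
#' @param p_threshold p-value threshold (default 0.05).
#' @return Named integer vector `(accumulated, depleted, unchanged)`.
#' @export
volcano_classify <- function(results, fc_threshold = 1.5, p_threshold = 0.05) {
  if (nrow(results) == 0L) {
    stop("precondition error: empty result set", call. = FALSE)
  }
  cat <- classify_volcano_rows(results$log2_fc, results$p_value,
                               fc_threshold, p_threshold)
  counts <- table(cat)
  stats::setNames(as.integer(counts), names(counts))
}

#' Per-COG-class counts of accumulated and depleted proteins
#'
#' Proteins without a COG assignment and proteins in class S (function
#' unknown) are excluded; the remaining significantly changed proteins are
#' tallied per class and direction, classes in alphabetical order.
#'
#' @param results An `fs_lfq_result` (with `category` column) or data.frame
#'   with `protein` and `category`.
#' @param cog_map Named character vector protein -> single-letter COG class
#'   (may be partial).
#' @param fc_threshold,p_threshold Recompute categories at these thresholds
#'   when `results` lacks a `category` column.
#' @return data.frame with `cog_class`, `accumulated`, `depleted`.
#' @export
cog_summary <- function(results, cog_map, fc_threshold = 1.5,
                        p_threshold = 0.05) {
  if (!"category" %in% names(results)) {
    results$category <- classify_volcano_rows(results$log2_fc,
                                              results$p_value,
                                              fc_threshold, p_threshold)
  }
  cls <- cog_map[results$protein]
  keep <- !is.na(cls) & cls != "S" &
    results$category %in% c("accumulated", "depleted")
  n_unmapped <- sum(results$category %in% c("accumulated", "depleted") &
                      is.na(cls))
  if (n_unmapped > 0L) {
    message(n_unmapped, " changed protein(s) without a COG class excluded")
  }
  if (!any(keep)) {
    return(data.frame(cog_class = character(), accumulated = integer(),
                      depleted = integer(), stringsAsFactors = FALSE))
  }
  sub <- data.frame(class = as.character(cls[keep]),
                    category = results$category[keep])
  tab <- table(sub$class, factor(sub$category,
                                 levels = c("accumulated", "depleted")))
  out <- data.frame(
    cog_class = rownames(tab),
    accumulated = as.integer(tab[, "accumulated"]),
    depleted = as.integer(tab[, "depleted"]),
    stringsAsFactors = FALSE
  )
  out[order(out$cog_class), , drop = FALSE]
}

#' Read an LFQ intensity table and design
#'
#' @param lfq_path TSV: first column protein id, remaining columns one per
#'   sample.
#' @param design_path TSV with columns `sample` and `group`.
#' @return An [fs_lfq_table][lfq_table].
#' @export
read_lfq <- function(lfq_path, design_path) {
  tab <- utils::read.delim(lfq_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  rownames(tab) <- tab[[1L]]
  m <- as.matrix(tab[, -1L, drop = FALSE])
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(design))) {
    stop("input error: design table needs 'sample' and 'group' columns",
         call. = FALSE)
  }
  lfq_table(m, stats::setNames(design$group, design$sample))
}
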