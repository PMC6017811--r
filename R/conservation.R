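#' Classify alignment positions by loading magnitude
#'
#' Positions are classified relative to the maximum absolute loading on the
#' chosen component: strictly above `upper` of the maximum -> `variable`,
#' strictly below `lower` -> `conserved`, otherwise `intermediate`. The
#' default thresholds (30% / 10%) are the ones used to colour variable and
#' conserved positions on the structural model.
#'
#' @param loadings Either an `fs_pca` object or a numeric vector of
#'   per-column loadings.
#' @param component Component index used when `loadings` is an `fs_pca`
#'   (default 2, the family-discriminating component).
#' @param upper,lower Fractions of the maximal absolute loading,
#'   `0 <= lower < upper <= 1`.
#' @return A data.frame with `column` (1-based), `loading_abs`, `pct_of_max`
#'   and `category` (factor: variable/conserved/intermediate).
#' @export
classify_positions <- function(loadings, component = 2L, upper = 0.30,
                               lower = 0.10) {
  if (inherits(loadings, "fs_pca")) {
    if (component > loadings$k) {
      stop("parameter error: component ", component, " exceeds k = ",
           loadings$k, call. = FALSE)
    }
    loadings <- loadings$loadings[, component]
  }
  loadings <- as.numeric(loadings)
  if (length(loadings) == 0L) {
    stop("precondition error: empty loadings", call. = FALSE)
  }
  if (!(lower >= 0 && lower < upper && upper <= 1)) {
    stop("parameter error: need 0 <= lower < upper <= 1", call. = FALSE)
  }
  la <- abs(loadings)
  mx <- max(la)
  if (mx == 0) {
    stop("degenerate-input error: all loadings zero", call. = FALSE)
  }
  pct <- la / mx
  category <- ifelse(pct > upper, "variable",
                     ifelse(pct < lower, "conserved", "intermediate"))
  data.frame(
    column = seq_along(loadings),
    loading_abs = la,
    pct_of_max = pct,
    category = factor(category,
                      levels = c("variable", "intermediate", "conserved"))
  )
}

#' Sequence-logo information content of a column
#'
#' Standard logo definition: `IC = log2(alphabet_size) - H - e_n` where `H`
#' is the Shannon entropy of the observed symbol frequencies and `e_n` the
#' small-sample correction `(alphabet_size - 1) / (2 ln(2) n)`. Gaps are
#' excluded from the frequencies (standard logo convention); IC is clamped
#' at zero.
#'
#' @param counts An `fs_symbol_counts` from [column_counts()], or a named
#'   integer vector of symbol counts.
#' @param alphabet_size Alphabet size for the IC maximum (default 20).
#' @param apply_correction Apply the small-sample correction (default off,
#'   keeping closed-form values exact).
#' @return A list of class `fs_logo_column`: `column`, `frequencies`,
#'   `entropy_bits`, `information_content_bits`, `correction`, `n_observed`.
#' @export
information_content <- function(counts, alphabet_size = 20L,
                                apply_correction = FALSE) {
  col_idx <- NA_integer_
  if (inherits(counts, "fs_symbol_counts")) {
    col_idx <- counts$column_index
    counts <- counts$counts
  }
  counts <- counts[names(counts) != "-"]
  n <- sum(counts)
  if (n == 0L) {
    stop("empty-column error: no observed residues", call. = FALSE)
  }
  p <- counts[counts > 0] / n
  H <- -sum(p * log2(p))
  e_n <- if (apply_correction) (alphabet_size - 1) / (2 * log(2) * n) else 0
  ic <- max(0, log2(alphabet_size) - H - e_n)
  structure(
    list(column = col_idx, frequencies = p, entropy_bits = H,
         information_content_bits = ic, correction = e_n, n_observed = n),
    class = "fs_logo_column"
  )
}

#' Map ungapped reference coordinates to alignment columns
#'
#' @param aln An [fs_alignment].
#' @param reference_id Id of the reference sequence.
#' @param ref_start,ref_end 1-based residue coordinates on the ungapped
#'   reference sequence, `ref_start <= ref_end`.
#' @return Integer vector of alignment columns, one per reference residue.
#' @export
reference_window_columns <- function(aln, reference_id, ref_start, ref_end) {
  stopifnot(inherits(aln, "fs_alignment"))
  i <- match(reference_id, aln$ids)
  if (is.na(i)) {
    stop("key error: reference id '", reference_id, "' not in alignment",
         call. = FALSE)
  }
  chars <- strsplit(aln$seqs[i], "", fixed = TRUE)[[1L]]
  res_cols <- which(chars != "-")
  if (ref_start < 1L || ref_end < ref_start || ref_end > length(res_cols)) {
    stop("range error: window ", ref_start, "..", ref_end,
         " outside ungapped reference length ", length(res_cols),
         call. = FALSE)
  }
  res_cols[ref_start:ref_end]
}

#' Logo columns for a motif window on a reference sequence
#'
#' Maps an ungapped residue window on the reference (e.g. a Walker A or
#' Walker B motif) to alignment columns and computes per-column logo
#' information content.
#'
#' @inheritParams reference_window_columns
#' @param alphabet_size,apply_correction Passed to [information_content()].
#' @return List of `fs_logo_column`, in window order.
#' @export
motif_window <- function(aln, reference_id, ref_start, ref_end,
                         alphabet_size = 20L, apply_correction = FALSE) {
  cols <- reference_window_columns(aln, reference_id, ref_start, ref_end)
  lapply(cols, function(j) {
    information_content(column_counts(aln, j, gap_policy = "skip_gap"),
                        alphabet_size = alphabet_size,
                        apply_correction = apply_correction)
  })
}

#' Flatten logo columns to a data.frame
#'
#' @param logo List of `fs_logo_column` from [motif_window()].
#' @return data.frame with `column`, `entropy_bits`,
#'   `information_content_bits`, `n_observed` and a `frequencies` list column
#'   flattened into `symbol:frequency` strings.
#' @export
logo_table <- function(logo) {
  do.call(rbind, lapply(logo, function(lc) {
    data.frame(
      column = lc$column,
      entropy_bits = lc$entropy_bits,
      information_content_bits = lc$information_content_bits,
      n_observed = lc$n_observed,
      frequencies = paste(names(lc$frequencies),
                          sprintf("%.4f", lc$frequencies),
                          sep = ":", collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
}

#' Export per-residue structure annotations
#'
#' Joins a position classification with a column -> (chain, residue) mapping
#' to produce a per-residue attribute table suitable for colouring a
#' structural model (e.g. via the B-factor field or an attribute file).
#' Columns without a structure mapping are omitted; duplicate residue
#' targets resolve last-writer-wins with a warning.
#'
#' @param classification data.frame from [classify_positions()].
#' @param column_to_residue data.frame with `column`, `chain`, `residue`.
#' @return data.frame with `chain`, `residue`, `category`, `pct_of_max`.
#' @export
map_to_structure <- function(classification, column_to_residue) {
  stopifnot(is.data.frame(classification),
            all(c("column", "category", "pct_of_max") %in%
                  names(classification)))
  if (!is.data.frame(column_to_residue) ||
      !all(c("column", "chain", "residue") %in% names(column_to_residue))) {
    stop("precondition error: mapping needs column/chain/residue fields",
         call. = FALSE)
  }
  if (nrow(column_to_residue) == 0L) {
    return(data.frame(chain = character(), residue = integer(),
                      category = character(), pct_of_max = numeric(),
                      stringsAsFactors = FALSE))
  }
  missing_cols <- setdiff(column_to_residue$column, classification$column)
  if (length(missing_cols) > 0L) {
    stop("key error: mapped column ", missing_cols[1L],
         " absent from classification", call. = FALSE)
  }
  idx <- match(column_to_residue$column, classification$column)
  out <- data.frame(
    chain = as.character(column_to_residue$chain),
    residue = as.integer(column_to_residue$residue),
    category = as.character(classification$category[idx]),
    pct_of_max = classification$pct_of_max[idx],
    stringsAsFactors = FALSE
  )
  key <- paste(out$chain, out$residue)
  if (anyDuplicated(key)) {
    warning("duplicate residue targets; keeping the last mapping for each")
    out <- out[!duplicated(key, fromLast = TRUE), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
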