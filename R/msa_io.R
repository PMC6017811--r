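AA_ALPHABET_FS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
  "X", "-"
)

#' Construct a validated protein alignment
#'
#' An `fs_alignment` holds equal-length, upper-case aligned amino-acid
#' sequences over the 20 canonical residues plus `X` (unknown) and `-` (gap),
#' with optional per-sequence family labels. All user-facing column
#' coordinates are 1-based.
#'
#' @param ids Character vector of unique, non-empty sequence identifiers.
#' @param seqs Character vector of aligned sequences, same length as `ids`.
#' @param labels Optional named character vector mapping ids to family names.
#' @return An object of class `fs_alignment` with elements `ids`, `seqs`,
#'   `n_cols` and `labels`.
#' @export
fs_alignment <- function(ids, seqs, labels = NULL) {
  ids <- as.character(ids)
  seqs <- toupper(gsub(".", "-", as.character(seqs), fixed = TRUE))
  if (length(ids) != length(seqs)) {
    stop("alignment-shape error: ", length(ids), " ids but ",
         length(seqs), " sequences", call. = FALSE)
  }
  if (length(ids) == 0L) {
    stop("input error: empty alignment", call. = FALSE)
  }
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("identity error: empty or missing sequence id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("identity error: duplicate sequence id '",
         ids[duplicated(ids)][1L], "'", call. = FALSE)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("alignment-shape error: sequence lengths differ (",
         paste(unique(lens), collapse = ", "), ")", call. = FALSE)
  }
  if (lens[1L] < 1L) {
    stop("alignment-shape error: zero-length sequences", call. = FALSE)
  }
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    bad <- setdiff(unique(chars), AA_ALPHABET_FS)
    if (length(bad) > 0L) {
      stop("alphabet error: symbol '", bad[1L], "' in record '", ids[i],
           "' is outside the amino-acid alphabet", call. = FALSE)
    }
  }
  aln <- structure(
    list(ids = ids, seqs = seqs, n_cols = unname(lens[1L]), labels = NULL),
    class = "fs_alignment"
  )
  if (!is.null(labels)) aln <- attach_labels(aln, labels)
  aln
}

#' @export
print.fs_alignment <- function(x, ...) {
  cat("fs_alignment: ", length(x$ids), " sequences x ", x$n_cols,
      " columns\n", sep = "")
  if (!is.null(x$labels)) {
    fam <- table(x$labels)
    cat("families:", paste(names(fam), fam, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA or Clustal file and validates it: sequences must be
#' equal length, ids unique, and every character in the amino-acid alphabet
#' (20 residues, `X`, `-`). Lower-case input is upper-cased and `.` gaps are
#' normalised to `-` at read time.
#'
#' @param path Path to the alignment file.
#' @param format Either `"fasta"` or `"clustal"`.
#' @return An [fs_alignment].
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("input error: file not found: ", path, call. = FALSE)
  }
  if (file.size(path) == 0L) {
    stop("input error: empty file: ", path, call. = FALSE)
  }
  if (format == "fasta") {
    set <- tryCatch(
      Biostrings::readBStringSet(path),
      error = function(e) stop("input error: cannot parse FASTA: ",
                               conditionMessage(e), call. = FALSE)
    )
    if (length(set) == 0L) {
      stop("input error: no records in ", path, call. = FALSE)
    }
    # keep only the first whitespace-delimited token of each header
    ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
    seqs <- as.character(set)
  } else {
    msa <- tryCatch(
      Biostrings::readAAMultipleAlignment(path, format = "clustal"),
      error = function(e) stop("input error: cannot parse Clustal: ",
                               conditionMessage(e), call. = FALSE)
    )
    seqs <- as.character(msa)
    ids <- names(seqs)
    seqs <- unname(seqs)
  }
  fs_alignment(ids, seqs)
}

#' Write an alignment to FASTA or Clustal
#'
#' @param aln An [fs_alignment].
#' @param path Output path.
#' @param format Either `"fasta"` or `"clustal"`.
#' @param width Residues per output line.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "clustal"),
                            width = 60L) {
  format <- match.arg(format)
  stopifnot(inherits(aln, "fs_alignment"))
  if (format == "fasta") {
    set <- Biostrings::BStringSet(aln$seqs)
    names(set) <- aln$ids
    Biostrings::writeXStringSet(set, filepath = path, width = width)
  } else {
    # no installed package writes Clustal; emit the minimal dialect
    # readAAMultipleAlignment accepts
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("CLUSTAL W (famspace) multiple sequence alignment",
                 "", ""), con)
    idw <- max(nchar(aln$ids)) + 3L
    starts <- seq(1L, aln$n_cols, by = width)
    for (s in starts) {
      e <- min(s + width - 1L, aln$n_cols)
      for (i in seq_along(aln$ids)) {
        writeLines(sprintf("%-*s%s", idw, aln$ids[i],
                           substr(aln$seqs[i], s, e)), con)
      }
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Attach family labels to an alignment
#'
#' @param aln An [fs_alignment].
#' @param label_map Named character vector: names are sequence ids, values
#'   family names. Ids without an entry are flagged `"unlabeled"`.
#' @return The alignment with a full `labels` vector (one entry per id).
#' @export
attach_labels <- function(aln, label_map) {
  stopifnot(inherits(aln, "fs_alignment"))
  label_map <- unlist(label_map)
  unknown <- setdiff(names(label_map), aln$ids)
  if (length(unknown) > 0L) {
    stop("key error: label for unknown id '", unknown[1L], "'", call. = FALSE)
  }
  labels <- rep("unlabeled", length(aln$ids))
  names(labels) <- aln$ids
  if (length(label_map) > 0L) {
    labels[names(label_map)] <- as.character(label_map)
  }
  aln$labels <- labels
  aln
}

#' Read a two-column id/family label table
#'
#' @param path TSV with columns `id` and `family` (header required).
#' @return Named character vector suitable for [attach_labels()].
#' @export
read_labels <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "family") %in% names(tab))) {
    stop("input error: label table needs 'id' and 'family' columns",
         call. = FALSE)
  }
  stats::setNames(as.character(tab$family), as.character(tab$id))
}

#' Count residue symbols in one alignment column
#'
#' @param aln An [fs_alignment].
#' @param col 1-based column index.
#' @param gap_policy `"count_gap"` counts `-` like any symbol;
#'   `"skip_gap"` excludes gaps from counts and from `n_observed`.
#' @return A list of class `fs_symbol_counts`: `column_index`, `counts`
#'   (named integer vector), `n_observed`.
#' @export
column_counts <- function(aln, col, gap_policy = c("count_gap", "skip_gap")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(aln, "fs_alignment"))
  if (!is.numeric(col) || length(col) != 1L || col < 1L || col > aln$n_cols) {
    stop("index error: column ", col, " outside 1..", aln$n_cols,
         call. = FALSE)
  }
  chars <- substr(aln$seqs, col, col)
  if (gap_policy == "skip_gap") chars <- chars[chars != "-"]
  counts <- table(chars)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(
    list(column_index = as.integer(col), counts = counts,
         n_observed = sum(counts)),
    class = "fs_symbol_counts"
  )
}

#' Write a per-position score table
#'
#' Writes a TSV with 1-based column indices, sorted by column index. The
#' expected fields are `column`, one or more score columns, and `category`.
#'
#' @param rows A data.frame with at least a `column` field.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_position_table <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0L) {
    stop("precondition error: empty position table", call. = FALSE)
  }
  if (!"column" %in% names(rows)) {
    stop("precondition error: rows need a 'column' field", call. = FALSE)
  }
  rows <- rows[order(rows$column), , drop = FALSE]
  ok <- tryCatch({
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("I/O error: cannot write ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}
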