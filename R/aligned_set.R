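#' Gapped protein alignment with residue/column maps
#'
#' An `aligned_set` stores equal-length gapped rows (gap symbol `-`) keyed by
#' row id, and provides the residue-index/column maps used by the intron
#' projection and conservation scans.  Columns are 0-based; residue indices
#' are 1-based within the ungapped sequence, matching the residue numbering
#' convention used throughout the package.
#'
#' @param rows Named character vector of equal-length gapped sequences.
#' @return An object of class `aligned_set`.
#' @examples
#' aln <- aligned_set(c(a = "MT-EY", b = "MTSEY"))
#' ncol_alignment(aln)
#' column_of(aln, "a", 3)
#' @export
aligned_set <- function(rows) {
  if (is.null(names(rows)) || any(names(rows) == "") || anyDuplicated(names(rows))) {
    abort("alignment rows must have unique non-empty names")
  }
  rows <- toupper(rows)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1) {
    abort("all alignment rows must have equal length", class = "rasevol_ragged_alignment")
  }
  if (widths[1] == 0) abort("alignment has zero columns")
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(mat) <- names(rows)
  if (any(colSums(mat != "-") == 0)) {
    abort("alignment contains an all-gap column")
  }
  for (i in seq_along(rows)) {
    check_residues(gsub("-", "", rows[i], fixed = TRUE), names(rows)[i])
  }
  structure(list(rows = rows, mat = mat), class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("<aligned_set: %d rows x %d columns>\n",
              length(x$rows), nchar(x$rows[1])))
  shown <- head(x$rows, 8)
  for (i in seq_along(shown)) {
    seqshow <- if (nchar(shown[i]) > 60) paste0(substr(shown[i], 1, 57), "...") else shown[i]
    cat(sprintf("  %-20s %s\n", names(shown)[i], seqshow))
  }
  if (length(x$rows) > 8) cat(sprintf("  ... and %d more rows\n", length(x$rows) - 8))
  invisible(x)
}

#' @rdname aligned_set
#' @param x An `aligned_set`.
#' @export
ncol_alignment <- function(x) nchar(x$rows[[1]])

#' @rdname aligned_set
#' @export
row_ids <- function(x) names(x$rows)

#' Ungapped sequences of an alignment
#' @param x An `aligned_set`.
#' @return Named character vector of ungapped sequences.
#' @export
ungapped <- function(x) {
  vapply(x$rows, function(r) gsub("-", "", r, fixed = TRUE), character(1))
}

#' @exportS3Method tibble::as_tibble
as_tibble.aligned_set <- function(x, ...) {
  tibble(id = names(x$rows), aligned = unname(x$rows),
         residues = unname(ungapped(x)))
}

row_chars <- function(aln, row_id) {
  if (!row_id %in% rownames(aln$mat)) {
    abort(sprintf("unknown alignment row '%s'", row_id))
  }
  aln$mat[row_id, ]
}

#' Map a residue index to its alignment column
#'
#' @param aln An [aligned_set()].
#' @param row_id Row identifier.
#' @param residue_index 1-based index within the ungapped sequence.
#' @return 0-based alignment column holding that residue.
#' @seealso [residue_at()] for the inverse map.
#' @export
column_of <- function(aln, row_id, residue_index) {
  chars <- row_chars(aln, row_id)
  nongap <- which(chars != "-")
  if (length(residue_index) != 1 || residue_index < 1 || residue_index > length(nongap)) {
    abort(sprintf("residue index %s out of range for row '%s' (length %d)",
                  as.character(residue_index)[1], row_id, length(nongap)),
          class = "rasevol_range_error")
  }
  nongap[residue_index] - 1L
}

#' Residue index at an alignment column
#'
#' Inverse of [column_of()]; errors if the column holds a gap in that row.
#'
#' @inheritParams column_of
#' @param column 0-based alignment column.
#' @return 1-based residue index within the ungapped row.
#' @export
residue_at <- function(aln, row_id, column) {
  chars <- row_chars(aln, row_id)
  if (length(column) != 1 || column < 0 || column >= length(chars)) {
    abort(sprintf("column %s out of range", as.character(column)[1]),
          class = "rasevol_range_error")
  }
  col1 <- column + 1L
  if (chars[col1] == "-") {
    abort(sprintf("column %d is a gap in row '%s'", column, row_id),
          class = "rasevol_gap_column")
  }
  sum(chars[seq_len(col1)] != "-")
}

#' Read an aligned FASTA file
#'
#' @param source Path to an aligned FASTA file, or FASTA text.
#' @return An [aligned_set()].
#' @export
read_alignment <- function(source) {
  if (grepl("^\\s*>", source)) {
    tf <- tempfile(fileext = ".fasta")
    on.exit(unlink(tf), add = TRUE)
    writeLines(source, tf)
    source <- tf
  }
  set <- Biostrings::readBStringSet(source)
  if (length(set) == 0) abort("empty alignment source")
  ids <- sub("\\s.*$", "", names(set))
  aligned_set(setNames(toupper(as.character(set)), ids))
}

#' Write an alignment as aligned FASTA
#' @param aln An [aligned_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(aln$rows)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
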