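#' Read protein sequences from FASTA
#'
#' Parses a protein FASTA file (or literal FASTA text) into a tibble of
#' sequence records.  Headers may carry optional `species=` and `clade=`
#' key-value tags after the identifier, e.g.
#' `>hsap_kras4b species=Homo sapiens clade=vertebrate`.
#'
#' Residues are uppercased and a single trailing stop symbol `*` is stripped
#' with a warning.  The alphabet is restricted to the 20 standard amino acids
#' plus `X`; anything else is an error naming the record and position.
#'
#' @param source Path to a FASTA file, or a character scalar containing FASTA
#'   text (detected by a leading `>`).
#' @return A tibble with columns `id`, `species`, `clade` and `residues`, one
#'   row per FASTA entry.  Ids must be unique.
#' @examples
#' fa <- ">h1 species=Homo sapiens clade=vertebrate\nMTEYKLVVVG\n>h2\nMSSDDE"
#' read_protein_fasta(fa)
#' @export
read_protein_fasta <- function(source) {
  if (length(source) != 1 || !is.character(source)) {
    abort("`source` must be a single path or FASTA string")
  }
  if (grepl("^\\s*>", source)) {
    tf <- tempfile(fileext = ".fasta")
    on.exit(unlink(tf), add = TRUE)
    writeLines(source, tf)
    source <- tf
  }
  set <- tryCatch(
    Biostrings::readBStringSet(source),
    error = function(e) abort(paste0("cannot read FASTA: ", conditionMessage(e)))
  )
  if (length(set) == 0) abort("empty FASTA source")

  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate sequence id '%s'", ids[duplicated(ids)][1]),
          class = "rasevol_duplicate_id")
  }
  tag <- function(header, key) {
    m <- regmatches(header, regexec(paste0(key, "=([^=]*?)(?=\\s+\\S+=|$)"),
                                    header, perl = TRUE))[[1]]
    if (length(m) == 2) trimws(m[2]) else NA_character_
  }
  residues <- toupper(as.character(set))
  residues <- gsub("[[:space:]]", "", residues)
  has_stop <- grepl("\\*$", residues)
  if (any(has_stop)) {
    warn(sprintf("stripped trailing stop '*' from %d record(s)", sum(has_stop)))
    residues <- sub("\\*$", "", residues)
  }
  for (i in seq_along(residues)) {
    if (nchar(residues[i]) == 0) abort(sprintf("record '%s' is empty", ids[i]))
    check_residues(residues[i], ids[i])
  }
  tibble(
    id = unname(ids),
    species = unname(vapply(headers, tag, character(1), key = "species")),
    clade = unname(vapply(headers, tag, character(1), key = "clade")),
    residues = unname(residues)
  )
}

#' Write protein records to FASTA
#'
#' Inverse of [read_protein_fasta()]: `species=`/`clade=` tags are emitted when
#' present so a read/write round trip preserves ids, tags and residues.
#'
#' @param records Tibble with columns `id` and `residues` (optionally
#'   `species`, `clade`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  stopifnot(all(c("id", "residues") %in% names(records)))
  header <- records$id
  if ("species" %in% names(records)) {
    header <- ifelse(is.na(records$species), header,
                     paste0(header, " species=", records$species))
  }
  if ("clade" %in% names(records)) {
    header <- ifelse(is.na(records$clade), header,
                     paste0(header, " clade=", records$clade))
  }
  set <- Biostrings::BStringSet(setNames(records$residues, header))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
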