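## Switch-region signature blocks.
##
## Two short G-domain blocks overlap the conformational switch elements and
## are diagnostic of the RAS oncoprotein lineage: residues 31-42
## (EYDPTIEDSYRK, overlapping switch I at 30-40) and residues 59-72
## (AGQEEYSAMRDQYM, overlapping switch II at 58-72).  Scanning is ungapped
## (Hamming distance): the blocks are fixed-length motifs in near-identical
## G-domains.

#' Built-in switch-region signature blocks
#'
#' @return A tibble with columns `name`, `expected_start` (1-based) and
#'   `residues` for the two diagnostic blocks.
#' @export
signature_blocks <- function() {
  tibble(
    name = c("block1", "block2"),
    expected_start = c(31L, 59L),
    residues = c("EYDPTIEDSYRK", "AGQEEYSAMRDQYM")
  )
}

#' Switch-region spans
#' @return Tibble with `name`, `start`, `end` for switch I (30-40) and
#'   switch II (58-72).
#' @export
switch_regions <- function() {
  tibble(name = c("switchI", "switchII"),
         start = c(30L, 58L), end = c(40L, 72L))
}

#' Hamming distance between equal-length peptides
#'
#' Counts positions where the residues differ; `X` always counts as a
#' mismatch, even against itself.
#'
#' @param a,b Equal-length strings.
#' @return Integer mismatch count.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("hamming distance requires equal lengths")
  ca <- split1(toupper(a)); cb <- split1(toupper(b))
  as.integer(sum(ca != cb | ca == "X" | cb == "X"))
}

#' Scan a sequence for a signature block
#'
#' Ungapped sliding-window scan reporting every window within
#' `max_mismatch` Hamming distance of the block, sorted by mismatches and
#' then position.
#'
#' @param record One-row tibble with `id`/`residues`, or a character
#'   sequence.
#' @param block One-row tibble from [signature_blocks()] (or any tibble with
#'   `name`, `expected_start`, `residues`).
#' @param max_mismatch Maximum Hamming distance to report (default 0).
#' @return Tibble of hits: `record_id`, `block`, `start` (1-based),
#'   `mismatches`, `peptide`, `offset` (start − expected start).  Empty when
#'   nothing matches.
#' @export
scan_signature <- function(record, block, max_mismatch = 0L) {
  seqs <- as_sequence(record)
  chars <- split1(seqs$residues)
  bchars <- split1(block$residues[[1]])
  k <- length(bchars)
  n <- length(chars)
  empty <- tibble(record_id = character(), block = character(),
                  start = integer(), mismatches = integer(),
                  peptide = character(), offset = integer())
  if (n < k) return(empty)
  starts <- seq_len(n - k + 1L)
  mism <- vapply(starts, function(s) {
    w <- chars[s:(s + k - 1L)]
    sum(w != bchars | w == "X")
  }, numeric(1))
  keep <- which(mism <= max_mismatch)
  if (length(keep) == 0) return(empty)
  block_name <- block$name[[1]]
  expected <- block$expected_start[[1]]
  hits <- tibble(
    record_id = seqs$id,
    block = block_name,
    start = starts[keep],
    mismatches = as.integer(mism[keep]),
    peptide = vapply(starts[keep], function(s)
      paste(chars[s:(s + k - 1L)], collapse = ""), character(1)),
    offset = starts[keep] - expected
  )
  arrange(hits, .data$mismatches, .data$start)
}

#' Scan a batch of records against all signature blocks
#'
#' @param records Tibble of sequence records.
#' @param blocks Tibble of blocks (default [signature_blocks()]).
#' @inheritParams scan_signature
#' @return Row-bound [scan_signature()] hits for every record x block pair.
#' @export
scan_signatures <- function(records, blocks = signature_blocks(),
                            max_mismatch = 0L) {
  purrr::map_dfr(seq_len(nrow(records)), function(i) {
    purrr::map_dfr(seq_len(nrow(blocks)), function(j) {
      scan_signature(records[i, ], blocks[j, ], max_mismatch = max_mismatch)
    })
  })
}

#' Fully conserved gap-free blocks of an alignment
#'
#' Maximal runs of at least `min_length` consecutive columns that are
#' gap-free and identical across all rows.  A column containing any gap can
#' never be 100% identical.
#'
#' @param aln An [aligned_set()] with >= 2 rows.
#' @param min_length Minimum run length to report (default 1).
#' @return Tibble with 0-based `start_column`, `end_column` (inclusive) and
#'   `length`.
#' @export
conserved_blocks <- function(aln, min_length = 1L) {
  if (length(aln$rows) < 2) abort("conservation needs at least 2 rows")
  mat <- aln$mat
  ok <- apply(mat, 2, function(col) {
    !any(col == "-") && !any(col == "X") && length(unique(col)) == 1
  })
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_length
  tibble(
    start_column = starts[keep] - 1L,
    end_column = ends[keep] - 1L,
    length = runs$lengths[keep]
  )
}

#' Per-sequence signature summary with switch-region overlap
#'
#' Joins scan hits with the switch-region spans and reports, per hit, the
#' number of residues overlapping switch I and switch II.
#'
#' @param hits Output of [scan_signature()]/[scan_signatures()].
#' @param conserved Optional output of [conserved_blocks()]; when given, a
#'   `in_conserved_run` flag marks hits fully inside a conserved run
#'   (interpreted in reference coordinates on a gap-free alignment).
#' @return Tibble: one row per hit with `switchI_overlap` and
#'   `switchII_overlap` (residue counts), or an empty table with the full
#'   header.
#' @export
signature_report <- function(hits, conserved = NULL) {
  sw <- switch_regions()
  overlap <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
  out <- hits |>
    mutate(
      end = .data$start + nchar(.data$peptide) - 1L,
      switchI_overlap = overlap(.data$start, .data$end,
                                sw$start[sw$name == "switchI"],
                                sw$end[sw$name == "switchI"]),
      switchII_overlap = overlap(.data$start, .data$end,
                                 sw$start[sw$name == "switchII"],
                                 sw$end[sw$name == "switchII"])
    )
  if (!is.null(conserved) && nrow(hits) > 0) {
    out$in_conserved_run <- purrr::map2_lgl(out$start, out$end, function(s, e) {
      any(conserved$start_column <= s - 1L & conserved$end_column >= e - 1L)
    })
  }
  out
}
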