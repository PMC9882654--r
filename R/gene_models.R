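#' Read gene models (coding-exon structures)
#'
#' Reads coding-exon coordinates either from the package's gene-model TSV
#' (header `gene_id region_id strand start end rank`; coordinates 0-based
#' half-open) or from a GFF3 subset whose `CDS` features are grouped by their
#' `Parent` attribute (GFF3 coordinates are converted from 1-based inclusive).
#'
#' Exons are returned sorted into transcript order (5'→3'): ascending genomic
#' start on `+` genes, descending on `-` genes.  `complete_cds` records
#' whether the total coding length is a multiple of 3.
#'
#' @param source Path to a TSV or GFF3 file (GFF3 detected by a `.gff`/`.gff3`
#'   extension or a `##gff-version` first line).
#' @return A tibble with one row per coding exon: `gene_id`, `region_id`,
#'   `strand`, `start`, `end`, `rank`, `complete_cds`.
#' @export
read_gene_models <- function(source) {
  if (!file.exists(source)) abort(sprintf("no such file: '%s'", source))
  first <- readLines(source, n = 1)
  is_gff <- grepl("\\.gff3?$", source, ignore.case = TRUE) ||
    grepl("^##gff-version", first)
  gm <- if (is_gff) read_gene_models_gff3(source) else read_gene_models_tsv(source)
  validate_gene_models(gm)
}

read_gene_models_tsv <- function(source) {
  gm <- readr::read_tsv(source, show_col_types = FALSE, progress = FALSE)
  need <- c("gene_id", "region_id", "strand", "start", "end", "rank")
  missing_cols <- setdiff(need, names(gm))
  if (length(missing_cols) > 0) {
    abort(paste0("gene-model TSV lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  as_tibble(gm[need])
}

read_gene_models_gff3 <- function(source) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(source)
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0) abort("GFF3 source contains no CDS features")
  parent <- as.character(vapply(cds$Parent, function(p) p[[1]], character(1)))
  tibble(
    gene_id = parent,
    region_id = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(GenomicRanges::strand(cds)),
    # GFF3 is 1-based inclusive; internal convention is 0-based half-open
    start = GenomicRanges::start(cds) - 1L,
    end = GenomicRanges::end(cds),
    rank = NA_integer_
  )
}

validate_gene_models <- function(gm) {
  if (!all(gm$strand %in% c("+", "-"))) {
    abort(sprintf("unknown strand '%s'",
                  setdiff(unique(gm$strand), c("+", "-"))[1]),
          class = "rasevol_strand_error")
  }
  if (any(gm$end <= gm$start)) {
    bad <- gm$gene_id[which(gm$end <= gm$start)[1]]
    abort(sprintf("gene '%s' has an empty or inverted exon span", bad))
  }
  out <- gm |>
    group_by(.data$gene_id) |>
    group_modify_gene() |>
    ungroup()
  out
}

group_modify_gene <- function(grouped) {
  dplyr::group_modify(grouped, function(df, key) {
    gene <- key$gene_id
    if (length(unique(df$region_id)) != 1) {
      abort(sprintf("gene '%s' mixes region_ids", gene))
    }
    if (length(unique(df$strand)) != 1) {
      abort(sprintf("gene '%s' mixes strands", gene))
    }
    # transcript order: 5'->3' along the coding strand
    ord <- if (df$strand[1] == "+") order(df$start) else order(-df$start)
    df <- df[ord, ]
    starts <- sort(df$start)
    ends <- df$end[order(df$start)]
    if (nrow(df) > 1 && any(starts[-1] < ends[-length(ends)])) {
      abort(sprintf("gene '%s' has overlapping exons", gene),
            class = "rasevol_overlap_error")
    }
    df$rank <- seq_len(nrow(df))
    df$complete_cds <- sum(df$end - df$start) %% 3 == 0
    df
  })
}

#' Build a gene-model tibble from exon spans
#'
#' Convenience constructor used by the simulator and in examples.
#'
#' @param gene_id,region_id,strand Scalars describing the gene.
#' @param exons Two-column matrix or data frame of genomic `(start, end)`
#'   spans, 0-based half-open, in any order.
#' @return A validated gene-model tibble (see [read_gene_models()]).
#' @examples
#' gene_model("g1", exons = cbind(c(0, 300), c(93, 479)))
#' @export
gene_model <- function(gene_id, exons, region_id = "chr1", strand = "+") {
  exons <- as.data.frame(exons)
  names(exons) <- c("start", "end")
  gm <- tibble(
    gene_id = gene_id, region_id = region_id, strand = strand,
    start = as.integer(exons$start), end = as.integer(exons$end),
    rank = NA_integer_
  )
  validate_gene_models(gm)
}

#' Coding-exon lengths in transcript order
#' @param gm Gene-model tibble for a single gene.
#' @return Integer vector of exon lengths, 5'→3'.
#' @export
exon_lengths <- function(gm) {
  if (length(unique(gm$gene_id)) != 1) abort("expects a single gene")
  gm <- gm[order(gm$rank), ]
  as.integer(gm$end - gm$start)
}
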