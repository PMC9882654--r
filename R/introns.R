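## Intron positions, phases, and cross-species homology.
##
## Phase is the position of an intron relative to codon boundaries: phase 0
## introns fall between codons, phase 1 between the first and second
## nucleotide of a codon, phase 2 between the second and third.  A phase-1/2
## intron interrupts a residue; a phase-0 intron sits on a residue boundary
## and is keyed by the residue immediately following it.  Two introns are
## homologous when they occupy the same aligned amino-acid position with the
## same phase.

#' Compute intron positions and phases from a gene model
#'
#' One record per inter-exon junction of each complete-CDS gene:
#' `cds_offset` is the cumulative coding length upstream of the intron,
#' `phase = cds_offset mod 3`, and `protein_position` is the interrupted
#' residue (phase 1/2) or the residue immediately after the boundary
#' (phase 0), i.e. `floor(cds_offset/3) + 1`.
#'
#' @param gene_models Gene-model tibble from [read_gene_models()] or
#'   [gene_model()] (one or many genes).
#' @return A tibble with columns `gene_id`, `ordinal`, `cds_offset`, `phase`,
#'   `protein_position`, `boundary` (TRUE iff phase 0).  Single-exon genes
#'   contribute no rows.
#' @examples
#' gm <- gene_model("g1", cbind(c(0, 200, 500, 800),
#'                              c(93, 379, 660, 935)))
#' compute_introns(gm)  # phases 0, 2, 0
#' @export
compute_introns <- function(gene_models) {
  genes <- split(gene_models, gene_models$gene_id)
  purrr::map_dfr(genes, function(gm) {
    if (!all(gm$complete_cds)) {
      abort(sprintf("gene '%s' has an incomplete CDS (length not divisible by 3)",
                    gm$gene_id[1]), class = "rasevol_incomplete_cds")
    }
    lens <- exon_lengths(gm)
    if (any(lens <= 0)) abort(sprintf("gene '%s' has a zero-length exon", gm$gene_id[1]))
    if (length(lens) < 2) {
      return(tibble(gene_id = character(), ordinal = integer(),
                    cds_offset = integer(), phase = integer(),
                    protein_position = integer(), boundary = logical()))
    }
    offsets <- cumsum(lens)[-length(lens)]
    tibble(
      gene_id = gm$gene_id[1],
      ordinal = seq_along(offsets),
      cds_offset = as.integer(offsets),
      phase = as.integer(offsets %% 3),
      protein_position = as.integer(offsets %/% 3 + 1L),
      boundary = offsets %% 3 == 0
    )
  })
}

#' Project intron records onto alignment columns
#'
#' Maps each intron's `protein_position` to the 0-based column of its row in
#' a shared protein alignment.  Phase-1/2 introns land on the column of the
#' interrupted residue; phase-0 introns are keyed by the column of the
#' residue that follows the boundary (and stay distinguishable through their
#' `boundary` flag).
#'
#' @param introns Tibble from [compute_introns()].
#' @param aln An [aligned_set()] containing one row per gene.
#' @param id_map Optional named character vector mapping `gene_id` to
#'   alignment row id (default: identity).
#' @return The intron tibble with an added `column` (0-based).
#' @export
project_introns <- function(introns, aln, id_map = NULL) {
  if (nrow(introns) == 0) return(mutate(introns, column = integer()))
  rows <- if (is.null(id_map)) introns$gene_id else unname(id_map[introns$gene_id])
  if (anyNA(rows)) {
    abort(sprintf("no alignment row mapped for gene '%s'",
                  introns$gene_id[which(is.na(rows))[1]]))
  }
  lens <- nchar(ungapped(aln))
  introns$column <- purrr::map2_int(rows, introns$protein_position, function(r, p) {
    if (!r %in% row_ids(aln)) abort(sprintf("gene row '%s' not in alignment", r))
    if (p > lens[[r]]) {
      abort(sprintf(
        "gene '%s': intron protein position %d exceeds row length %d (CDS/protein mismatch)",
        r, p, lens[[r]]), class = "rasevol_cds_mismatch")
    }
    column_of(aln, r, p)
  })
  introns
}

#' Cluster homologous introns across species
#'
#' Exact grouping on the key (alignment column, phase): introns are
#' homologous when they occupy the same aligned amino-acid position and have
#' the same phase.  Phase-0 boundaries only ever group with other phase-0
#' boundaries.  Singleton groups are lineage-specific introns.
#'
#' @param projected Output of [project_introns()] (one shared alignment).
#' @return A tibble with one row per intron carrying `group_id`, plus
#'   group-level `alignment_column`, `phase` and `n_members`.
#' @export
cluster_homologous <- function(projected) {
  if (nrow(projected) == 0) {
    return(mutate(projected, group_id = integer(), n_members = integer()))
  }
  projected |>
    group_by(.data$column, .data$phase) |>
    mutate(n_members = n()) |>
    ungroup() |>
    mutate(group_id = dplyr::dense_rank(
      interaction(.data$column, .data$phase, drop = TRUE)))
}

#' Assign letter labels to intron homology groups
#'
#' Letters `a`, `b`, `c`, ... are assigned in ascending alignment-column
#' order (ties broken by ascending phase); beyond 26 groups, double letters
#' (`aa`, `ab`, ...) are used.
#'
#' @param clustered Output of [cluster_homologous()].
#' @return The same tibble with a `group_label` column.
#' @export
label_groups <- function(clustered) {
  if (nrow(clustered) == 0) return(mutate(clustered, group_label = character()))
  keys <- clustered |>
    dplyr::distinct(.data$column, .data$phase) |>
    arrange(.data$column, .data$phase) |>
    mutate(group_label = letter_labels(dplyr::n()))
  left_join(clustered, keys, by = c("column", "phase"))
}

letter_labels <- function(n) {
  singles <- letters
  if (n <= 26) return(singles[seq_len(n)])
  doubles <- as.vector(t(outer(letters, letters, paste0)))
  c(singles, doubles)[seq_len(n)]
}

#' Intron homology table for a set of genes
#'
#' End-to-end wrapper: [compute_introns()] on all gene models, projection
#' onto the shared alignment, homology clustering and letter labelling — a
#' machine-readable intron-conservation figure.
#'
#' @inheritParams project_introns
#' @param gene_models Gene-model tibble covering one or more genes.
#' @return Tibble with columns `gene_id`, `ordinal`, `cds_offset`, `phase`,
#'   `protein_position`, `boundary`, `column`, `n_members`, `group_label`.
#' @export
intron_homology <- function(gene_models, aln, id_map = NULL) {
  compute_introns(gene_models) |>
    project_introns(aln, id_map = id_map) |>
    cluster_homologous() |>
    label_groups() |>
    select(-"group_id") |>
    arrange(.data$gene_id, .data$ordinal)
}
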