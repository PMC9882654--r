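## End-to-end orchestration: FASTA (+ optional gene models / alignment) in,
## the five analysis artifacts out.

#' Run the full comparative-analysis pipeline
#'
#' Executes every stage whose inputs are available and writes one TSV or
#' Newick artifact per stage to `out_dir`:
#' * `motif_table.tsv` — HVR motif annotation and archetype per sequence;
#' * `signature_report.tsv` — switch-region signature hits;
#' * `identity_matrix.tsv` — percent identity of every record against the
#'   references (default: the records themselves);
#' * `intron_homology.tsv` — intron phases, alignment columns and homology
#'   groups (only when gene models are given);
#' * `tree.nwk` — BioNJ tree with bootstrap supports (only when >= 3
#'   sequences are available);
#' * `run_log.txt` — package version, seed and parameters.
#'
#' Stages with absent inputs are skipped with a log entry; a hard failure in
#' any stage aborts with a stage-named condition.
#'
#' @param fasta Path to a protein FASTA file, or a record tibble.
#' @param genes Optional path to a gene-model TSV/GFF3, or a gene-model
#'   tibble.
#' @param alignment Optional path to an aligned FASTA or an
#'   [aligned_set()]; when absent, a progressive MSA is built internally.
#' @param references Optional FASTA path/tibble of reference sequences for
#'   the identity matrix.
#' @param out_dir Output directory (created if needed).
#' @param model Distance model for the tree stage.
#' @param bootstrap Number of bootstrap replicates (0 disables supports).
#' @param max_mismatch Signature-scan mismatch budget.
#' @param max_gap_fraction Column-curation threshold before distances.
#' @param seed Single integer seed governing all randomness.
#' @return Invisibly, a named list of the computed stage results.
#' @export
run_pipeline <- function(fasta, genes = NULL, alignment = NULL,
                         references = NULL, out_dir = ".",
                         model = "kimura", bootstrap = 100L,
                         max_mismatch = 2L, max_gap_fraction = 0.2,
                         seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    sprintf("rasevol %s", as.character(utils::packageVersion("rasevol"))),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("distance model: %s; bootstrap: %d; max_mismatch: %d; max_gap_fraction: %g",
            model, bootstrap, max_mismatch, max_gap_fraction)
  )
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "rasevol_stage_error")
    })
  }
  results <- list()

  records <- stage("read-fasta", {
    if (is.character(fasta)) read_protein_fasta(fasta) else as_tibble(fasta)
  })
  note("records: %d", nrow(records))

  results$motif_table <- stage("annotate-hvr", annotate_hvr(records))
  write_artifact(results$motif_table, file.path(out_dir, "motif_table.tsv"))

  results$signature <- stage("signature-scan", {
    signature_report(scan_signatures(records, max_mismatch = max_mismatch))
  })
  write_artifact(results$signature, file.path(out_dir, "signature_report.tsv"))

  refs <- if (is.null(references)) records else {
    if (is.character(references)) read_protein_fasta(references) else as_tibble(references)
  }
  results$identity <- stage("identity", identity_matrix(records, refs))
  write_artifact(identity_wide(results$identity),
                 file.path(out_dir, "identity_matrix.tsv"))

  aln <- NULL
  if (!is.null(alignment)) {
    aln <- stage("read-alignment", {
      if (inherits(alignment, "aligned_set")) alignment else read_alignment(alignment)
    })
  } else if (nrow(records) >= 2) {
    aln <- stage("msa", progressive_msa(records))
    note("alignment: progressive MSA built internally")
  } else {
    note("alignment: skipped (single record)")
  }

  if (!is.null(genes)) {
    gm <- stage("gene-structure", {
      if (is.character(genes)) read_gene_models(genes) else as_tibble(genes)
    })
    results$intron_homology <- stage("intron-homology", intron_homology(gm, aln))
    write_artifact(results$intron_homology,
                   file.path(out_dir, "intron_homology.tsv"))
  } else {
    note("intron homology: skipped (no gene models)")
  }

  if (!is.null(aln) && length(aln$rows) >= 3) {
    results$tree <- stage("tree", {
      cur <- curate_alignment(aln, max_gap_fraction = max_gap_fraction)
      if (bootstrap > 0) {
        bootstrap_support(cur, model = model, replicates = bootstrap, seed = seed)
      } else {
        bionj_tree(protein_distance(cur, model = model))
      }
    })
    write_newick(results$tree, file.path(out_dir, "tree.nwk"))
  } else {
    note("tree: skipped (fewer than 3 aligned sequences)")
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(results)
}

write_artifact <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}
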