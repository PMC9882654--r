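canonical_gene <- function(id = "g1") {
  # coding exon lengths 93, 179, 160, 135 laid out with 200-nt introns
  starts <- c(0, 293, 672, 1032)
  gene_model(id, cbind(starts, starts + c(93, 179, 160, 135)))
}

test_that("intron phases follow cumulative coding length mod 3", {
  ir <- compute_introns(canonical_gene())
  expect_equal(ir$cds_offset, c(93L, 272L, 432L))
  expect_equal(ir$phase, c(0L, 2L, 0L))
  expect_equal(ir$protein_position, c(32L, 91L, 145L))
  expect_equal(ir$boundary, c(TRUE, FALSE, TRUE))
})

test_that("single-exon genes have no introns and incomplete CDS errors", {
  single <- gene_model("s1", cbind(0, 567))
  expect_equal(nrow(compute_introns(single)), 0)
  incomplete <- gene_model("s2", cbind(0, 100))
  expect_error(compute_introns(incomplete), class = "rasevol_incomplete_cds")
})

test_that("projection maps protein positions through row gaps", {
  ir <- tibble::tibble(gene_id = "a", ordinal = 1L, cds_offset = 3L,
                       phase = 0L, protein_position = 1L, boundary = TRUE)
  aln <- aligned_set(c(a = "--MTEY", b = "KLMTEY"))
  proj <- project_introns(ir, aln)
  expect_equal(proj$column, 2L)

  gapfree <- aligned_set(c(a = "MTEY", b = "MSEY"))
  expect_equal(project_introns(ir, aln = gapfree)$column, 0L)

  toolong <- dplyr::mutate(ir, protein_position = 99L)
  expect_error(project_introns(toolong, aln), class = "rasevol_cds_mismatch")
})

test_that("homology requires both the same column and the same phase", {
  proj <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    ordinal = 1L, cds_offset = c(93L, 93L, 93L, 94L),
    phase = c(2L, 2L, 2L, 0L),
    protein_position = 32L, boundary = c(FALSE, FALSE, FALSE, TRUE),
    column = c(40L, 40L, 40L, 40L)
  )
  grouped <- cluster_homologous(proj)
  expect_equal(sort(unique(grouped$n_members)), c(1L, 3L))
  # same column, different phase -> two distinct groups
  expect_equal(length(unique(grouped$group_id)), 2)

  labelled <- label_groups(grouped)
  # tie at the same column broken by ascending phase
  expect_equal(labelled$group_label[labelled$phase == 0L], "a")
  expect_equal(unique(labelled$group_label[labelled$phase == 2L]), "b")
})

test_that("group letters run a, b, c by column and extend past z", {
  proj <- tibble::tibble(
    gene_id = letters[1:3], ordinal = 1L, cds_offset = 3L, phase = 0L,
    protein_position = 1L, boundary = TRUE, column = c(150L, 40L, 90L)
  )
  lab <- label_groups(cluster_homologous(proj))
  expect_equal(lab$group_label[order(lab$column)], c("a", "b", "c"))
  expect_equal(rasevol:::letter_labels(28)[27:28], c("aa", "ab"))
})

test_that("grouping is invariant to row order", {
  proj <- tibble::tibble(
    gene_id = c("a", "b", "c"), ordinal = 1L, cds_offset = 3L, phase = 0L,
    protein_position = 1L, boundary = TRUE, column = c(10L, 10L, 25L)
  )
  l1 <- label_groups(cluster_homologous(proj))
  l2 <- label_groups(cluster_homologous(proj[c(3, 1, 2), ]))
  key <- function(x) x[order(x$gene_id), c("gene_id", "group_label")]
  expect_equal(key(l1), key(l2))
})

test_that("planted intron structure is recovered exactly on simulated families", {
  sim <- simulate_family("KRAS4B-like", n_leaves = 6, rate = 0.05, seed = 13)
  plan <- dplyr::bind_rows(
    vertebrate_intron_plan(),
    tibble::tibble(label = "d", protein_position = 60L, phase = 0L,
                   lineages = "t01")  # lineage-specific intron
  )
  gms <- make_gene_models(sim$records, plan)
  aln <- sim_alignment(sim)
  hom <- intron_homology(gms$gene_models, aln)

  # every gene's computed introns equal the planted truth
  joined <- dplyr::inner_join(hom, gms$truth,
                              by = c("gene_id", "cds_offset", "phase",
                                     "protein_position"))
  expect_equal(nrow(joined), nrow(gms$truth))
  expect_equal(nrow(hom), nrow(gms$truth))

  # shared introns a-c form 6-member groups; lineage-specific d is a singleton
  sizes <- joined |> dplyr::distinct(.data$label, .data$n_members)
  expect_equal(sizes$n_members[sizes$label %in% c("a", "b", "c")], rep(6L, 3))
  expect_equal(sizes$n_members[sizes$label == "d"], 1L)

  # letters follow ascending alignment columns: a < d < b < c positions
  lab_by_col <- joined |> dplyr::distinct(.data$label, .data$column, .data$group_label) |>
    dplyr::arrange(.data$column)
  expect_equal(lab_by_col$group_label, letters[seq_len(nrow(lab_by_col))])
})

test_that("simulated CDS lengths satisfy 3 x (protein length + 1)", {
  sim <- simulate_family("NRAS-like", n_leaves = 4, rate = 0.1, seed = 2)
  gms <- make_gene_models(sim$records)
  lens <- vapply(split(gms$gene_models, gms$gene_models$gene_id),
                 function(g) sum(exon_lengths(g)), integer(1))
  prot <- nchar(sim$records$residues)[match(names(lens), sim$records$id)]
  expect_equal(unname(lens), 3L * (prot + 1L))
})

test_that("intronless (fungus-style) plans give single-exon models", {
  sim <- simulate_family("KRAS4B-like", n_leaves = 3, rate = 0, seed = 1)
  plan <- vertebrate_intron_plan()[0, ]
  gms <- make_gene_models(sim$records, plan)
  expect_equal(nrow(gms$gene_models), 3)  # one exon per gene
  expect_equal(nrow(compute_introns(gms$gene_models)), 0)
})
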