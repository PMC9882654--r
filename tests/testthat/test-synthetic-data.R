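test_that("templates carry the signature blocks and their own grammar", {
  arch <- build_archetypes()
  expect_equal(nrow(arch), 6)
  for (i in seq_len(nrow(arch))) {
    expect_equal(substr(arch$sequence[i], 31, 42), signature_blocks()$residues[1])
    expect_equal(substr(arch$sequence[i], 59, 72), signature_blocks()$residues[2])
    expect_equal(nchar(arch$sequence[i]), nchar(arch$mask[i]))
  }
  # prenylation split: KRASBL and invertebrate are geranylgeranylated
  tab <- annotate_hvr(dplyr::transmute(arch, id = label, clade = clade,
                                       residues = sequence))
  gg <- tab$archetype[tab$prenyl_type == "geranylgeranyl"]
  expect_setequal(gg, c("KRASBL-like", "invertebrate-like"))
})

test_that("rate zero reproduces the template at every leaf", {
  sim <- simulate_family("HRAS-like", n_leaves = 5, rate = 0, seed = 3)
  expect_equal(unique(sim$records$residues), sim$truth$template)
})

test_that("the same seed gives the same family; different seeds differ", {
  s1 <- simulate_family("NRAS-like", n_leaves = 6, rate = 0.2, seed = 11)
  s2 <- simulate_family("NRAS-like", n_leaves = 6, rate = 0.2, seed = 11)
  s3 <- simulate_family("NRAS-like", n_leaves = 6, rate = 0.2, seed = 12)
  expect_identical(s1$records, s2$records)
  expect_false(identical(s1$records$residues, s3$records$residues))
})

test_that("mask-respecting evolution freezes the signature columns", {
  sim <- simulate_family("KRAS4B-like", n_leaves = 10, branch_length = 0.15,
                         rate = 0.4, seed = 17)
  block1 <- vapply(sim$records$residues, substr, character(1), 31, 42,
                   USE.NAMES = FALSE)
  block2 <- vapply(sim$records$residues, substr, character(1), 59, 72,
                   USE.NAMES = FALSE)
  expect_equal(unique(block1), "EYDPTIEDSYRK")
  expect_equal(unique(block2), "AGQEEYSAMRDQYM")
  # sequences did actually diverge elsewhere
  expect_gt(length(unique(sim$records$residues)), 1)
})

test_that("unmasked evolution does mutate frozen positions eventually", {
  sim <- simulate_family("KRAS4B-like", n_leaves = 10, branch_length = 0.5,
                         rate = 1, seed = 23, mask_respect = FALSE)
  block1 <- vapply(sim$records$residues, substr, character(1), 31, 42,
                   USE.NAMES = FALSE)
  expect_gt(length(unique(block1)), 1)
})

test_that("noiseless families are recovered perfectly by every annotator", {
  for (label in c("KRAS4B-like", "HRAS-like", "KRAS4A-like")) {
    sim <- simulate_family(label, n_leaves = 4, rate = 0, seed = 5)
    tab <- annotate_hvr(sim$records)
    expect_equal(unique(tab$archetype), label)
    gms <- make_gene_models(sim$records)
    hom <- intron_homology(gms$gene_models, sim_alignment(sim))
    expect_equal(sort(unique(hom$group_label)), c("a", "b", "c"))
    expect_equal(unique(hom$n_members), 4L)
  }
})

test_that("archetype recovery stays perfect under moderate masked divergence", {
  for (label in build_archetypes()$label) {
    sim <- simulate_family(label, n_leaves = 6, branch_length = 0.1,
                           rate = 0.3, seed = 29)
    tab <- annotate_hvr(sim$records)
    expect_equal(unique(tab$archetype), label)
  }
})

test_that("tree recovery from simulated sequences is usually exact", {
  skip_if_not_installed("phangorn")
  # scaled-down property: 8 leaves, >= 0.05 expected subs/site per branch
  hits <- 0
  n_rep <- 20
  for (k in seq_len(n_rep)) {
    set.seed(100 + k)
    tr <- random_tree(8, min_bl = 0.1, max_bl = 0.3)
    arch <- build_archetypes()
    sim <- evolve_family(arch[1, ], tr, rate = 1, mask_respect = TRUE,
                         seed = 200 + k)
    d <- protein_distance(sim_alignment(sim), "kimura")
    phy <- bionj_tree(d)
    if (phangorn::RF.dist(ape::unroot(tr), phy) == 0) hits <- hits + 1
  }
  expect_gte(hits, 0.9 * n_rep)
})

test_that("gene-model planting validates its plan", {
  sim <- simulate_family("KRAS4B-like", n_leaves = 2, rate = 0, seed = 1)
  bad <- tibble::tibble(label = "z", protein_position = 500L, phase = 0L,
                        lineages = NA_character_)
  expect_error(make_gene_models(sim$records, bad), "beyond CDS")
  dup <- vertebrate_intron_plan()[c(1, 1), ]
  expect_error(make_gene_models(sim$records, dup), "duplicate")
})

test_that("balanced trees are deterministic and bifurcating", {
  t1 <- balanced_tree(12, 0.1)
  t2 <- balanced_tree(12, 0.1)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_equal(length(t1$tip.label), 12)
  expect_true(all(t1$edge.length == 0.1))
})
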