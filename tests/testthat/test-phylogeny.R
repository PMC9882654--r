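test_that("alignment curation drops gappy columns only", {
  aln <- aligned_set(c(a = "MT-EY", b = "MTSEY", c = "MT-EY", d = "MTSEY"))
  cur <- curate_alignment(aln, max_gap_fraction = 0.2)
  expect_equal(ncol_alignment(cur), 4)        # 50%-gap column dropped
  expect_equal(row_ids(cur), row_ids(aln))    # row order preserved
  cur2 <- curate_alignment(aln, max_gap_fraction = 1.0)
  expect_equal(ncol_alignment(cur2), 5)
  gapfree <- aligned_set(c(a = "MTEY", b = "MSEY"))
  expect_equal(curate_alignment(gapfree)$rows, gapfree$rows)
})

test_that("distance corrections follow their closed forms", {
  # two rows differing at half the sites -> p = 0.5
  aln <- aligned_set(c(a = "AAAAAAAAAA", b = "AAAAACCCCC"))
  expect_equal(protein_distance(aln, "p")$matrix[1, 2], 0.5)
  expect_equal(protein_distance(aln, "poisson")$matrix[1, 2], -log(0.5),
               tolerance = 1e-9)
  # p = 0.3
  aln3 <- aligned_set(c(a = "AAAAAAAAAA", b = "AAAAAAACCC"))
  expect_equal(protein_distance(aln3, "kimura")$matrix[1, 2],
               -log(1 - 0.3 - 0.2 * 0.09), tolerance = 1e-9)
  # identical rows are at distance zero; pairwise gaps are excluded
  aln0 <- aligned_set(c(a = "MT-EY", b = "MTSEY"))
  expect_equal(protein_distance(aln0, "p")$matrix[1, 2], 0)
  expect_equal(protein_distance(aln0, "p")$n_sites[1, 2], 4L)
})

test_that("kimura >= poisson >= p over (0, 0.7) and saturation is flagged", {
  for (p in seq(0.05, 0.7, by = 0.05)) {
    pois <- -log(1 - p)
    kim <- -log(1 - p - 0.2 * p^2)
    expect_gte(kim, pois)
    expect_gte(pois, p)
  }
  # p high enough to saturate the kimura argument
  aln <- aligned_set(c(a = strrep("A", 10), b = strrep("C", 10)))
  d <- protein_distance(aln, "kimura", ceiling = 7)
  expect_true(d$saturated[1, 2])
  expect_equal(d$matrix[1, 2], 7)
})

test_that("three-taxon tree has the closed-form branch lengths", {
  m <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.4,
                0.5, 0.4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  phy <- bionj_tree(m)
  bl <- setNames(phy$edge.length[match(1:3, phy$edge[, 2])], phy$tip.label)
  expect_equal(unname(bl["A"]), (0.3 + 0.5 - 0.4) / 2, tolerance = 1e-9)
  expect_equal(unname(bl["B"]), (0.3 + 0.4 - 0.5) / 2, tolerance = 1e-9)
  expect_equal(unname(bl["C"]), (0.5 + 0.4 - 0.3) / 2, tolerance = 1e-9)
})

test_that("additive matrices are reconstructed exactly", {
  skip_if_not_installed("phangorn")
  set.seed(47)
  for (n in c(5, 6, 8)) {
    tr <- random_tree(n)
    D <- ape::cophenetic.phylo(tr)
    phy <- bionj_tree(D)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), phy), 0)
    # path-length matrix of the reconstruction equals the input
    expect_equal(ape::cophenetic.phylo(phy)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9)
  }
})

test_that("degenerate and invalid distance inputs are handled", {
  m2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  phy <- bionj_tree(m2)
  expect_equal(sort(phy$tip.label), c("A", "B"))
  expect_equal(sum(phy$edge.length), 0.4)
  bad <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(bionj_tree(bad), "symmetric")
})

test_that("bootstrap supports are deterministic under a fixed seed", {
  sim <- simulate_family("KRAS4B-like", n_leaves = 6, branch_length = 0.12,
                         rate = 0.3, seed = 53)
  aln <- sim_alignment(sim)
  b1 <- bootstrap_support(aln, "kimura", replicates = 30, seed = 99)
  b2 <- bootstrap_support(aln, "kimura", replicates = 30, seed = 99)
  expect_identical(b1$node.label, b2$node.label)
  sup <- as.numeric(b1$node.label[b1$node.label != ""])
  expect_true(all(sup >= 0 & sup <= 100))
  expect_error(bootstrap_support(aln, replicates = 0), "replicates")
})

test_that("newick round trip preserves topology, lengths and supports", {
  sim <- simulate_family("NRAS-like", n_leaves = 5, branch_length = 0.15,
                         rate = 0.3, seed = 59)
  aln <- sim_alignment(sim)
  phy <- bootstrap_support(aln, "kimura", replicates = 20, seed = 7)
  txt <- write_newick(phy)
  back <- read_newick(txt)
  expect_setequal(tree_bipartitions(back), tree_bipartitions(phy))
  expect_equal(sort(back$edge.length), sort(phy$edge.length), tolerance = 1e-4)
  expect_setequal(setdiff(back$node.label, ""), setdiff(phy$node.label, ""))
})

test_that("labels with metacharacters are quoted in newick output", {
  m <- matrix(c(0, 1, 1, 0), 2, 2,
              dimnames = list(c("sp one", "b"), c("sp one", "b")))
  txt <- write_newick(bionj_tree(m))
  expect_match(txt, "'sp one'", fixed = TRUE)
})

test_that("tree agrees with the independent BioNJ implementation in ape", {
  set.seed(61)
  for (n in c(5, 8)) {
    tr <- random_tree(n)
    D <- ape::cophenetic.phylo(tr)
    mine <- bionj_tree(D)
    theirs <- ape::bionj(as.dist(D))
    expect_equal(phangorn::RF.dist(mine, theirs), 0)
    # ape's implementation works in single precision; compare loosely
    expect_equal(sort(mine$edge.length), sort(theirs$edge.length),
                 tolerance = 1e-4)
  }
})
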