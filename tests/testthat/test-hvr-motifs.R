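test_that("charge model scores basic and acidic residues", {
  expect_identical(net_charge("KKKKKKSKTK"), 8L)
  expect_identical(net_charge(""), 0L)
  expect_identical(net_charge("KEK"), 1L)
  expect_identical(net_charge("HHHH"), 0L)   # histidine neutral
  expect_identical(net_charge("XDX"), -1L)   # X contributes nothing
})

test_that("domain split uses residue 166 by default and flags short records", {
  arch <- build_archetypes()
  hras <- arch$sequence[arch$label == "HRAS-like"]  # 189 aa
  d <- split_domains(hras)
  expect_equal(nchar(d$gdomain), 166)
  expect_equal(nchar(d$hvr), 23)
  expect_equal(d$hvr_start, 167)

  expect_error(split_domains(random_protein(100)), class = "rasevol_short_record")
  expect_warning(d2 <- split_domains(substr(hras, 1, 166)), "empty HVR")
  expect_equal(d2$hvr, "")
})

test_that("anchored split cuts fungal-like extended termini at reference 166", {
  arch <- build_archetypes()
  ref <- arch$sequence[1]
  core <- substr(ref, 1, 166)
  set.seed(9)
  fungal <- paste0(random_protein(40), core, random_protein(44))  # 250 aa
  d <- split_domains(fungal, reference = ref)
  expect_equal(d$hvr_start, 40 + 166 + 1)
  expect_equal(nchar(d$hvr), 44)
})

test_that("CaaX call applies the terminal L/F geranylgeranyl rule", {
  expect_true(classify_caax("KKKKCVIM")$valid)
  expect_equal(classify_caax("KKKKCVIM")$prenyl_type, "farnesyl")
  expect_equal(classify_caax("KKKKCTIL")$prenyl_type, "geranylgeranyl")
  expect_equal(classify_caax("KKKKCTIF")$prenyl_type, "geranylgeranyl")
  bad <- classify_caax("KKKKAVIM")
  expect_false(bad$valid)
  expect_true(is.na(bad$prenyl_type))
  expect_error(classify_caax("CVI"), "shorter")

  # pure function of the last 4 residues: prepending never changes the call
  set.seed(5)
  for (i in 1:10) {
    tail4 <- random_protein(4)
    base <- classify_caax(paste0("AAAA", tail4))
    ext <- classify_caax(paste0(random_protein(sample(4:30, 1)), "AAAA", tail4))
    expect_equal(ext$valid, base$valid)
    expect_equal(ext$prenyl_type, base$prenyl_type)
  }
})

test_that("motif detector finds PBR1 upstream of the palmitoyl cysteine", {
  hvr <- "GDKLRKLNPQDESGCMKCKCVLS"  # PBR1 KLRK, palmitoyl C15/C18, CaaX CVLS
  caax <- classify_caax(hvr, 167)
  palm <- find_palmitoyl_cys(hvr, 167, caax)
  expect_equal(palm, c(181L, 184L))
  hits <- detect_motifs(hvr, 167, caax, palm)
  pbr1 <- hits[hits$kind == "PBR1", ]
  expect_equal(pbr1$peptide, "KLRK")
  expect_equal(pbr1$net_charge, 3L)
  expect_equal(pbr1$start, 169L)
})

test_that("PBR2 requires the hydrophobic second position", {
  # KIRK between the palmitoyl C and the CaaX C matches; KRIK does not
  mk <- function(mid) paste0("GDKLRKNSSDEG", "C", "L", mid, "CIIM")
  caax <- classify_caax(mk("KIRK"), 167)
  palm <- find_palmitoyl_cys(mk("KIRK"), 167, caax)
  hits <- detect_motifs(mk("KIRK"), 167, caax, palm)
  expect_equal(hits$peptide[hits$kind == "PBR2"], "KIRK")
  expect_equal(hits$net_charge[hits$kind == "PBR2"], 3L)

  hits2 <- detect_motifs(mk("KRIK"), 167, classify_caax(mk("KRIK"), 167),
                         find_palmitoyl_cys(mk("KRIK"), 167, caax))
  expect_false("PBR2" %in% hits2$kind)
})

test_that("NB and PBD are both reported on a KRAS4B-type HVR", {
  hvr <- paste0("MHKEKMSK", "KKKKKKSKTK", "CVIM")
  caax <- classify_caax(hvr, 167)
  hits <- detect_motifs(hvr, 167, caax, integer(0))
  expect_equal(hits$peptide[hits$kind == "NB"], "KEK")
  expect_equal(hits$net_charge[hits$kind == "NB"], 1L)
  pbd <- hits[hits$kind == "PBD", ]
  expect_equal(pbd$peptide, "KKKKKKSKTK")
  expect_equal(pbd$net_charge, 8L)
  expect_true(sum(strsplit(pbd$peptide, "")[[1]] %in% c("K", "R")) >= 4)
})

test_that("invalid CaaX blocks PBD and PBR2 with a warning", {
  hvr <- "KKKKKKSKTKAVIM"
  caax <- classify_caax(hvr, 167)
  expect_warning(hits <- detect_motifs(hvr, 167, caax, integer(0)), "CaaX")
  expect_false(any(c("PBD", "PBR2") %in% hits$kind))
})

test_that("phospho acceptor sits at c-4 and must be S or T", {
  caax <- classify_caax("KKKKKKSKTKCVIM", 175)
  expect_equal(detect_phospho_acceptor("KKKKKKSKTKCVIM", 175, caax), 181L)
  caaxT <- classify_caax("KKKKKKTKTKCVIM", 175)
  expect_equal(detect_phospho_acceptor("KKKKKKTKTKCVIM", 175, caaxT), 181L)
  caaxA <- classify_caax("KKKKKKAKTKCVIM", 175)
  expect_true(is.na(detect_phospho_acceptor("KKKKKKAKTKCVIM", 175, caaxA)))
})

test_that("each archetype template annotates to its own label", {
  arch <- build_archetypes()
  labels <- vapply(seq_len(nrow(arch)), function(i) {
    profile_hvr(list(id = arch$label[i], residues = arch$sequence[i],
                     clade = arch$clade[i]))$archetype
  }, character(1))
  expect_equal(labels, arch$label)
})

test_that("profiles without motifs or without a CaaX are unclassified, not errors", {
  p <- profile_hvr(list(id = "bare", residues = paste0(
    substr(build_archetypes()$sequence[1], 1, 166), "GGSGGSGGSGGSGGSGGSAVIM")))
  expect_false(p$valid)
  expect_equal(p$archetype, "unclassified")
})

test_that("motif hit charges are internally consistent", {
  # every stored net_charge equals an independent recount; PBR hits are +3,
  # NB +1, PBD >= +4 by construction of the grammar
  sims <- lapply(build_archetypes()$label, function(l)
    simulate_family(l, n_leaves = 4, branch_length = 0.1, rate = 0.2, seed = 21))
  for (sim in sims) {
    for (i in seq_len(nrow(sim$records))) {
      p <- profile_hvr(sim$records[i, ])
      if (nrow(p$hits) == 0) next
      recount <- vapply(p$hits$peptide, net_charge, integer(1), USE.NAMES = FALSE)
      expect_identical(p$hits$net_charge, recount)
      expect_true(all(p$hits$net_charge[p$hits$kind %in% c("PBR1", "PBR2")] == 3L))
      expect_true(all(p$hits$net_charge[p$hits$kind == "NB"] == 1L))
      expect_true(all(p$hits$net_charge[p$hits$kind == "PBD"] >= 4L))
    }
  }
})

test_that("annotate_hvr renders one motif-table row per record", {
  sim <- simulate_family("KRAS4A-like", n_leaves = 3, rate = 0, seed = 1)
  tab <- annotate_hvr(sim$records)
  expect_equal(nrow(tab), 3)
  expect_equal(unique(tab$archetype), "KRAS4A-like")
  expect_equal(unique(tab$pbr2), "KIRK")
  expect_true(all(tab$valid))
})

test_that("tidy and glance summarise a profile", {
  arch <- build_archetypes()
  p <- profile_hvr(list(id = "k4b", residues = arch$sequence[1],
                        clade = arch$clade[1]))
  td <- tidy(p)
  expect_true(all(c("NB", "PBD", "CaaX", "phospho-acceptor") %in% td$kind))
  g <- glance(p)
  expect_equal(g$archetype, "KRAS4B-like")
  expect_equal(g$pbd_charge, 8L)
})
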