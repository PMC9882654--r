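## Synthetic ortholog-family generator.
##
## Emulates the statistical structure the analysis assumes: families of
## 180-320 aa RAS-like proteins sharing a 166-residue G-domain with two
## frozen switch-region signature blocks, archetype-specific HVRs realizing
## the membrane-anchor motif grammar, and per-lineage gene models with
## introns planted at shared or lineage-specific positions and phases.
## Sequences evolve along a tree under a uniform substitution kernel
## constrained by a per-position class mask; no indels are simulated, so
## generated families are alignment-ready as-is.

## Synthetic 166-residue G-domain scaffold: a RAS-like look-alike (P-loop-,
## G-box-flavoured filler), not a copy of any real sequence, carrying the
## two signature blocks at their canonical positions 31-42 and 59-72.
gdomain_scaffold <- function() {
  seg1 <- "MSDLKVAVLGAPGVGKSTLAHQFVDGHWPE"            # 1-30
  b1   <- "EYDPTIEDSYRK"                              # 31-42
  seg3 <- "DTIEGHEAVLMVYSVT"                          # 43-58
  b2   <- "AGQEEYSAMRDQYM"                            # 59-72
  seg5 <- paste0("RTGEGFLLVF", "SINERGSFDE", "IHTFREQILR",  # 73-166
                 "VKDAERVPMV", "LVGNKADLAH", "REVSTEEGQA",
                 "LARELGMPFI", "ETSAKQRTNV", "DEAFYTLVRE", "IRKH")
  g <- paste0(seg1, b1, seg3, b2, seg5)
  stopifnot(nchar(g) == 166,
            substr(g, 31, 42) == "EYDPTIEDSYRK",
            substr(g, 59, 72) == "AGQEEYSAMRDQYM")
  g
}

gdomain_mask <- function() {
  paste0(strrep(".", 30), strrep("F", 12), strrep(".", 16),
         strrep("F", 14), strrep(".", 94))
}

#' Archetype templates for the six HVR architectures
#'
#' Each template is a full-length synthetic protein (shared G-domain
#' scaffold + archetype HVR) with a per-position constraint mask.  Mask
#' classes: `F` frozen, `B` basic-only (K/R), `H` hydrophobic-only,
#' `A` acidic-only (D/E), `S` S/T-only, `C` cysteine (frozen), `.` free.
#' Free positions never mutate to cysteine, so the palmitoylation
#' architecture of a family is determined by its template.
#'
#' Annotating any template with [profile_hvr()] recovers exactly its own
#' archetype label.
#'
#' @return A tibble with columns `label`, `clade`, `hvr`, `sequence`,
#'   `mask`.
#' @export
build_archetypes <- function() {
  g <- gdomain_scaffold()
  gm <- gdomain_mask()
  hvrs <- tibble(
    label = c("KRAS4B-like", "KRASBL-like", "invertebrate-like",
              "HRAS-like", "NRAS-like", "KRAS4A-like"),
    clade = c("vertebrate", "vertebrate", "invertebrate",
              "vertebrate", "vertebrate", "vertebrate"),
    hvr = c(
      paste0("MHKEKMSK", kras4b_pbd, "CVIM"),
      paste0("MNREKSSK", "KKKKKKSKTK", "CVIL"),
      paste0("MTKDKSSK", "KKKKKRSKTK", "CAIL"),
      "GDKLRKLNPQDESGCMKCKCVLS",
      "GDKIRKHNSQDTESGCMKCVVM",
      "GDKLRKNSSDEGCLKIRKCIIM"
    ),
    hvr_mask = c(
      "..BAB...BBBBBBSBSBCHHF",
      "..BAB...BBBBBBSBSBCHHF",
      "..BAB...BBBBBBSBSBCHHF",
      "..BHBB........C..C.CHHF",
      "..BHBB.........C..CHHF",
      "..BHBB......C.BHBBCHHF"
    )
  )
  stopifnot(nchar(hvrs$hvr) == nchar(hvrs$hvr_mask))
  hvrs |>
    mutate(sequence = paste0(g, .data$hvr),
           mask = paste0(gm, .data$hvr_mask)) |>
    select("label", "clade", "hvr", "sequence", "mask")
}

mask_classes <- function() {
  list(
    "F" = character(0),                 # frozen
    "C" = character(0),                 # cysteine, frozen
    "B" = BASIC,
    "A" = ACIDIC,
    "H" = HYDROPHOBIC,
    "S" = c("S", "T"),
    "." = setdiff(AA20, "C")            # free, but never creates a cysteine
  )
}

mutate_sequence <- function(chars, mask_chars, p_mut, mask_respect) {
  classes <- mask_classes()
  hit <- which(stats::runif(length(chars)) < p_mut)
  for (i in hit) {
    allowed <- if (mask_respect) classes[[mask_chars[i]]] else AA20
    allowed <- setdiff(allowed, chars[i])
    if (length(allowed) == 0) next
    chars[i] <- sample(allowed, 1)
  }
  chars
}

#' Evolve an ortholog family along a tree
#'
#' Starting from an archetype template at the root, each branch mutates each
#' position independently with probability `branch length x rate`
#' (capped at 1).  With `mask_respect = TRUE`, frozen positions never change
#' and class-constrained positions resample within their class;
#' substitutions are drawn uniformly over the allowed residues excluding the
#' current one.
#'
#' @param template One row of [build_archetypes()] (or a list with
#'   `label`, `clade`, `sequence`, `mask`).
#' @param tree An `ape::phylo` or Newick text/path with branch lengths.
#' @param rate Expected substitutions per site per unit branch length
#'   (>= 0).
#' @param mask_respect Honour the constraint mask (default TRUE).
#' @param seed Integer seed; fixed seed gives an identical family.
#' @return An object of class `sim_family`: `records` (tibble with `id`,
#'   `species`, `clade`, `residues`) and `truth` (template label and motif
#'   table, the tree, seed and parameters).
#' @export
evolve_family <- function(template, tree, rate = 0.1, mask_respect = TRUE,
                          seed = 1L) {
  if (rate < 0) abort("rate must be >= 0")
  template <- as.list(as.data.frame(template))
  phy <- if (inherits(tree, "phylo")) tree else read_newick(tree)
  if (is.null(phy) || is.null(phy$edge)) abort("malformed tree")
  if (is.null(phy$edge.length)) abort("tree must have branch lengths")
  phy <- ape::reorder.phylo(phy, "cladewise")

  chars0 <- split1(template$sequence)
  mask_chars <- split1(template$mask)
  stopifnot(length(chars0) == length(mask_chars))

  set.seed(as.integer(seed))
  n_tip <- length(phy$tip.label)
  node_seq <- vector("list", n_tip + phy$Nnode)
  node_seq[[n_tip + 1L]] <- chars0
  for (e in seq_len(nrow(phy$edge))) {
    parent <- phy$edge[e, 1]; child <- phy$edge[e, 2]
    p_mut <- min(1, phy$edge.length[e] * rate)
    node_seq[[child]] <- mutate_sequence(node_seq[[parent]], mask_chars,
                                         p_mut, mask_respect)
  }
  records <- tibble(
    id = phy$tip.label,
    species = phy$tip.label,
    clade = template$clade,
    residues = vapply(seq_len(n_tip), function(i)
      paste(node_seq[[i]], collapse = ""), character(1))
  )
  template_profile <- profile_hvr(list(id = "template",
                                       residues = template$sequence,
                                       clade = template$clade))
  structure(list(
    records = records,
    truth = list(
      archetype = template$label,
      clade = template$clade,
      tree = phy,
      template = template$sequence,
      mask = template$mask,
      motifs = tidy(template_profile),
      seed = as.integer(seed),
      params = list(rate = rate, mask_respect = mask_respect)
    )
  ), class = "sim_family")
}

#' @export
print.sim_family <- function(x, ...) {
  cat(sprintf("<sim_family: %d x %s leaves (rate %g, seed %d)>\n",
              nrow(x$records), x$truth$archetype,
              x$truth$params$rate, x$truth$seed))
  invisible(x)
}

#' Deterministic balanced tree
#'
#' Recursively bisects the leaf set, giving a balanced unrooted-ready
#' bifurcating topology with equal branch lengths — the shape used for
#' seeded simulation checks.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param branch_length Length of every branch.
#' @param labels Optional leaf labels (default `t01`, `t02`, ...).
#' @return An `ape::phylo`.
#' @export
balanced_tree <- function(n_leaves, branch_length = 0.1, labels = NULL) {
  if (n_leaves < 2) abort("need at least 2 leaves")
  if (is.null(labels)) {
    labels <- sprintf("t%02d", seq_len(n_leaves))
  }
  build <- function(labs) {
    if (length(labs) == 1) return(labs)
    k <- ceiling(length(labs) / 2)
    sprintf("(%s:%g,%s:%g)", build(labs[seq_len(k)]), branch_length,
            build(labs[-seq_len(k)]), branch_length)
  }
  ape::read.tree(text = paste0(build(labels), ";"))
}

#' Simulate a family from a named archetype
#'
#' Convenience wrapper: picks the archetype template, builds a balanced tree
#' (unless one is supplied) and calls [evolve_family()].
#'
#' @param archetype One of the labels of [build_archetypes()].
#' @param n_leaves Number of leaves for the default balanced tree.
#' @param branch_length Branch length of the default tree.
#' @inheritParams evolve_family
#' @export
simulate_family <- function(archetype = "KRAS4B-like", n_leaves = 12,
                            branch_length = 0.1, tree = NULL, rate = 0.1,
                            mask_respect = TRUE, seed = 1L) {
  arch <- build_archetypes()
  if (!archetype %in% arch$label) {
    abort(sprintf("unknown archetype '%s'", archetype))
  }
  if (is.null(tree)) tree <- balanced_tree(n_leaves, branch_length)
  evolve_family(arch[arch$label == archetype, ], tree, rate = rate,
                mask_respect = mask_respect, seed = seed)
}

#' Default intron plan: the canonical three-intron vertebrate structure
#'
#' Introns a, b and c in phases 0, 2 and 0 at coding offsets 93, 272 and 432
#' (for a 188-residue protein these imply coding-exon lengths 93, 179, 160
#' and 135).  Optional invertebrate intron d (phase 0, splitting exon 2) and
#' lineage-specific introns can be added via the `extra` argument of
#' [make_gene_models()] or by binding rows.
#'
#' @return Tibble with columns `label`, `protein_position`, `phase`,
#'   `lineages` (NA = all lineages).
#' @export
vertebrate_intron_plan <- function() {
  tibble(
    label = c("a", "b", "c"),
    protein_position = c(32L, 91L, 145L),
    phase = c(0L, 2L, 0L),
    lineages = NA_character_
  )
}

plan_cds_offset <- function(protein_position, phase) {
  as.integer((protein_position - 1L) * 3L + ifelse(phase == 0L, 0L, phase))
}

#' Plant gene models with known intron structure
#'
#' Builds one gene model per record whose computed introns reproduce the
#' planned positions and phases exactly.  A plan row applies to a record
#' when its `lineages` field is `NA` or contains the record id in a
#' comma-separated list; intron losses are expressed by listing only the
#' retaining lineages.
#'
#' @param records Record tibble (`id`, `residues`) — typically
#'   `sim$records`.
#' @param plan Intron-plan tibble (see [vertebrate_intron_plan()]).
#' @param intron_length Genomic length of every intron (default 200).
#' @param origin Genomic start coordinate of each gene (default 1000).
#' @param strand `"+"` or `"-"` layout (default `"+"`).
#' @return A list: `gene_models` (validated tibble covering all records,
#'   gene ids equal to record ids) and `truth` (planned introns per gene).
#' @export
make_gene_models <- function(records, plan = vertebrate_intron_plan(),
                             intron_length = 200L, origin = 1000L,
                             strand = "+") {
  if (anyDuplicated(plan$label)) abort("duplicate intron labels in plan")
  out <- purrr::map(seq_len(nrow(records)), function(i) {
    id <- records$id[i]
    cds_len <- 3L * (nchar(records$residues[i]) + 1L)  # stop codon included
    mine <- plan[is.na(plan$lineages) |
                   purrr::map_lgl(plan$lineages, function(l)
                     id %in% trimws(strsplit(l, ",")[[1]])), , drop = FALSE]
    offsets <- plan_cds_offset(mine$protein_position, mine$phase)
    if (anyDuplicated(offsets)) abort("duplicate intron positions in plan")
    if (any(offsets <= 0 | offsets >= cds_len)) {
      abort(sprintf("intron plan position beyond CDS of '%s'", id))
    }
    ord <- order(offsets)
    offsets <- offsets[ord]
    exon_lens <- diff(c(0L, offsets, cds_len))
    n_ex <- length(exon_lens)
    starts_tx <- origin + cumsum(c(0L, head(exon_lens, -1))) +
      intron_length * (seq_len(n_ex) - 1L)
    ends_tx <- starts_tx + exon_lens
    if (strand == "-") {
      span_hi <- max(ends_tx)
      new_starts <- span_hi - ends_tx + origin
      new_ends <- span_hi - starts_tx + origin
      starts_tx <- new_starts; ends_tx <- new_ends
    }
    gm <- gene_model(id, cbind(starts_tx, ends_tx), region_id = paste0("chr_", id),
                     strand = strand)
    truth <- tibble(gene_id = id, label = mine$label[ord],
                    cds_offset = offsets,
                    phase = mine$phase[ord],
                    protein_position = mine$protein_position[ord])
    list(gm = gm, truth = truth)
  })
  list(
    gene_models = bind_rows(purrr::map(out, "gm")),
    truth = bind_rows(purrr::map(out, "truth"))
  )
}
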