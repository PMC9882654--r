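Package: rasevol
Title: Membrane-Anchor Motif Annotation and Molecular Evolution of RAS
    Ortholog Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates the C-terminal hypervariable region (HVR) of
    RAS-family GTPase orthologs with membrane-targeting motifs (CaaX
    prenylation box with the farnesyl/geranylgeranyl terminal-residue
    rule, polybasic regions PBR1 and PBR2, the neutralized-basic NB
    triplet, the polybasic domain PBD, palmitoylatable cysteines and the
    phospho-acceptor position) and classifies each sequence into an
    isoform archetype.  Computes intron positions and phases from
    coding-exon models, projects them onto a protein alignment and
    clusters homologous introns across species.  Scans G-domains for
    conserved switch-region signature blocks, builds pairwise-identity
    matrices with an affine-gap global aligner, reconstructs BioNJ
    distance trees with bootstrap support, and ships a seeded simulator
    of ortholog families with constraint-masked sequence evolution and
    planted intron structures so the whole pipeline runs at desk scale
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    GenomicRanges,
    jsonlite,
    optparse,
    phangorn,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
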