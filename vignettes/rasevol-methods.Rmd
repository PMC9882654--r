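---
title: "Methods: motif grammars, intron homology, and distance trees in rasevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif grammars, intron homology, and distance trees in rasevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rasevol)
```

# The analysis

RAS-family GTPases consist of a conserved catalytic G-domain (residues
1–166) and a short C-terminal hypervariable region (HVR, roughly 18–23
residues) that carries all of the protein's membrane-targeting information.
`rasevol` implements a comparative pipeline over ortholog families of such
proteins: it annotates each HVR under a motif grammar, classifies sequences
into isoform archetypes, maps intron positions and phases onto a shared
protein alignment to find homologous introns, scans G-domains for two
diagnostic switch-region signature blocks, computes pairwise-identity
matrices, and reconstructs BioNJ distance trees with bootstrap support.  A
seeded simulator generates ortholog families with known truth so every
stage can be validated end to end at desk scale.

# The HVR motif grammar

The grammar encodes the canonical membrane-anchor architectures of the RAS
isoforms:

* **CaaX box** — the last four residues.  The call is valid iff the
  fourth-from-last residue is cysteine.  A terminal leucine or
  phenylalanine signals modification with the 20-carbon geranylgeranyl
  lipid; any other terminal residue signals the 15-carbon farnesyl lipid.
  The call is deliberately a pure function of the last four residues.
* **Charge model** — net charge is +1 per K/R and −1 per D/E; histidine
  and everything else count 0, a reasonable approximation at physiological
  pH.  Under this model the human KRAS4B polylysine second signal
  `KKKKKKSKTK` (shipped as the constant `kras4b_pbd`) scores +8, and every
  PBR consensus match scores exactly +3.
* **PBR1/PBR2** — the four-residue polybasic consensus
  `[K/R][hydrophobic][K/R][K/R]`.  The hydrophobic class is
  {A, V, L, I, M, F, W, Y} (the standard strongly hydrophobic set; the
  grammar's source material names no explicit set).  PBR1 is searched
  strictly upstream of the first palmitoylatable cysteine; PBR2 strictly
  between the last palmitoylatable cysteine and the CaaX cysteine.  In
  sequences with no palmitoyl cysteines (KRAS4B-type architectures) PBR1 is
  still searched upstream of the PBD so the annotator does not presuppose
  the archetype.  The leftmost match always wins, for determinism.
* **NB** — the "neutralized basic" triplet `[K/R][D/E][K/R]`, searched in
  the region upstream of the PBD (or upstream of the CaaX cysteine when no
  PBD exists).
* **PBD** — the polybasic domain: within the 10-residue window ending
  immediately before the CaaX cysteine, the *longest* suffix that starts at
  a K/R, contains at least four K/R and keeps net charge ≥ +4.  We chose
  the longest (rather than shortest) qualifying suffix deliberately: the
  canonical KRAS4B polylysine stretch contains interspersed S/T and must be
  reported whole, at its published +8 charge — a shortest-suffix rule would
  truncate it to a +4 hexapeptide and misstate the electrostatics.
* **Phospho-acceptor** — position `c − 4`, i.e. exactly three residues
  strictly between the acceptor and the CaaX cysteine `c`, reported iff it
  is S or T.  This offset makes serine 181 of human KRAS4B (CaaX cysteine
  185) the canonical acceptor.  The offset is a fixed design choice; do not
  change it silently, since "three residues upstream" admits more than one
  reading.
* **Palmitoylatable cysteines** — every HVR cysteine except the CaaX
  cysteine.  No enzymology is predicted; these are candidate sites only.

Archetype classification is a fixed-precedence decision table
(`classify_archetype()`): PBD+NB+phospho with no palmitoyl cysteine maps to
KRAS4B-like (farnesyl) or, when geranylgeranylated, to KRASBL-like for
vertebrate-labelled records and invertebrate-like otherwise; PBR1 with two
palmitoyl cysteines is HRAS-like; PBR1 with one palmitoyl cysteine is
KRAS4A-like when PBR2 is present and NRAS-like when it is not; anything
else is unclassified.  Precedence resolves ambiguity deterministically.

# Domain splitting

By default the G-domain is residues 1–166 and the HVR starts at 167.  For
proteins with extended termini (fungal orthologs run to 213–322 residues),
anchored mode pairwise-aligns the record to a user-supplied reference and
cuts after the column aligned to reference residue 166; an anchor landing
inside a gap run longer than 10 columns is rejected as unreliable.

# Intron phases and homology

Intron phase is the position of the intron relative to codon boundaries
(0 between codons, 1 after the first nucleotide, 2 after the second).  From
a gene model with coding exons in transcript order, each inter-exon
junction gets `cds_offset` (coding nucleotides upstream), `phase =
cds_offset mod 3` and a protein position: the interrupted residue for
phases 1/2, the residue following the boundary for phase 0.  Homology is
exact: two introns are homologous iff they project to the same alignment
column with the same phase.  Phase-0 boundaries never merge with phase-1/2
residue positions, and no fuzz window is applied — the published rule is
exact co-location, and on near-identical G-domain alignments a slack
window would only manufacture false homologies.  Groups are lettered a, b,
c, … by ascending column (ties by ascending phase).

The canonical vertebrate structure — four coding exons of 93, 179, 160 and
135 nt with introns a/b/c in phases 0/2/0 — is the simulator's default
intron plan.

# Signature blocks

Two G-domain blocks are diagnostic of the RAS oncoprotein lineage:
`EYDPTIEDSYRK` at residues 31–42 (overlapping switch I, 30–40) and
`AGQEEYSAMRDQYM` at 59–72 (overlapping switch II, 58–72).  Scanning is
ungapped Hamming distance — the blocks are fixed-length motifs in
near-identical domains, so edit-distance flexibility would add parameters
without adding sensitivity.  `X` counts as a mismatch even against itself.
The two blocks are scanned independently; a combined report row gives
switch-region overlaps per hit.  Conservation scanning
(`conserved_blocks()`) reports maximal runs of gap-free columns identical
across all rows; a column containing any gap can never be 100% identical.

# Pairwise alignment and identity

`global_align()` is an affine-gap Needleman–Wunsch (Gotoh three-state)
implemented in C++, scoring with BLOSUM62 and BLAST-style gap costs
(existence 11, extension 1; a gap of length *k* costs 11 + *k*).
Tie-breaking in the traceback is fixed — diagonal first, then a gap in the
first sequence — so outputs are deterministic.  Percent identity divides by
total alignment columns, gapped columns included, matching the
`Identities = n/m` convention of common pairwise-alignment servers;
`denominator = "ungapped"` is available.  In the test suite the aligner is
checked against both an independent plain-R dynamic program and
`Biostrings::pairwiseAlignment`.

`progressive_msa()` is a minimal deterministic progressive aligner (guide
order by single-linkage on pairwise p-distances, then profile-profile
alignment under the same scoring).  It is a convenience for near-identical
families; divergent sets should be aligned externally and supplied as
aligned FASTA.

# Distances and trees

Distances are computed per pair over the columns where neither row is
gapped: p-distance, Poisson correction `−ln(1−p)`, or the Kimura protein
correction `−ln(1 − p − 0.2p²)` (default).  Saturated pairs are set to a
ceiling (default 10) and flagged.  The Kimura correction stands in for full
rate-matrix maximum-likelihood distances; on the near-identical families
this pipeline targets the corrections differ negligibly, and the
substitution-model machinery is deliberately out of scope.

`bionj_tree()` implements BioNJ in double precision: standard NJ
Q-criterion for pair selection, NJ split formula for branch lengths, and
the variance-weighted BioNJ lambda for the matrix reduction.  Ties are
broken by the lowest label-index pair; negative branch lengths are clamped
to zero with a warning; two taxa yield one evenly split edge.  On additive
matrices the generating topology and branch lengths are recovered exactly
(within 1e-9), which is the property the test suite asserts against random
5–8 leaf trees; `ape::bionj` (an independent single-precision
implementation) serves as a cross-check, not as the implementation.
Bootstrap support resamples alignment columns with replacement (via
`ape::boot.phylo`), rebuilds the tree per replicate, and reports the
percentage of replicates containing each internal bipartition; a single
integer seed makes supports bit-identical across runs.

# The synthetic-data generator

`build_archetypes()` defines six templates, one per HVR architecture.  The
G-domain scaffold is a synthetic 166-residue RAS-like sequence (not a copy
of any real protein) carrying the two signature blocks at 31–42 and 59–72;
the KRAS4B polylysine decapeptide `KKKKKKSKTK` is retained verbatim in the
KRAS4B-like HVR because the +8 charge claim anchors to that exact peptide.
Each position carries a constraint class: frozen (signature blocks, CaaX
cysteine and terminal residue), basic-only, hydrophobic-only, acidic-only,
S/T-only, cysteine, or free.

`evolve_family()` evolves the template along a tree: on each branch every
position mutates independently with probability `branch length × rate`
(capped at 1), resampling uniformly within its allowed class and excluding
the current residue.  Design choices worth stating:

* The kernel is uniform within classes, not an empirical rate matrix.  It
  is sufficient to exercise every downstream statistic; relative rates and
  exchangeabilities are irrelevant to what the pipeline measures.
* Free positions never mutate to cysteine.  HVR cysteine content is
  motif-defining (it determines the palmitoylation architecture), so
  cysteines exist only where a template places them.  This is what makes
  archetype recovery exact under moderate masked divergence.
* No indels are simulated; generated families are alignment-ready
  as-is.  The analyses concern near-gap-free regions, and gap handling is
  exercised through user-style fixtures instead.

Defaults mirror the study conditions the pipeline assumes: families of 12
leaves on balanced trees with branch length 0.1 and rate 0.1
substitutions/site, i.e. ~1% expected change per site per branch with the
signature mask respected.  What passing tests on these families shows is
that the *method* recovers planted truth exactly under in-model conditions;
it does not certify behaviour on real data with indels, compositional
drift, or alignment error.

`make_gene_models()` plants gene models whose computed introns reproduce a
plan of (protein position, phase) pairs exactly, with per-lineage
inclusion for lineage-specific introns and losses; exons are laid out with
200-nt introns on either strand.

# Numerical and degenerate-input choices

* Genomic coordinates are 0-based half-open; protein positions and residue
  indices are 1-based; alignment columns are 0-based.
* The stop codon is excluded from protein length but included in the
  mod-3 CDS completeness check (CDS length = 3 × (protein length + 1)).
* `X` is accepted on input and always scores as mismatch/zero
  charge/non-motif.
* A record of exactly 166 residues yields an empty HVR with a warning, not
  an error; batch annotation converts per-record failures into profiles
  flagged invalid instead of aborting.
* Alignment curation drops columns whose gap fraction strictly exceeds the
  threshold (default 0.2) and errors if nothing survives.

# Problem sizes

The shipped tests run simulations of 3–12 leaves on ~190-residue proteins,
bootstrap at 20–200 replicates, and alignment property checks on random
pairs up to 40 residues; the whole suite completes in well under a minute
on one CPU.  These sizes were chosen as the smallest that make the
statistical properties (bootstrap support ≥ 95 on a clean split, ≥ 90%
exact topology recovery) non-trivial.

# Known limitations

* The progressive MSA is not a general-purpose aligner; use it only on
  near-identical families.
* Distance trees use corrections, not likelihood; very divergent or
  saturated data should go to a dedicated ML tool.
* The motif grammar is positional and charge-based; it does not predict
  actual palmitoylation or phosphorylation, and pKa-dependent charge at
  arbitrary pH is out of scope.
* Splice-site signals are not inspected; gene models are trusted as given.
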