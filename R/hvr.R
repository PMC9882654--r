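## Membrane-anchor (HVR) motif grammar.
##
## RAS-family GTPases end in a hypervariable region (HVR) carrying the
## membrane-targeting signals: a C-terminal CaaX prenylation box, and a
## "second signal" that is either a polybasic domain (PBD, KRAS4B-type) or
## palmitoylatable cysteines flanked by short polybasic regions (PBR1/PBR2,
## HRAS/NRAS/KRAS4A-type).  The grammar implemented here:
##   CaaX  - last four residues; valid iff position length-3 is C; terminal
##           L or F signals geranylgeranylation, anything else farnesylation.
##   PBR   - [K/R][hydrophobic][K/R][K/R], net charge +3 by construction.
##   NB    - [K/R][D/E][K/R] "neutralized basic" triplet, net charge +1.
##   PBD   - polybasic stretch of <=10 residues immediately upstream of the
##           CaaX cysteine with >=4 K/R and net charge >= +4.
##   phospho-acceptor - S/T at position c-4 (three residues strictly between
##           it and the CaaX cysteine c), the S181 analogue of human KRAS4B.

#' Net charge of a peptide at physiological pH
#'
#' Simple residue-count charge model: +1 per K or R, -1 per D or E, 0 for
#' everything else (histidine is treated as neutral at physiological pH).
#' This is the model under which the human KRAS4B polylysine second signal
#' `KKKKKKSKTK` scores +8 and every PBR consensus match scores +3.
#'
#' @param peptide Character scalar (may be empty).
#' @return Integer net charge.
#' @examples
#' net_charge("KKKKKKSKTK") # +8
#' net_charge("KEK")        # +1
#' @export
net_charge <- function(peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1)
  if (nchar(peptide) == 0) return(0L)
  chars <- split1(toupper(peptide))
  as.integer(sum(chars %in% BASIC) - sum(chars %in% ACIDIC))
}

#' The human KRAS4B polylysine decapeptide
#'
#' The second-signal polybasic stretch of human KRAS4B (residues 175-184),
#' kept verbatim as the package's charge-model anchor fixture: its net charge
#' under [net_charge()] is +8.
#' @format A character scalar, `"KKKKKKSKTK"`.
#' @export
kras4b_pbd <- "KKKKKKSKTK"

#' Split a RAS protein into G-domain and HVR
#'
#' Default mode cuts after residue 166 (the catalytic G-domain spans residues
#' 1-166; the remainder is the HVR).  Anchored mode, for proteins with
#' extended termini (fungal orthologs run to 213-322 residues), pairwise-aligns
#' the record to a reference G-domain and cuts after the column aligned to
#' reference residue 166.
#'
#' @param record One-row tibble (or list) with `id` and `residues`, or a plain
#'   character sequence.
#' @param reference Optional reference sequence (character) whose residue 166
#'   anchors the cut in anchored mode.
#' @param gdomain_end Last residue of the G-domain (default 166).
#' @return A list with `gdomain`, `hvr` and `hvr_start` (1-based index of the
#'   first HVR residue; `hvr` may be empty, with a warning).
#' @export
split_domains <- function(record, reference = NULL, gdomain_end = 166L) {
  seqs <- as_sequence(record)
  n <- nchar(seqs$residues)
  if (is.null(reference)) {
    if (n < gdomain_end) {
      abort(sprintf("record '%s' is shorter (%d aa) than the G-domain (%d aa)",
                    seqs$id, n, gdomain_end), class = "rasevol_short_record")
    }
    cut <- gdomain_end
  } else {
    reference <- as_sequence(reference)$residues
    if (nchar(reference) < gdomain_end) abort("reference shorter than G-domain")
    pw <- global_align(seqs$residues, reference)
    b_chars <- split1(pw$row_b)
    a_chars <- split1(pw$row_a)
    ref_cols <- which(b_chars != "-")
    anchor_col <- ref_cols[gdomain_end]
    # reject anchors landing inside a long gap run of the record
    if (a_chars[anchor_col] == "-") {
      run <- rle(a_chars == "-")
      idx <- cumsum(run$lengths)
      k <- which(idx >= anchor_col)[1]
      if (run$lengths[k] > 10) {
        abort(sprintf(
          "reference residue %d aligns inside a %d-column gap of record '%s'",
          gdomain_end, run$lengths[k], seqs$id), class = "rasevol_anchor_gap")
      }
    }
    cut <- sum(a_chars[seq_len(anchor_col)] != "-")
  }
  if (cut >= n) {
    warn(sprintf("record '%s' has an empty HVR (length %d, cut at %d)",
                 seqs$id, n, cut))
  }
  list(
    gdomain = substr(seqs$residues, 1, cut),
    hvr = if (cut < n) substr(seqs$residues, cut + 1, n) else "",
    hvr_start = cut + 1L
  )
}

as_sequence <- function(record) {
  if (is.character(record) && length(record) == 1) {
    return(list(id = "<sequence>", residues = toupper(record)))
  }
  rec <- as.list(record)
  if (is.null(rec$residues)) abort("record must carry a `residues` field")
  list(id = if (!is.null(rec$id)) rec$id else "<sequence>",
       residues = toupper(rec$residues[[1]]))
}

#' Classify the C-terminal CaaX prenylation box
#'
#' Inspects the final four residues of the HVR.  The call is valid iff the
#' fourth-from-last residue is a cysteine; a terminal L or F signals
#' geranylgeranylation (20-carbon lipid), anything else farnesylation
#' (15-carbon).  The call is a pure function of the last four residues.
#'
#' @param hvr_segment HVR sequence (length >= 4).
#' @param hvr_start 1-based whole-protein position of the first HVR residue,
#'   used to report `cys_position` in protein coordinates.
#' @return A list of class `caax_call`: `valid`, `cys_position`, `a1`, `a2`,
#'   `x`, `prenyl_type` (`"farnesyl"`, `"geranylgeranyl"` or `NA`),
#'   `peptide`.
#' @examples
#' classify_caax("KKKKKKSKTKCVIM", 175)$prenyl_type   # farnesyl
#' classify_caax("KKKKKKSKTKCVIL", 175)$prenyl_type   # geranylgeranyl
#' @export
classify_caax <- function(hvr_segment, hvr_start = 1L) {
  hvr_segment <- toupper(hvr_segment)
  n <- nchar(hvr_segment)
  if (n < 4) abort("HVR segment shorter than a CaaX box (4 residues)")
  box <- split1(substr(hvr_segment, n - 3, n))
  valid <- box[1] == "C"
  structure(list(
    valid = valid,
    cys_position = hvr_start + n - 4L,
    a1 = box[2], a2 = box[3], x = box[4],
    prenyl_type = if (!valid) NA_character_
                  else if (box[4] %in% c("L", "F")) "geranylgeranyl"
                  else "farnesyl",
    peptide = paste(box, collapse = "")
  ), class = "caax_call")
}

## leftmost window in residues[lo..hi] (1-based, inclusive) matching a class
## pattern; pattern is a list of allowed-residue vectors
find_motif <- function(chars, lo, hi, pattern) {
  k <- length(pattern)
  if (hi - lo + 1 < k) return(NA_integer_)
  for (s in lo:(hi - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!chars[s + j - 1] %in% pattern[[j]]) { ok <- FALSE; break }
    }
    if (ok) return(s)
  }
  NA_integer_
}

pbr_pattern <- list(BASIC, HYDROPHOBIC, BASIC, BASIC)
nb_pattern <- list(BASIC, ACIDIC, BASIC)

motif_hit <- function(kind, start_hvr, peptide, hvr_start) {
  tibble(
    kind = kind,
    start = hvr_start + start_hvr - 1L,
    end = hvr_start + start_hvr + nchar(peptide) - 2L,
    peptide = peptide,
    net_charge = net_charge(peptide)
  )
}

#' Detect polybasic membrane-anchor motifs in an HVR
#'
#' Annotates the HVR with the polybasic motif grammar:
#' * **PBD** — the polybasic domain: within the 10-residue window ending
#'   immediately before the CaaX cysteine, the longest suffix that starts at a
#'   K/R, contains at least four K/R and has net charge >= +4.
#' * **NB** — leftmost `[K/R][D/E][K/R]` triplet upstream of the PBD (or of
#'   the CaaX cysteine when no PBD exists).
#' * **PBR1** — leftmost `[K/R][hydrophobic][K/R][K/R]` 4-mer strictly
#'   upstream of the first palmitoylatable cysteine; in sequences without
#'   palmitoyl cysteines the region upstream of the PBD/CaaX is searched.
#' * **PBR2** — the same consensus strictly between the last palmitoyl
#'   cysteine and the CaaX cysteine.
#'
#' All positions are reported in whole-protein coordinates.  An invalid CaaX
#' call blocks PBD and PBR2 (reported absent with a warning).
#'
#' @param hvr_segment HVR sequence.
#' @param hvr_start Whole-protein position of the first HVR residue.
#' @param caax A [classify_caax()] call for this segment.
#' @param palmitoyl_cys Whole-protein positions of HVR cysteines excluding the
#'   CaaX cysteine (see [find_palmitoyl_cys()]).
#' @return A tibble of motif hits: `kind`, `start`, `end`, `peptide`,
#'   `net_charge`.
#' @export
detect_motifs <- function(hvr_segment, hvr_start, caax,
                          palmitoyl_cys = integer(0)) {
  chars <- split1(toupper(hvr_segment))
  n <- length(chars)
  hits <- list()
  palm_local <- palmitoyl_cys - hvr_start + 1L

  cys_local <- if (isTRUE(caax$valid)) caax$cys_position - hvr_start + 1L else NA_integer_
  if (!isTRUE(caax$valid)) {
    warn("invalid CaaX call: PBD and PBR2 not searched")
  }

  ## PBD: longest qualifying suffix of the <=10-residue window before the C
  pbd_start_local <- NA_integer_
  if (!is.na(cys_local) && cys_local > 1L) {
    win_lo <- max(1L, cys_local - 10L)
    for (s in win_lo:(cys_local - 1L)) {
      if (!chars[s] %in% BASIC) next
      pep <- paste(chars[s:(cys_local - 1L)], collapse = "")
      if (sum(split1(pep) %in% BASIC) >= 4 && net_charge(pep) >= 4) {
        pbd_start_local <- s
        hits$PBD <- motif_hit("PBD", s, pep, hvr_start)
        break
      }
    }
  }

  ## NB: upstream of the PBD (or of the CaaX cysteine when no PBD)
  nb_hi <- if (!is.na(pbd_start_local)) pbd_start_local - 1L
           else if (!is.na(cys_local)) cys_local - 1L else n
  s <- find_motif(chars, 1L, nb_hi, nb_pattern)
  if (!is.na(s)) {
    hits$NB <- motif_hit("NB", s, paste(chars[s:(s + 2L)], collapse = ""), hvr_start)
  }

  ## PBR1: strictly upstream of the first palmitoyl cysteine, or of the
  ## PBD/CaaX when no palmitoyl cysteine exists
  pbr1_hi <- if (length(palm_local) > 0) min(palm_local) - 1L else nb_hi
  s <- find_motif(chars, 1L, pbr1_hi, pbr_pattern)
  if (!is.na(s)) {
    hits$PBR1 <- motif_hit("PBR1", s, paste(chars[s:(s + 3L)], collapse = ""), hvr_start)
  }

  ## PBR2: strictly between the last palmitoyl cysteine and the CaaX cysteine
  if (!is.na(cys_local) && length(palm_local) > 0) {
    lo <- max(palm_local) + 1L
    hi <- cys_local - 1L
    s <- find_motif(chars, lo, hi, pbr_pattern)
    if (!is.na(s)) {
      hits$PBR2 <- motif_hit("PBR2", s, paste(chars[s:(s + 3L)], collapse = ""), hvr_start)
    }
  }

  if (length(hits) == 0) {
    return(tibble(kind = character(), start = integer(), end = integer(),
                  peptide = character(), net_charge = integer()))
  }
  bind_rows(hits[intersect(c("PBR1", "PBR2", "NB", "PBD"), names(hits))])
}

#' Palmitoylatable cysteines of an HVR
#'
#' All cysteines in the HVR excluding the CaaX cysteine, in whole-protein
#' coordinates.  These are candidate palmitoylation sites (the second signal
#' of the HRAS/NRAS/KRAS4A archetypes); no enzymology is predicted.
#'
#' @inheritParams detect_motifs
#' @return Integer vector of positions.
#' @export
find_palmitoyl_cys <- function(hvr_segment, hvr_start, caax) {
  chars <- split1(toupper(hvr_segment))
  pos <- which(chars == "C") + hvr_start - 1L
  if (isTRUE(caax$valid)) pos <- setdiff(pos, caax$cys_position)
  as.integer(pos)
}

#' Phospho-acceptor position upstream of the CaaX box
#'
#' Reports position `c - 4` (three residues strictly between it and the CaaX
#' cysteine `c`) iff that residue is serine or threonine — the analogue of
#' phospho-serine 181 upstream of cysteine 185 in human KRAS4B.
#'
#' @inheritParams detect_motifs
#' @return Whole-protein position of the acceptor, or `NA` if absent.
#' @export
detect_phospho_acceptor <- function(hvr_segment, hvr_start, caax) {
  if (!isTRUE(caax$valid)) return(NA_integer_)
  chars <- split1(toupper(hvr_segment))
  cys_local <- caax$cys_position - hvr_start + 1L
  acc_local <- cys_local - 4L
  if (acc_local < 1) return(NA_integer_)
  if (chars[acc_local] %in% c("S", "T")) acc_local + hvr_start - 1L else NA_integer_
}

#' Annotate the full membrane-anchor architecture of one sequence
#'
#' Composition of [split_domains()], [classify_caax()],
#' [find_palmitoyl_cys()], [detect_motifs()], [detect_phospho_acceptor()] and
#' [classify_archetype()].  Sub-operation failures are captured into a profile
#' flagged `valid = FALSE` rather than aborting a batch run.
#'
#' @param record One-row tibble with `id`, `residues` and optionally
#'   `species`, `clade`; or a plain character sequence.
#' @param reference Optional reference for anchored domain splitting.
#' @return An object of class `hvr_profile`.  Use [tidy()] for the motif-hit
#'   table and [glance()] for a one-row summary.
#' @export
profile_hvr <- function(record, reference = NULL) {
  seqs <- as_sequence(record)
  field <- function(nm) {
    if (is.character(record)) return(NA_character_)
    v <- as.list(record)[[nm]]
    if (is.null(v)) NA_character_ else v[[1]]
  }
  clade <- field("clade")
  species <- field("species")
  prof <- list(
    record_id = seqs$id, species = species, clade = clade,
    valid = TRUE, notes = character(0)
  )
  res <- tryCatch({
    doms <- withCallingHandlers(
      split_domains(seqs$residues, reference = reference),
      warning = function(w) invokeRestart("muffleWarning")
    )
    prof$hvr_start <- doms$hvr_start
    prof$gdomain <- doms$gdomain
    prof$hvr_sequence <- doms$hvr
    caax <- if (nchar(doms$hvr) >= 4) classify_caax(doms$hvr, doms$hvr_start)
            else structure(list(valid = FALSE, cys_position = NA_integer_,
                                a1 = NA, a2 = NA, x = NA,
                                prenyl_type = NA_character_, peptide = NA_character_),
                           class = "caax_call")
    prof$caax <- caax
    prof$palmitoyl_cys <- find_palmitoyl_cys(doms$hvr, doms$hvr_start, caax)
    prof$hits <- withCallingHandlers(
      detect_motifs(doms$hvr, doms$hvr_start, caax, prof$palmitoyl_cys),
      warning = function(w) {
        prof$notes <<- c(prof$notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    prof$phospho_acceptor <- detect_phospho_acceptor(doms$hvr, doms$hvr_start, caax)
    prof$hvr_net_charge <- net_charge(doms$hvr)
    prof$valid <- isTRUE(caax$valid)
    prof
  }, error = function(e) {
    prof$valid <- FALSE
    prof$notes <- c(prof$notes, conditionMessage(e))
    prof$hits <- tibble(kind = character(), start = integer(), end = integer(),
                        peptide = character(), net_charge = integer())
    prof$caax <- NULL
    prof$palmitoyl_cys <- integer(0)
    prof$phospho_acceptor <- NA_integer_
    prof$hvr_net_charge <- NA_integer_
    prof
  })
  res$archetype <- classify_archetype(res)
  structure(res, class = "hvr_profile")
}

has_hit <- function(profile, kind) {
  !is.null(profile$hits) && kind %in% profile$hits$kind
}

#' Classify an HVR profile into an isoform archetype
#'
#' Decision table over the annotated motifs, applied in order:
#' 1. PBD and NB and phospho-acceptor with no palmitoyl cysteine:
#'    farnesylated → `KRAS4B-like`; geranylgeranylated → `KRASBL-like` when
#'    the clade label is `"vertebrate"`, else `invertebrate-like`.
#' 2. PBR1 with two palmitoyl cysteines → `HRAS-like`.
#' 3. PBR1, one palmitoyl cysteine and PBR2 → `KRAS4A-like`.
#' 4. PBR1, one palmitoyl cysteine, no PBR2 → `NRAS-like`.
#' 5. Anything else → `unclassified`.
#'
#' @param profile An `hvr_profile` (or a bare list with the same fields).
#' @return A single archetype label.
#' @export
classify_archetype <- function(profile) {
  if (!isTRUE(profile$valid) || is.null(profile$caax) || !isTRUE(profile$caax$valid)) {
    return("unclassified")
  }
  n_palm <- length(profile$palmitoyl_cys)
  phospho <- !is.na(profile$phospho_acceptor)
  gg <- identical(profile$caax$prenyl_type, "geranylgeranyl")
  vertebrate <- identical(profile$clade, "vertebrate")

  if (has_hit(profile, "PBD") && has_hit(profile, "NB") && phospho && n_palm == 0) {
    if (!gg) return("KRAS4B-like")
    return(if (vertebrate) "KRASBL-like" else "invertebrate-like")
  }
  if (has_hit(profile, "PBR1") && n_palm == 2) return("HRAS-like")
  if (has_hit(profile, "PBR1") && n_palm == 1) {
    return(if (has_hit(profile, "PBR2")) "KRAS4A-like" else "NRAS-like")
  }
  "unclassified"
}

#' @export
print.hvr_profile <- function(x, ...) {
  cat(sprintf("<hvr_profile: %s>\n", x$record_id))
  if (!isTRUE(x$valid)) cat("  invalid:", paste(x$notes, collapse = "; "), "\n")
  if (!is.null(x$hvr_sequence)) {
    cat(sprintf("  HVR %d.. : %s\n", x$hvr_start, x$hvr_sequence))
  }
  if (!is.null(x$caax) && isTRUE(x$caax$valid)) {
    cat(sprintf("  CaaX %s at C%d (%s)\n", x$caax$peptide,
                x$caax$cys_position, x$caax$prenyl_type))
  }
  if (!is.null(x$hits) && nrow(x$hits) > 0) {
    for (i in seq_len(nrow(x$hits))) {
      cat(sprintf("  %-4s %d-%d %s (%+d)\n", x$hits$kind[i], x$hits$start[i],
                  x$hits$end[i], x$hits$peptide[i], x$hits$net_charge[i]))
    }
  }
  cat(sprintf("  archetype: %s\n", x$archetype))
  invisible(x)
}

#' Annotate a batch of sequences with the HVR motif grammar
#'
#' Runs [profile_hvr()] over every record and renders the per-sequence motif
#' table (one row per sequence, mirroring a motif-architecture figure).
#'
#' @param records Tibble from [read_protein_fasta()] (columns `id`,
#'   `residues`, optionally `species`, `clade`).
#' @param reference Optional reference sequence for anchored splitting of
#'   records longer than the default G-domain.
#' @return A tibble with columns `record_id`, `species`, `clade`, `archetype`,
#'   `caax_peptide`, `prenyl_type`, `pbr1`, `pbr2`, `nb`, `pbd`, `pbd_charge`,
#'   `palmitoyl_positions`, `phospho_position`, `hvr_charge`, `valid`.
#' @export
annotate_hvr <- function(records, reference = NULL) {
  profiles <- purrr::map(seq_len(nrow(records)), function(i) {
    profile_hvr(records[i, ], reference = reference)
  })
  purrr::map_dfr(profiles, glance_profile_row)
}

glance_profile_row <- function(p) {
  pick <- function(kind, field = "peptide") {
    if (has_hit(p, kind)) p$hits[[field]][p$hits$kind == kind] else
      if (field == "net_charge") NA_integer_ else NA_character_
  }
  tibble(
    record_id = p$record_id,
    species = p$species %||% NA_character_,
    clade = p$clade %||% NA_character_,
    archetype = p$archetype,
    caax_peptide = if (!is.null(p$caax) && isTRUE(p$caax$valid)) p$caax$peptide else NA_character_,
    prenyl_type = if (!is.null(p$caax)) p$caax$prenyl_type else NA_character_,
    pbr1 = pick("PBR1"), pbr2 = pick("PBR2"),
    nb = pick("NB"), pbd = pick("PBD"),
    pbd_charge = pick("PBD", "net_charge"),
    palmitoyl_positions = paste(p$palmitoyl_cys, collapse = ","),
    phospho_position = p$phospho_acceptor %||% NA_integer_,
    hvr_charge = p$hvr_net_charge %||% NA_integer_,
    valid = isTRUE(p$valid)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method generics::tidy
tidy.hvr_profile <- function(x, ...) {
  hits <- x$hits
  if (is.null(hits)) {
    hits <- tibble(kind = character(), start = integer(), end = integer(),
                   peptide = character(), net_charge = integer())
  }
  extra <- list()
  if (!is.null(x$caax) && isTRUE(x$caax$valid)) {
    extra$caax <- tibble(kind = "CaaX", start = x$caax$cys_position,
                         end = x$caax$cys_position + 3L,
                         peptide = x$caax$peptide,
                         net_charge = net_charge(x$caax$peptide))
  }
  if (length(x$palmitoyl_cys) > 0) {
    extra$palm <- tibble(kind = "palmitoyl-C", start = x$palmitoyl_cys,
                         end = x$palmitoyl_cys, peptide = "C", net_charge = 0L)
  }
  if (!is.null(x$phospho_acceptor) && !is.na(x$phospho_acceptor)) {
    p <- x$phospho_acceptor - x$hvr_start + 1L
    extra$phos <- tibble(kind = "phospho-acceptor", start = x$phospho_acceptor,
                         end = x$phospho_acceptor,
                         peptide = substr(x$hvr_sequence, p, p), net_charge = 0L)
  }
  out <- bind_rows(c(list(hits), extra))
  mutate(out, record_id = x$record_id, .before = 1) |> arrange(.data$start)
}

#' @exportS3Method generics::glance
glance.hvr_profile <- function(x, ...) {
  glance_profile_row(x)
}
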