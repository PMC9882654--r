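## Pairwise global alignment and percent identity.
##
## The aligner is an affine-gap Needleman-Wunsch (Gotoh) with BLAST-style
## scoring defaults (BLOSUM62, gap existence 11, extension 1; a gap of
## length k costs 11 + k) so that percent identities match the "align two
## sequences" convention used for the reference identity ranges.

sub_matrix_env <- new.env(parent = emptyenv())

#' Fetch a bundled substitution matrix
#'
#' @param name Matrix name (one of the matrices shipped with Biostrings,
#'   e.g. `"BLOSUM62"`, `"BLOSUM45"`, `"BLOSUM80"`, `"PAM250"`).
#' @return A numeric substitution matrix with residue row/column names.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  if (!is.null(sub_matrix_env[[name]])) return(sub_matrix_env[[name]])
  ok <- tryCatch({
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    sub_matrix_env[[name]] <- get(name, envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok) abort(sprintf("unknown substitution matrix '%s'", name))
  sub_matrix_env[[name]]
}

chars_to_idx <- function(chars, alphabet) {
  idx <- match(chars, alphabet)
  if (anyNA(idx[chars != "-"])) {
    bad <- chars[chars != "-" & is.na(idx)][1]
    abort(sprintf("residue '%s' not in substitution matrix alphabet", bad))
  }
  idx[is.na(idx)] <- 0L
  as.integer(idx - 1L)  # 0-based; gaps become -1
}

#' Global pairwise protein alignment with affine gaps
#'
#' @param a,b Protein sequences (character scalars, non-empty).
#' @param matrix_name Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Positive gap penalties (defaults 11 and 1; a
#'   gap of length k costs `gap_open + k * gap_extend`).
#' @return An object of class `pairwise_alignment`: gapped rows `row_a` and
#'   `row_b`, `score`, `identities` and `columns`.
#' @examples
#' pw <- global_align("ACDE", "ACE")
#' percent_identity(pw)
#' @export
global_align <- function(a, b, matrix_name = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  if (!is.character(a) || !is.character(b) || nchar(a) == 0 || nchar(b) == 0) {
    abort("both sequences must be non-empty strings")
  }
  if (gap_open <= 0 || gap_extend <= 0) abort("gap penalties must be positive")
  S <- substitution_matrix(matrix_name)
  alphabet <- rownames(S)
  ca <- split1(toupper(a)); cb <- split1(toupper(b))
  A <- matrix(chars_to_idx(ca, alphabet), nrow = 1)
  B <- matrix(chars_to_idx(cb, alphabet), nrow = 1)
  res <- align_profiles_cpp(A, B, S, gap_open, gap_extend)
  ga <- ifelse(res$a_cols == 0, "-", ca[pmax(res$a_cols, 1)])
  gb <- ifelse(res$b_cols == 0, "-", cb[pmax(res$b_cols, 1)])
  structure(list(
    row_a = paste(ga, collapse = ""),
    row_b = paste(gb, collapse = ""),
    score = res$score,
    identities = sum(ga == gb & ga != "-"),
    columns = length(ga)
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment: score %.1f, identities %d/%d (%.1f%%)>\n",
              x$score, x$identities, x$columns, percent_identity(x)))
  cat(" ", x$row_a, "\n ", x$row_b, "\n")
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' By default the denominator is the total number of alignment columns,
#' gapped columns included (the BLAST `Identities = n/m` convention);
#' `denominator = "ungapped"` restricts it to gap-free columns.
#'
#' @param pw A [global_align()] result.
#' @param denominator `"columns"` (default) or `"ungapped"`.
#' @return Percentage, rounded to one decimal.
#' @export
percent_identity <- function(pw, denominator = c("columns", "ungapped")) {
  denominator <- match.arg(denominator)
  if (pw$columns == 0) abort("alignment has zero columns")
  denom <- if (denominator == "columns") pw$columns else {
    a <- split1(pw$row_a); b <- split1(pw$row_b)
    sum(a != "-" & b != "-")
  }
  if (denom == 0) abort("alignment has zero comparable columns")
  round(100 * pw$identities / denom, 1)
}

#' Percent-identity matrix against reference sequences
#'
#' Globally aligns every record against every reference and tabulates percent
#' identities — the machine-readable form of a per-clade identity heat map.
#'
#' @param records,references Tibbles with `id` and `residues` columns.
#' @param ... Passed to [global_align()].
#' @param denominator Passed to [percent_identity()].
#' @return A long tibble of class `identity_tbl` with columns `record_id`,
#'   `reference_id`, `identity`.  Use [identity_wide()] for the records x
#'   references table, or [autoplot()] for a heat map.
#' @export
identity_matrix <- function(records, references, ...,
                            denominator = c("columns", "ungapped")) {
  denominator <- match.arg(denominator)
  if (nrow(records) == 0 || nrow(references) == 0) {
    abort("need at least one record and one reference")
  }
  grid <- tidyr::expand_grid(record_id = records$id, reference_id = references$id)
  grid$identity <- purrr::map2_dbl(grid$record_id, grid$reference_id, function(r, f) {
    tryCatch({
      pw <- global_align(records$residues[records$id == r],
                         references$residues[references$id == f], ...)
      percent_identity(pw, denominator = denominator)
    }, error = function(e) {
      warn(sprintf("alignment %s vs %s failed: %s", r, f, conditionMessage(e)))
      NA_real_
    })
  })
  class(grid) <- c("identity_tbl", class(grid))
  grid
}

#' Pivot an identity table to records x references form
#' @param identity_tbl Output of [identity_matrix()].
#' @return A wide tibble, one row per record, one column per reference.
#' @export
identity_wide <- function(identity_tbl) {
  tidyr::pivot_wider(as_tibble(identity_tbl), names_from = "reference_id",
                     values_from = "identity")
}

## ---- progressive multiple alignment ------------------------------------

profile_of <- function(id, residues) {
  list(ids = id, mat = matrix(split1(residues), nrow = 1))
}

merge_profiles <- function(pa, pb, S, gap_open, gap_extend) {
  alphabet <- rownames(S)
  A <- matrix(chars_to_idx(as.vector(t(pa$mat)), alphabet),
              nrow = nrow(pa$mat), byrow = TRUE)
  B <- matrix(chars_to_idx(as.vector(t(pb$mat)), alphabet),
              nrow = nrow(pb$mat), byrow = TRUE)
  res <- align_profiles_cpp(A, B, S, gap_open, gap_extend)
  k <- length(res$a_cols)
  expand <- function(mat, cols) {
    out <- matrix("-", nrow = nrow(mat), ncol = k)
    keep <- cols != 0
    out[, keep] <- mat[, cols[keep], drop = FALSE]
    out
  }
  list(ids = c(pa$ids, pb$ids),
       mat = rbind(expand(pa$mat, res$a_cols), expand(pb$mat, res$b_cols)))
}

#' Progressive multiple sequence alignment
#'
#' A minimal deterministic progressive aligner for near-identical protein
#' families: guide order from single-linkage clustering of pairwise
#' p-distances, then profile-to-profile affine-gap alignment under the same
#' scoring as [global_align()].  For divergent sets supply an external
#' alignment instead.
#'
#' @inheritParams global_align
#' @param records Tibble with `id` and `residues` (>= 2 rows).
#' @return An [aligned_set()].
#' @export
progressive_msa <- function(records, matrix_name = "BLOSUM62",
                            gap_open = 11, gap_extend = 1) {
  n <- nrow(records)
  if (is.null(n) || n < 2) abort("progressive MSA needs at least 2 records")
  S <- substitution_matrix(matrix_name)

  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pw <- global_align(records$residues[i], records$residues[j],
                         matrix_name, gap_open, gap_extend)
      D[i, j] <- D[j, i] <- 1 - pw$identities / pw$columns
    }
  }
  profiles <- purrr::map(seq_len(n), function(i) {
    profile_of(records$id[i], records$residues[i])
  })
  if (n == 2) {
    merged <- merge_profiles(profiles[[1]], profiles[[2]], S, gap_open, gap_extend)
  } else {
    hc <- hclust(as.dist(D), method = "single")
    nodes <- vector("list", n - 1)
    for (k in seq_len(n - 1)) {
      grab <- function(idx) if (idx < 0) profiles[[-idx]] else nodes[[idx]]
      nodes[[k]] <- merge_profiles(grab(hc$merge[k, 1]), grab(hc$merge[k, 2]),
                                   S, gap_open, gap_extend)
    }
    merged <- nodes[[n - 1]]
  }
  rows <- apply(merged$mat, 1, paste, collapse = "")
  names(rows) <- merged$ids
  aligned_set(rows[records$id])
}

#' @exportS3Method generics::glance
glance.pairwise_alignment <- function(x, ...) {
  tibble(score = x$score, identities = x$identities, columns = x$columns,
         percent_identity = percent_identity(x))
}

#' @exportS3Method generics::tidy
tidy.pairwise_alignment <- function(x, ...) {
  a <- split1(x$row_a); b <- split1(x$row_b)
  tibble(column = seq_along(a), a = a, b = b,
         match = a == b & a != "-")
}
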