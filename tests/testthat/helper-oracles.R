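# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive results with different code paths (plain-R
# dynamic programming, column-by-column scans) rather than calling into the
# functions they check.

AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) {
  paste(sample(AA_STANDARD, n, replace = TRUE), collapse = "")
}

# Plain-R Gotoh affine-gap global alignment score (no traceback), with the
# same scoring convention as the package: a gap of length k costs
# open + k * ext.
oracle_align_score <- function(a, b, S, open = 11, ext = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e30
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- S[ca[i], cb[j]]
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext,
                             X[i + 1, j] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Column-by-column conservation check over a character vector of gapped rows.
oracle_conserved_columns <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, ""))
  vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    !any(col == "-") && !any(col == "X") && length(unique(col)) == 1
  }, logical(1))
}

# Expand conserved_blocks() runs back into a per-column logical mask.
runs_to_mask <- function(runs, n_col) {
  mask <- rep(FALSE, n_col)
  for (i in seq_len(nrow(runs))) {
    mask[(runs$start_column[i] + 1):(runs$end_column[i] + 1)] <- TRUE
  }
  mask
}

# Random bifurcating tree with branch lengths; used for additive-matrix
# recovery checks.
random_tree <- function(n_leaves, min_bl = 0.05, max_bl = 0.5) {
  tr <- ape::rtree(n_leaves, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_bl, max_bl)
  tr
}

records_of <- function(sim) sim$records

sim_alignment <- function(sim) {
  aligned_set(stats::setNames(sim$records$residues, sim$records$id))
}
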