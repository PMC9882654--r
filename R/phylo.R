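## Distance-based protein phylogenies.
##
## Trees are reconstructed with BioNJ (variance-weighted neighbor joining)
## on pairwise distances computed over pairwise gap-free
## alignment columns, with the Kimura protein correction as the default
## stand-in for maximum-likelihood distances on near-identical sequences.
## Bootstrap support resamples alignment columns with replacement.

#' Drop gappy alignment columns
#'
#' A simplified alignment-curation step: removes columns whose gap fraction
#' exceeds `max_gap_fraction`, preserving row order.
#'
#' @param aln An [aligned_set()].
#' @param max_gap_fraction Columns with a strictly greater gap fraction are
#'   dropped (default 0.2).
#' @return A curated [aligned_set()].
#' @export
curate_alignment <- function(aln, max_gap_fraction = 0.2) {
  mat <- aln$mat
  gap_frac <- colMeans(mat == "-")
  keep <- gap_frac <= max_gap_fraction
  if (!any(keep)) abort("curation removed every column")
  mat <- mat[, keep, drop = FALSE]
  aligned_set(apply(mat, 1, paste, collapse = ""))
}

#' Pairwise protein distances from an alignment
#'
#' For every pair of rows, the mismatch fraction `p` is computed over the
#' columns where neither row has a gap, then corrected:
#' * `"p"` — uncorrected p-distance;
#' * `"poisson"` — `-ln(1 - p)`;
#' * `"kimura"` — `-ln(1 - p - 0.2 p^2)` (default).
#'
#' Saturated pairs (correction argument <= 0) are set to `ceiling` and
#' flagged.
#'
#' @param aln An [aligned_set()] with >= 2 rows.
#' @param model Distance model.
#' @param ceiling Distance assigned to saturated pairs (default 10).
#' @return An object of class `protein_dist`: `matrix` (square, symmetric,
#'   zero diagonal), `n_sites` (pairwise comparable columns), `saturated`
#'   (logical matrix), `model`.
#' @export
protein_distance <- function(aln, model = c("kimura", "poisson", "p"),
                             ceiling = 10) {
  model <- match.arg(model)
  mat <- aln$mat
  dist_from_matrix(mat, model, ceiling)
}

dist_from_matrix <- function(mat, model, ceiling = 10) {
  n <- nrow(mat)
  if (n < 2) abort("distance computation needs at least 2 rows")
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  ns <- matrix(0L, n, n, dimnames = dimnames(d))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(d))
  gap <- mat == "-"
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      usable <- !gap[i, ] & !gap[j, ]
      m <- sum(usable)
      if (m == 0) {
        abort(sprintf("rows '%s' and '%s' share no gap-free columns",
                      rownames(mat)[i], rownames(mat)[j]))
      }
      p <- sum(mat[i, usable] != mat[j, usable]) / m
      val <- switch(model,
        p = p,
        poisson = if (p < 1) -log(1 - p) else NA_real_,
        kimura = {
          arg <- 1 - p - 0.2 * p^2
          if (arg > 0) -log(arg) else NA_real_
        }
      )
      if (is.na(val)) {
        val <- ceiling
        sat[i, j] <- sat[j, i] <- TRUE
      }
      d[i, j] <- d[j, i] <- val
      ns[i, j] <- ns[j, i] <- m
    }
  }
  structure(list(matrix = d, n_sites = ns, saturated = sat, model = model),
            class = "protein_dist")
}

#' @export
print.protein_dist <- function(x, ...) {
  cat(sprintf("<protein_dist: %d taxa, model %s%s>\n", nrow(x$matrix), x$model,
              if (any(x$saturated)) sprintf(", %d saturated pair(s)",
                                            sum(x$saturated) / 2) else ""))
  print(round(x$matrix, 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.protein_dist <- function(x, ...) {
  labs <- rownames(x$matrix)
  idx <- which(upper.tri(x$matrix), arr.ind = TRUE)
  tibble(item1 = labs[idx[, 1]], item2 = labs[idx[, 2]],
         distance = x$matrix[idx], n_sites = x$n_sites[idx],
         saturated = x$saturated[idx])
}

#' @exportS3Method generics::glance
glance.protein_dist <- function(x, ...) {
  off <- x$matrix[upper.tri(x$matrix)]
  tibble(model = x$model, n_taxa = nrow(x$matrix),
         min_distance = min(off), max_distance = max(off),
         n_saturated = sum(x$saturated) / 2)
}

as_dist_matrix <- function(d) {
  if (inherits(d, "protein_dist")) return(d$matrix)
  if (inherits(d, "dist")) return(as.matrix(d))
  if (is.matrix(d)) return(d)
  abort("expected a protein_dist, dist, or matrix")
}

#' BioNJ tree from a distance matrix
#'
#' Variance-weighted neighbor joining: agglomeration uses the standard NJ
#' Q-criterion, branch lengths the NJ split formula, and the matrix
#' reduction the BioNJ variance-weighted lambda, so that on additive
#' matrices the generating tree is recovered exactly (topology and branch
#' lengths).  Ties in the Q-criterion are broken by the lowest label-index
#' pair; negative branch lengths are clamped to zero with a warning; two
#' taxa yield a single edge split evenly.
#'
#' @param d A [protein_distance()] result, `dist` object, or square
#'   symmetric matrix with labels.
#' @return An unrooted `ape::phylo` tree.
#' @export
bionj_tree <- function(d) {
  m <- as_dist_matrix(d)
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  if (!isTRUE(all.equal(m, t(m))) || any(!is.finite(m))) {
    abort("distance matrix must be symmetric and finite")
  }
  n <- nrow(m)
  if (n < 2) abort("need at least 2 taxa")

  clamped <- 0L
  bl <- function(x) {
    if (x < 0) clamped <<- clamped + 1L
    sprintf("%.12g", max(0, x))
  }
  labs <- rownames(m)
  # build the newick with placeholder tip labels, then restore the real
  # labels on the parsed tree (keeps arbitrary label content safe)
  subtxt <- paste0("L", seq_len(n))
  restore <- function(phy) {
    phy$tip.label <- labs[as.integer(sub("^L", "", phy$tip.label))]
    phy
  }
  D <- m
  V <- m       # BioNJ variance estimates start at the distances

  if (n == 2) {
    txt <- sprintf("(%s:%s,%s:%s);", subtxt[1], bl(D[1, 2] / 2),
                   subtxt[2], bl(D[1, 2] / 2))
    return(restore(ape::read.tree(text = txt)))
  }

  while (nrow(D) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    # lowest label-index pair among the minima
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]

    b_i <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    b_j <- D[i, j] - b_i

    # variance-weighted reduction (BioNJ lambda)
    k <- setdiff(seq_len(r), c(i, j))
    lambda <- if (V[i, j] > 0 && r > 3) {
      0.5 + sum(V[j, k] - V[i, k]) / (2 * (r - 2) * V[i, j])
    } else 0.5
    lambda <- min(1, max(0, lambda))

    new_d <- lambda * (D[i, k] - b_i) + (1 - lambda) * (D[j, k] - b_j)
    new_v <- lambda * V[i, k] + (1 - lambda) * V[j, k] -
      lambda * (1 - lambda) * V[i, j]
    new_sub <- sprintf("(%s:%s,%s:%s)", subtxt[i], bl(b_i), subtxt[j], bl(b_j))

    keep <- k
    D <- rbind(cbind(D[keep, keep, drop = FALSE], new_d),
               c(new_d, 0))
    V <- rbind(cbind(V[keep, keep, drop = FALSE], new_v),
               c(new_v, 0))
    subtxt <- c(subtxt[keep], new_sub)
  }

  # final three clusters join at a central node with closed-form lengths
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", subtxt[1], bl(b1), subtxt[2], bl(b2),
                 subtxt[3], bl(b3))
  if (clamped > 0) {
    warn(sprintf("clamped %d negative branch length(s) to 0", clamped))
  }
  restore(ape::read.tree(text = txt))
}

#' BioNJ tree with bootstrap support
#'
#' Builds the full-data BioNJ tree, then resamples alignment columns with
#' replacement `replicates` times, recomputes distances and trees, and
#' annotates each internal edge of the full tree with the percentage of
#' replicates containing the same bipartition.  A fixed seed makes the
#' supports bit-identical across runs.
#'
#' @inheritParams protein_distance
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the column resampling.
#' @return An `ape::phylo` with `node.label` holding supports in `[0, 100]`
#'   (root label empty).
#' @export
bootstrap_support <- function(aln, model = c("kimura", "poisson", "p"),
                              replicates = 100L, seed = 1L, ceiling = 10) {
  model <- match.arg(model)
  if (replicates < 1) abort("replicates must be >= 1")
  mat <- aln$mat
  build <- function(x) bionj_tree(dist_from_matrix(x, model, ceiling))
  phy <- build(mat)
  set.seed(as.integer(seed))
  counts <- suppressWarnings(
    ape::boot.phylo(phy, mat, build, B = replicates, quiet = TRUE,
                    rooted = FALSE)
  )
  support <- round(100 * counts / replicates)
  support[1] <- NA  # root of the unrooted representation carries no split
  phy$node.label <- ifelse(is.na(support), "", as.character(support))
  phy
}

#' Write a tree as Newick text
#'
#' Branch lengths are printed with 6 significant digits; internal node
#' labels (bootstrap supports) are preserved; labels containing Newick
#' metacharacters or spaces are single-quoted.  `read_newick()` of the
#' output reproduces the topology, lengths and supports.
#'
#' @param tree An `ape::phylo`.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  quote_label <- function(x) {
    bad <- grepl("[][(),:;'\" \t]", x)
    x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
    x
  }
  n_tip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  node_lab <- tree$node.label
  fmt_node <- function(node) {
    if (node <= n_tip) return(quote_label(tree$tip.label[node]))
    parts <- vapply(kids[[as.character(node)]], function(e) {
      child <- tree$edge[e, 2]
      len <- if (!is.null(tree$edge.length))
        sprintf(":%.6g", tree$edge.length[e]) else ""
      paste0(fmt_node(child), len)
    }, character(1))
    lab <- if (!is.null(node_lab)) {
      l <- node_lab[node - n_tip]
      if (is.na(l)) "" else quote_label(l)
    } else ""
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  root <- n_tip + 1L
  txt <- paste0(fmt_node(root), ";")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a Newick tree
#' @param source Path to a Newick file, or Newick text.
#' @return An `ape::phylo`.
#' @export
read_newick <- function(source) {
  if (grepl("\\(", source)) ape::read.tree(text = source)
  else ape::read.tree(source)
}

#' Bipartitions (splits) of an unrooted tree
#'
#' Each internal edge is reported as the sorted tip set on one side, encoded
#' as a `|`-separated string of the lexicographically smaller side; used to
#' compare topologies.
#'
#' @param tree An `ape::phylo`.
#' @return Character vector of canonical split encodings.
#' @export
tree_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  all_tips <- sort(labs)
  enc <- vapply(parts, function(idx) {
    side <- sort(labs[idx])
    other <- setdiff(all_tips, side)
    if (length(side) < 2 || length(other) < 2) return(NA_character_)
    a <- paste(side, collapse = "|")
    b <- paste(other, collapse = "|")
    if (a < b) a else b
  }, character(1))
  unique(enc[!is.na(enc)])
}
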