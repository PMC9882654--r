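## ggplot2 views of the main result types.

#' Heat map of a percent-identity table
#'
#' @param object An `identity_tbl` from [identity_matrix()].
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.identity_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$reference_id,
                                       y = .data$record_id,
                                       fill = .data$identity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$identity)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), name = "% identity") +
    ggplot2::labs(x = "reference", y = "record") +
    ggplot2::theme_minimal()
}

#' Heat map of a pairwise distance matrix
#' @param object A [protein_distance()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.protein_dist <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$item1, y = .data$item2,
                                     fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = paste0(object$model, " distance")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Motif-architecture map of annotated HVRs
#'
#' One horizontal track per sequence, with boxes for PBR1/PBR2/NB/PBD/CaaX
#' and point marks for palmitoylatable cysteines and the phospho-acceptor —
#' the package's rendering of a per-sequence motif table.
#'
#' @param records Record tibble (see [read_protein_fasta()]).
#' @param reference Optional reference for anchored domain splitting.
#' @return A ggplot.
#' @export
plot_hvr_architecture <- function(records, reference = NULL) {
  feats <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    tidy(profile_hvr(records[i, ], reference = reference))
  })
  boxes <- filter(feats, .data$kind %in% c("PBR1", "PBR2", "NB", "PBD", "CaaX"))
  marks <- filter(feats, .data$kind %in% c("palmitoyl-C", "phospho-acceptor"))
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = boxes,
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5,
                   ymin = as.numeric(factor(.data$record_id)) - 0.35,
                   ymax = as.numeric(factor(.data$record_id)) + 0.35,
                   fill = .data$kind), alpha = 0.8) +
    ggplot2::geom_point(
      data = marks,
      ggplot2::aes(x = .data$start, y = as.numeric(factor(.data$record_id)),
                   shape = .data$kind), size = 3) +
    ggplot2::scale_y_continuous(
      breaks = seq_along(unique(feats$record_id)),
      labels = sort(unique(feats$record_id))) +
    ggplot2::labs(x = "protein position", y = NULL, fill = "motif",
                  shape = "site") +
    ggplot2::theme_minimal()
}

#' Intron-homology map
#'
#' Plots each gene's introns at their alignment column, coloured by phase
#' and labelled with their homology-group letter.
#'
#' @param homology Output of [intron_homology()].
#' @return A ggplot.
#' @export
plot_intron_map <- function(homology) {
  ggplot2::ggplot(homology,
                  ggplot2::aes(x = .data$column, y = .data$gene_id,
                               colour = factor(.data$phase))) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$group_label),
                       vjust = -1, show.legend = FALSE) +
    ggplot2::labs(x = "alignment column", y = NULL, colour = "phase") +
    ggplot2::theme_minimal()
}
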