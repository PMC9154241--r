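# Interpretation plots: meta-element profiles and pairwise feature scatters.

#' Meta-gene profile of chromatin state features
#'
#' Averages each feature over every sub-bin of the gene evaluation layout
#' (5 upstream, 10 body, 5 downstream bins, 5' to 3') across all genes,
#' optionally normalized by each feature's genome-wide mean, and draws the
#' TSS-to-TTS enrichment profile per feature.
#'
#' @param annotation Feature annotation tibble.
#' @param genes Gene tibble (with `strand`).
#' @param normalize Divide each feature by its genome-wide mean.
#' @return A ggplot object; the underlying tibble is in `$data`.
#' @export
plot_meta_gene <- function(annotation, genes, normalize = TRUE) {
  eb <- element_bins(genes, "gene")
  X <- featurize_elements(annotation, eb)
  long <- tidyr::pivot_longer(X, -"id", names_to = c("bin", "feature"),
                              names_pattern = "bin(\\d+)_(.*)",
                              values_to = "value")
  long$bin <- as.integer(long$bin)
  prof <- dplyr::summarise(dplyr::group_by(long, .data$bin, .data$feature),
                           value = mean(.data$value), .groups = "drop")
  if (normalize) {
    feats <- unique(prof$feature)
    gm <- vapply(feats, function(f) mean(annotation[[f]]), 1)
    prof$value <- prof$value / gm[prof$feature]
  }
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$bin, y = .data$value,
                                     colour = .data$feature)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(5.5, 15.5), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_x_continuous(breaks = c(1, 5.5, 10.5, 15.5, 20),
                                labels = c("-5kb", "TSS", "body", "TTS",
                                           "+5kb")) +
    ggplot2::labs(x = "position relative to gene",
                  y = if (normalize) "feature / genome-wide mean" else
                    "mean feature value") +
    ggplot2::theme_minimal()
}

#' Pairwise feature scatterplot over elements
#'
#' Each point is an element (e.g. a gene, coloured by expressed/not, or an
#' enhancer vs promoter), placed by its mean value of two features over the
#' element body — the visualization that separates element classes in
#' feature space.
#'
#' @param annotation Feature annotation tibble.
#' @param elements Element tibble (`chrom`, `start`, `end`, `id`, plus an
#'   optional grouping column named by `colour`).
#' @param x,y Feature column names to plot.
#' @param colour Optional name of a column of `elements` to colour by.
#' @return A ggplot object.
#' @export
plot_feature_scatter <- function(annotation, elements, x, y, colour = NULL) {
  eb <- split_equal(tibble::as_tibble(elements), 1L, region = "body")
  X <- featurize_elements(annotation[, c("chrom", "start", "end", x, y)], eb)
  names(X) <- sub("^bin01_", "", names(X))
  if (!is.null(colour)) {
    X[[colour]] <- elements[[colour]][match(X$id, elements$id)]
  }
  p <- ggplot2::ggplot(X, ggplot2::aes(x = .data[[x]], y = .data[[y]]))
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                                 alpha = 0.7)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  p + ggplot2::theme_minimal()
}

#' ROC curves of every feature against an element type
#'
#' @param annotation Feature annotation tibble.
#' @param elements Element intervals (tibble or BED path).
#' @return A ggplot object with one ROC curve per feature.
#' @export
plot_feature_roc <- function(annotation, elements) {
  mask <- element_mask(annotation, elements)
  feats <- setdiff(names(annotation), c("chrom", "start", "end", "chain"))
  curves <- purrr::map_dfr(feats, function(f) {
    r <- element_roc(annotation[[f]], mask)
    dplyr::mutate(r$curve,
                  feature = sprintf("%s (auROC %.3f)", f, r$auc))
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       colour = .data$feature)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}
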