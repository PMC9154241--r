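# ROC analysis of individual chromatin state features against genomic
# elements: each feature is used in turn as a classification score for
# "bin overlaps the element type", sweeping the threshold.

#' ROC curve and auROC of a score against a binary mask
#'
#' Sweeps all unique score values as thresholds (score >= threshold =>
#' positive prediction), returns the operating points and the area under
#' the curve by the trapezoid rule — equivalently the Mann–Whitney
#' probability that a random positive outscores a random negative, with
#' tied scores counting one half.
#'
#' @param scores Numeric per-bin scores (one chromatin state feature).
#' @param labels 0/1 (or logical) per-bin element membership.
#' @return A list: `curve` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
#' @examples
#' element_roc(c(0.1, 0.4, 0.35, 0.8, 0.65, 0.9), c(0, 0, 1, 1, 0, 1))$auc
element_roc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    rlang::abort("Both classes must be present to compute a ROC curve.")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  cum_tp <- cumsum(l); cum_fp <- cumsum(1L - l)
  last <- length(s) - match(thr, rev(s)) + 1L   # last index per threshold
  curve <- tibble::tibble(
    threshold = c(Inf, thr),
    tpr = c(0, cum_tp[last] / n_pos),
    fpr = c(0, cum_fp[last] / n_neg))
  # Mann-Whitney with ties at 0.5 == trapezoid area under this curve
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(curve = curve, auc = auc)
}

#' Per-bin element membership mask
#'
#' A genome bin is positive for an element type when it overlaps any
#' element interval by at least one base pair.
#'
#' @param bins Bin tibble (annotation resolution).
#' @param elements Interval set (`chrom`, `start`, `end` tibble or BED
#'   path).
#' @return An integer 0/1 vector, one entry per bin.
#' @export
element_mask <- function(bins, elements) {
  check_bins(bins)
  ivl <- as_interval_tbl(elements, "elements")
  gr_el <- GenomicRanges::GRanges(ivl$chrom,
                                  IRanges::IRanges(ivl$start + 1L, ivl$end))
  as.integer(GenomicRanges::countOverlaps(bins_granges(bins), gr_el) > 0L)
}

#' ROC of every feature against an element type
#'
#' Computes the auROC of each feature column of an annotation against the
#' element mask and flags the best-performing feature — the per-model score
#' used when comparing models on TSS or enhancer identification.
#'
#' @param annotation Feature annotation tibble (bin columns + features).
#' @param elements Element intervals (tibble or BED path).
#' @return A tibble (`feature`, `auroc`, `best`), sorted by `auroc`
#'   descending.
#' @export
eval_elements <- function(annotation, elements) {
  mask <- element_mask(annotation, elements)
  feats <- setdiff(names(annotation), c("chrom", "start", "end", "chain"))
  out <- purrr::map_dfr(feats, function(f) {
    tibble::tibble(feature = f,
                   auroc = element_roc(annotation[[f]], mask)$auc)
  })
  out <- dplyr::arrange(out, dplyr::desc(.data$auroc))
  out$best <- seq_len(nrow(out)) == 1L
  out
}
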