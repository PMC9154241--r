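#' Bin genome-wide signal tracks over a set of bins
#'
#' Reads one bedGraph/bigWig track per assay and computes, for every bin,
#' the mean base-pair signal over that bin (fold-enrichment values in, mean
#' fold enrichment out). Bases not covered by a track are read as signal 0,
#' the usual convention for fold-enrichment tracks. Intervals on
#' chromosomes absent from `bins` are skipped with a warning. Bins whose
#' value is not finite (NaN stretches in a track) are masked out: the bin
#' rows are kept but flagged, and [transform_signal()] / [em_fit()] exclude
#' them from chains.
#'
#' @param bins A bin tibble from [make_bins()] or [subset_bins()].
#' @param tracks Character vector of file paths (bedGraph or bigWig),
#'   optionally named; names become track column names.
#' @param stat Per-bin aggregation statistic, `"mean"` (default) or `"max"`.
#'
#' @return A tibble with the bin columns plus one numeric column per track,
#'   rows aligned 1:1 with `bins`.
#' @export
load_signal <- function(bins, tracks, stat = c("mean", "max")) {
  check_bins(bins)
  stat <- match.arg(stat)
  if (length(tracks) == 0L) rlang::abort("At least one track is required.")
  names(tracks) <- track_labels(tracks)
  gr_bins <- bins_granges(bins)
  seqlens <- vapply(split(bins$end, bins$chrom), max, numeric(1))

  out <- bins
  for (nm in names(tracks)) {
    path <- tracks[[nm]]
    if (!file.exists(path)) {
      rlang::abort(sprintf("Track file not found: %s", path))
    }
    gr <- import_track(path)
    bad <- !(as.character(GenomicRanges::seqnames(gr)) %in% names(seqlens))
    if (any(bad)) {
      rlang::warn(sprintf(
        "Track '%s': skipping %d interval(s) on chromosomes absent from the bins.",
        nm, sum(bad)))
      gr <- gr[!bad]
    }
    out[[nm]] <- bin_track_values(gr, gr_bins, seqlens, stat)
  }
  out
}

track_labels <- function(tracks) {
  nms <- names(tracks)
  auto <- sub("\\.(bedgraph|bedGraph|bg|bw|bigwig|bigWig)$", "",
              basename(unname(tracks)))
  if (is.null(nms)) return(auto)
  ifelse(nms == "" | is.na(nms), auto, nms)
}

import_track <- function(path) {
  if (grepl("\\.(bw|bigwig|bigWig)$", path)) {
    rtracklayer::import(path, format = "BigWig")
  } else {
    rtracklayer::import(path, format = "bedGraph")
  }
}

bin_track_values <- function(gr, gr_bins, seqlens, stat) {
  GenomeInfoDb::seqlevels(gr) <- names(seqlens)
  GenomeInfoDb::seqlengths(gr) <- unname(seqlens)
  cov <- GenomicRanges::coverage(gr, weight = gr$score)
  chroms <- as.character(GenomicRanges::seqnames(gr_bins))
  vals <- numeric(length(gr_bins))
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    v <- IRanges::Views(cov[[ch]],
                        IRanges::ranges(gr_bins[idx]))
    vals[idx] <- if (stat == "mean") IRanges::viewMeans(v) else
      IRanges::viewMaxs(v)
  }
  vals
}

#' Variance-stabilizing arcsinh transform
#'
#' `asinh(x) = log(x + sqrt(x^2 + 1))`, applied elementwise to signal values
#' before modelling (and to RPKM/TPM response values in the evaluations).
#' It behaves like `log(2x)` for large `x`, is linear near 0, maps 0 to 0
#' and is strictly increasing, which tames large fold-enrichment outliers
#' without dropping zeros.
#'
#' @param x Numeric vector (or matrix) of finite values.
#' @return Transformed values, same shape as `x`.
#' @export
#' @examples
#' asinh_transform(c(0, 1, 10))
asinh_transform <- function(x) {
  log(x + sqrt(x^2 + 1))
}

#' Apply the arcsinh transform to all track columns of a signal tibble
#'
#' @param signal A tibble from [load_signal()].
#' @return The tibble with every track column transformed.
#' @export
transform_signal <- function(signal) {
  tracks <- signal_track_names(signal)
  dplyr::mutate(signal, dplyr::across(dplyr::all_of(tracks), asinh_transform))
}

signal_track_names <- function(signal) {
  setdiff(names(signal), c("chrom", "start", "end", "chain"))
}

#' Extract the bin-by-track numeric matrix from a signal tibble
#' @param signal A tibble from [load_signal()].
#' @return A G x E numeric matrix with track names as columns.
#' @export
signal_matrix <- function(signal) {
  tracks <- signal_track_names(signal)
  as.matrix(signal[, tracks, drop = FALSE])
}

#' Drop masked (non-finite) bins and re-chain
#'
#' Bins with any non-finite track value cannot enter the model (there is no
#' missing-data marginalization); they are removed and chains re-split at
#' the gaps, exactly like blacklisted bins.
#'
#' @param signal A signal tibble.
#' @return The signal tibble restricted to fully finite rows, chains
#'   recomputed.
#' @export
drop_masked_bins <- function(signal) {
  m <- signal_matrix(signal)
  ok <- apply(is.finite(m), 1L, all)
  out <- signal[ok, , drop = FALSE]
  out$chain <- recompute_chains(out)
  out
}

#' Write a feature annotation as one bedGraph track per feature
#'
#' @param bins Bin tibble aligned with the annotation rows.
#' @param features A data frame or matrix of feature values (one column per
#'   feature), or an annotation tibble from [annotate_features()] (its bin
#'   columns are ignored).
#' @param out_prefix Output path prefix; files are
#'   `<out_prefix><feature>.bedGraph`.
#' @param digits Decimal places written (round-trips within 1e-6 at the
#'   default 6).
#' @return Invisibly, the vector of file paths written.
#' @export
write_features <- function(bins, features, out_prefix, digits = 6) {
  check_bins(bins)
  if (is.data.frame(features)) {
    keep <- setdiff(names(features), c("chrom", "start", "end", "chain"))
    features <- as.matrix(features[, keep, drop = FALSE])
  }
  features <- as.matrix(features)
  if (nrow(features) == 0L || ncol(features) == 0L) {
    rlang::abort("`features` is empty: nothing to write.")
  }
  if (nrow(features) != nrow(bins)) {
    rlang::abort("`features` must have exactly one row per bin.")
  }
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("F", seq_len(ncol(features)))
  }
  fmt <- paste0("%s\t%d\t%d\t%.", digits, "f")
  paths <- character(ncol(features))
  for (k in seq_len(ncol(features))) {
    paths[k] <- paste0(out_prefix, colnames(features)[k], ".bedGraph")
    lines <- sprintf(fmt, bins$chrom, bins$start, bins$end, features[, k])
    writeLines(lines, paths[k])
  }
  invisible(paths)
}
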