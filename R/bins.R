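#' Tile a genome into fixed-width bins
#'
#' Divides every chromosome into consecutive bins of `bin_size` base pairs
#' (default 200 bp, the resolution at which all modelling is done). The last
#' bin of a chromosome may be shorter. Bins are grouped into *chains*:
#' maximal runs of adjacent bins that the state space model treats as one
#' sequence. Initially each chromosome is one chain; [subset_bins()] splits
#' chains wherever bins are removed.
#'
#' @param chrom_sizes Chromosome lengths: a named numeric vector
#'   (`c(chr1 = 1e6)`), a two-column data frame (`chrom`, `length`), or the
#'   path to a two-column `chrom.sizes` file.
#' @param bin_size Bin width in base pairs.
#'
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open)
#'   and `chain` (integer chain id), sorted by (`chrom`, `start`).
#' @export
#' @examples
#' make_bins(c(chr1 = 1000, chr2 = 400), bin_size = 200)
make_bins <- function(chrom_sizes, bin_size = 200) {
  sizes <- as_chrom_sizes(chrom_sizes)
  if (nrow(sizes) == 0L) {
    rlang::abort("`chrom_sizes` is empty: at least one chromosome is required.")
  }
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0) {
    rlang::abort("`bin_size` must be a single positive number of base pairs.")
  }
  if (any(sizes$length <= 0)) {
    rlang::abort("All chromosome lengths must be positive.")
  }
  bin_size <- as.integer(bin_size)
  bins <- purrr::pmap_dfr(sizes, function(chrom, length) {
    starts <- seq.int(0L, length - 1L, by = bin_size)
    tibble::tibble(
      chrom = chrom,
      start = starts,
      end = pmin(starts + bin_size, as.integer(length))
    )
  })
  bins$chain <- as.integer(factor(bins$chrom, levels = unique(bins$chrom)))
  bins
}

as_chrom_sizes <- function(chrom_sizes) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L &&
      file.exists(chrom_sizes)) {
    tab <- utils::read.table(chrom_sizes, header = FALSE,
                             col.names = c("chrom", "length"),
                             colClasses = c("character", "numeric"))
    return(tibble::as_tibble(tab))
  }
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    return(tibble::tibble(chrom = names(chrom_sizes),
                          length = unname(chrom_sizes)))
  }
  if (is.data.frame(chrom_sizes)) {
    stopifnot(all(c("chrom", "length") %in% names(chrom_sizes)))
    return(tibble::as_tibble(chrom_sizes[, c("chrom", "length")]))
  }
  rlang::abort("`chrom_sizes` must be a named vector, data frame or file path.")
}

#' Restrict bins to training regions and remove blacklisted intervals
#'
#' A bin is retained when its midpoint falls inside `keep` (when supplied)
#' and outside `drop`. This is how training is concentrated on a subset of
#' the genome (ENCODE Pilot-style regions) and how blacklist regions are
#' excised. Chain ids are recomputed so that every maximal run of surviving
#' adjacent bins forms one chain; the model restarts its recursion at each
#' chain boundary.
#'
#' @param bins A bin tibble from [make_bins()].
#' @param keep,drop Interval sets: a data frame with columns
#'   `chrom`, `start`, `end` (0-based half-open), or a BED file path, or
#'   `NULL` to skip the filter.
#'
#' @return The retained bins with recomputed `chain` ids.
#' @export
subset_bins <- function(bins, keep = NULL, drop = NULL) {
  check_bins(bins)
  mid <- (bins$start + bins$end) / 2
  retained <- rep(TRUE, nrow(bins))
  if (!is.null(keep)) {
    keep <- as_interval_tbl(keep, "keep")
    retained <- retained & point_in_intervals(bins$chrom, mid, keep)
  }
  if (!is.null(drop)) {
    drop <- as_interval_tbl(drop, "drop")
    retained <- retained & !point_in_intervals(bins$chrom, mid, drop)
  }
  out <- bins[retained, , drop = FALSE]
  out$chain <- recompute_chains(out)
  out
}

recompute_chains <- function(bins) {
  if (nrow(bins) == 0L) return(integer(0))
  new_chain <- c(TRUE, bins$chrom[-1] != bins$chrom[-nrow(bins)] |
                   bins$start[-1] != bins$end[-nrow(bins)])
  cumsum(new_chain)
}

as_interval_tbl <- function(x, what) {
  if (is.character(x) && length(x) == 1L) {
    gr <- rtracklayer::import(x, format = "BED")
    x <- tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1L,
                        end = GenomicRanges::end(gr))
  }
  x <- tibble::as_tibble(x)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (any(x$start >= x$end)) {
    rlang::abort(sprintf(
      "Malformed `%s` interval: start must be < end (0-based half-open).", what))
  }
  x
}

# membership of a midpoint in [start, end] (closed, so a midpoint sitting on
# an interval boundary counts as inside); coordinates doubled so half-integer
# midpoints of odd-length terminal bins stay integral
point_in_intervals <- function(chrom, pos, intervals) {
  pts <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(as.integer(2 * pos) + 1L,
                                                 width = 1L))
  ivl <- GenomicRanges::GRanges(intervals$chrom,
                                IRanges::IRanges(2L * intervals$start + 1L,
                                                 2L * intervals$end + 1L))
  GenomicRanges::countOverlaps(pts, ivl) > 0L
}

check_bins <- function(bins) {
  stopifnot(is.data.frame(bins),
            all(c("chrom", "start", "end", "chain") %in% names(bins)))
  invisible(bins)
}

bins_granges <- function(bins) {
  GenomicRanges::GRanges(bins$chrom,
                         IRanges::IRanges(bins$start + 1L, bins$end))
}
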