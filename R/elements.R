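#' Read a gene table (BED6-like TSV)
#'
#' Columns: `chrom`, `start`, `end`, `id`, `expression`, `strand`
#' (0-based half-open coordinates; `expression` in RPKM-like units, raw —
#' the evaluations arcsinh-transform it). The TSS is `start` for `+` genes
#' and `end` for `-` genes.
#'
#' @param path TSV file path (header required).
#' @return A tibble of gene records.
#' @export
read_genes <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         start = readr::col_integer(),
                         end = readr::col_integer(),
                         id = readr::col_character(),
                         expression = readr::col_double(),
                         strand = readr::col_character()))
  stopifnot(all(g$start < g$end), all(g$strand %in% c("+", "-")))
  g
}

#' Read an enhancer table (BED5-like TSV)
#'
#' Columns: `chrom`, `start`, `end`, `id`, `activity` (TPM-like, raw).
#'
#' @param path TSV file path (header required).
#' @return A tibble of enhancer records.
#' @export
read_enhancers <- function(path) {
  e <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         start = readr::col_integer(),
                         end = readr::col_integer(),
                         id = readr::col_character(),
                         activity = readr::col_double()))
  stopifnot(all(e$start < e$end))
  e
}

#' Split elements into the evaluation sub-bin layout
#'
#' Gene scheme: the 5 kb upstream of the TSS, the gene body (TSS to TTS) and
#' the 5 kb downstream of the TTS are split into 5, 10 and 5 equal bins
#' respectively — 20 sub-intervals per gene, strand-oriented so bin 1 is the
#' 5'-most upstream bin for both strands. Enhancer scheme: 10 equal bins
#' over the element. Elements whose body is shorter than the body bin count
#' are skipped with a warning.
#'
#' @param elements A gene tibble (`chrom`, `start`, `end`, `id`, `strand`)
#'   or enhancer tibble (`chrom`, `start`, `end`, `id`).
#' @param scheme `"gene"` or `"enhancer"`.
#' @param flank Flanking distance in bp on each side (gene scheme).
#' @param n_body,n_flank Sub-bin counts for body and each flank.
#' @return A tibble (`id`, `bin`, `region`, `chrom`, `start`, `end`) with
#'   `bin` running 1..20 (gene) or 1..10 (enhancer) in 5' to 3' order.
#' @export
element_bins <- function(elements, scheme = c("gene", "enhancer"),
                         flank = 5000, n_body = 10L, n_flank = 5L) {
  scheme <- match.arg(scheme)
  elements <- tibble::as_tibble(elements)
  if (scheme == "enhancer") {
    return(split_equal(elements, n_body, region = "body"))
  }
  too_short <- (elements$end - elements$start) < n_body
  if (any(too_short)) {
    rlang::warn(sprintf("Skipping %d gene(s) shorter than %d bp.",
                        sum(too_short), n_body))
    elements <- elements[!too_short, , drop = FALSE]
  }
  purrr::pmap_dfr(
    elements[, c("chrom", "start", "end", "id", "strand")],
    function(chrom, start, end, id, strand) {
      body <- edges_to_bins(chrom, id, start, end, n_body, "body")
      up <- edges_to_bins(chrom, id, start - flank, start, n_flank, "upstream")
      down <- edges_to_bins(chrom, id, end, end + flank, n_flank, "downstream")
      out <- if (strand == "+") {
        dplyr::bind_rows(up, body, down)
      } else {
        # minus strand: 5' end is `end`; reverse so bin 1 is 5'-most
        dplyr::bind_rows(down[rev(seq_len(n_flank)), ],
                         body[rev(seq_len(n_body)), ],
                         up[rev(seq_len(n_flank)), ])
      }
      out$bin <- seq_len(nrow(out))
      out$region <- rep(c("upstream", "body", "downstream"),
                        c(n_flank, n_body, n_flank))
      out
    })
}

edges_to_bins <- function(chrom, id, from, to, n, region) {
  edges <- pmax(round(seq(from, to, length.out = n + 1L)), 0)
  tibble::tibble(id = id, chrom = chrom,
                 start = as.integer(edges[-(n + 1L)]),
                 end = as.integer(edges[-1L]),
                 region = region)
}

split_equal <- function(elements, n, region) {
  purrr::pmap_dfr(elements[, c("chrom", "start", "end", "id")],
                  function(chrom, start, end, id) {
                    b <- edges_to_bins(chrom, id, start, end, n, region)
                    b$bin <- seq_len(n)
                    b
                  })
}

#' Average annotation values over element sub-bins
#'
#' Builds the regression design: for every element, the base-pair-weighted
#' mean of each feature over each sub-bin, concatenated bin-major (all
#' features of bin 1, then bin 2, ...). For a discrete annotation (a
#' `label` column instead of numeric features) labels are one-hot encoded
#' first, so each slot is the fraction of the sub-bin carrying that label.
#' A gene scheme with K = 3 continuous features yields a 60-slot vector
#' (20 bins x 3). Elements with no annotated overlap at all are skipped.
#'
#' @param annotation A tibble with `chrom`, `start`, `end` plus numeric
#'   feature columns (continuous) or a `label` column (discrete).
#' @param bins_tbl Sub-bins from [element_bins()].
#' @return A wide tibble: `id`, then `bin<bb>_<feature>` columns.
#' @export
featurize_elements <- function(annotation, bins_tbl) {
  ann <- tibble::as_tibble(annotation)
  if ("label" %in% names(ann)) {
    labels <- sort(unique(ann$label))
    for (l in labels) ann[[paste0("L", l)]] <- as.numeric(ann$label == l)
    ann$label <- NULL
  }
  feat_cols <- setdiff(names(ann), c("chrom", "start", "end", "chain"))
  fm <- as.matrix(ann[, feat_cols, drop = FALSE])

  gr_ann <- GenomicRanges::GRanges(ann$chrom,
                                   IRanges::IRanges(ann$start + 1L, ann$end))
  gr_sub <- GenomicRanges::GRanges(bins_tbl$chrom,
                                   IRanges::IRanges(bins_tbl$start + 1L,
                                                    bins_tbl$end))
  ov <- GenomicRanges::findOverlaps(gr_sub, gr_ann)
  w <- IRanges::width(IRanges::pintersect(gr_sub[S4Vectors::queryHits(ov)],
                                          gr_ann[S4Vectors::subjectHits(ov)]))
  q <- S4Vectors::queryHits(ov)
  wsum <- tapply(w, q, sum)
  means <- matrix(NA_real_, nrow(bins_tbl), length(feat_cols),
                  dimnames = list(NULL, feat_cols))
  for (j in seq_along(feat_cols)) {
    sj <- tapply(w * fm[S4Vectors::subjectHits(ov), j], q, sum)
    means[as.integer(names(sj)), j] <- sj / wsum
  }
  long <- dplyr::bind_cols(bins_tbl[, c("id", "bin")],
                           tibble::as_tibble(means))
  n_bins <- max(bins_tbl$bin)
  wide <- tidyr::pivot_wider(
    long, id_cols = "id", names_from = "bin",
    values_from = dplyr::all_of(feat_cols),
    names_glue = paste0("bin{sprintf('%02d', as.integer(bin))}_{.value}"))
  # bin-major column order: bin01_F1, bin01_F2, ..., bin02_F1, ...
  ord <- as.vector(t(outer(sprintf("bin%02d", seq_len(n_bins)), feat_cols,
                           paste, sep = "_")))
  wide <- wide[, c("id", ord), drop = FALSE]
  complete <- stats::complete.cases(wide[, ord, drop = FALSE])
  n_all_missing <- sum(!complete & !apply(
    is.finite(as.matrix(wide[, ord])), 1L, any))
  if (any(!complete)) {
    rlang::warn(sprintf(
      "Skipping %d element(s) with unannotated sub-bins (%d with no overlap at all).",
      sum(!complete), n_all_missing))
  }
  wide[complete, , drop = FALSE]
}
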