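#' Build a toy annotated genome on disk
#'
#' Writes a small synthetic genome whose signal tracks are generated from a
#' planted latent architecture, so every evaluation protocol can run with
#' no downloads. Three latent activity types drive six tracks (two per
#' type, mimicking paired histone-mark assays) through a fixed
#' track-response matrix: *transcription* (elevated over gene bodies,
#' proportional to a per-gene activity), *promoter* (peaked over the 400 bp
#' upstream of each TSS with flanking decay, strength independent of
#' expression) and *regulatory* (peaked at both promoters and enhancers).
#' Peak shapes decay geometrically into flanking bins and a lognormal
#' per-bin jitter emulates the bin-to-bin fluctuation of real ChIP
#' enrichment; response gains put element peaks at realistic fold
#' enrichments (~5-40). Gene expression is a linear function of the gene's
#' latent activity plus Gaussian noise on the arcsinh scale (files store
#' the raw RPKM-like value); enhancer activity likewise. Tracks are written
#' in raw (pre-arcsinh) signal scale as one bedGraph per track, so a
#' pipeline reading them exercises the same transform as real
#' fold-enrichment data. Output is byte-identical for a fixed seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed RNG seed (required).
#' @param n_chrom,chrom_length Synthetic chromosome count and length (bp).
#' @param n_genes,gene_length Gene count and min/max length (bp).
#' @param n_enhancers,enhancer_length Enhancer count and min/max length.
#' @param signal_noise_sd,expression_noise_sd Gaussian noise scales for the
#'   track signal (raw scale) and the element responses (arcsinh scale).
#' @param bin_size Resolution at which tracks are generated and written.
#' @return Invisibly, a list with the file `paths`, the `genes`,
#'   `enhancers` and `promoters` tibbles and the track names.
#' @export
make_toy_genome <- function(dir, seed, n_chrom = 5L, chrom_length = 1000000L,
                            n_genes = 100L, gene_length = c(4000L, 12000L),
                            n_enhancers = 80L,
                            enhancer_length = c(600L, 1200L),
                            signal_noise_sd = 0.3,
                            expression_noise_sd = 0.2, bin_size = 200L) {
  withr::local_seed(as.integer(seed))
  dir.create(file.path(dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
  chroms <- paste0("chr", seq_len(n_chrom))
  sizes <- stats::setNames(rep(as.integer(chrom_length), n_chrom), chroms)

  margin <- 6000L                      # keep eval flanks inside the chromosome
  occupied <- replicate(n_chrom, cbind(numeric(0), numeric(0)),
                        simplify = FALSE)
  names(occupied) <- chroms

  place <- function(len, pad) {
    for (try in 1:300) {
      ch <- sample(chroms, 1L)
      start <- sample.int(chrom_length - len - 2L * margin, 1L) + margin
      start <- as.integer(round(start / bin_size) * bin_size)
      occ <- occupied[[ch]]
      lo <- start - pad; hi <- start + len + pad
      if (nrow(occ) == 0L || all(hi <= occ[, 1L] | lo >= occ[, 2L])) {
        occupied[[ch]] <<- rbind(occ, c(lo, hi))
        return(list(chrom = ch, start = start, end = start + len))
      }
    }
    rlang::abort("Could not place all elements; reduce counts or lengthen chromosomes.")
  }

  genes <- purrr::map_dfr(seq_len(n_genes), function(i) {
    len <- as.integer(round(stats::runif(1, gene_length[1], gene_length[2]) /
                              bin_size) * bin_size)
    pos <- place(len, pad = 5400L)     # keep flank bins element-free
    tibble::tibble(chrom = pos$chrom, start = pos$start, end = pos$end,
                   id = sprintf("gene%03d", i),
                   activity = stats::runif(1, 0.3, 2.5),
                   promoter_strength = stats::runif(1, 0.8, 1.6),
                   strand = sample(c("+", "-"), 1L))
  })
  genes$expression <- sinh(1.5 * genes$activity +
                             stats::rnorm(n_genes, 0, expression_noise_sd))

  enhancers <- purrr::map_dfr(seq_len(n_enhancers), function(i) {
    len <- as.integer(round(stats::runif(1, enhancer_length[1],
                                         enhancer_length[2]) /
                              bin_size) * bin_size)
    pos <- place(len, pad = 1400L)
    tibble::tibble(chrom = pos$chrom, start = pos$start, end = pos$end,
                   id = sprintf("enh%03d", i),
                   latent = stats::runif(1, 0.3, 2.5))
  })
  enhancers$activity <- sinh(1.5 * enhancers$latent +
                               stats::rnorm(n_enhancers, 0,
                                            expression_noise_sd))

  promoters <- tibble::tibble(
    chrom = genes$chrom,
    start = ifelse(genes$strand == "+", genes$start - 400L, genes$end),
    end = ifelse(genes$strand == "+", genes$start, genes$end + 400L),
    id = paste0(genes$id, "_prom"))

  # latent activity per bin; peaks decay geometrically into `flank_bins`
  # neighbouring bins (halving per bin), like real ChIP peak shoulders
  bins <- make_bins(sizes, bin_size)
  act <- matrix(0, nrow(bins), 3,
                dimnames = list(NULL, c("txn", "prom", "reg")))
  paint <- function(col, tbl, value, flank_bins = 0L) {
    for (r in seq_len(nrow(tbl))) {
      ids <- which(bins$chrom == tbl$chrom[r] &
                     bins$start < tbl$end[r] + flank_bins * bin_size &
                     bins$end > tbl$start[r] - flank_bins * bin_size)
      core <- bins$start[ids] < tbl$end[r] & bins$end[ids] > tbl$start[r]
      d <- numeric(length(ids))
      d[!core] <- pmin(abs(bins$start[ids][!core] - tbl$end[r]),
                       abs(tbl$start[r] - bins$end[ids][!core])) /
        bin_size + 1
      w <- ifelse(core, 1, 0.5^d)
      act[ids, col] <<- act[ids, col] +
        value[r] * w * exp(stats::rnorm(length(ids), 0, 0.3))
    }
  }
  paint("txn", genes, genes$activity)
  paint("prom", promoters, genes$promoter_strength, flank_bins = 3L)
  paint("reg", promoters, genes$promoter_strength, flank_bins = 3L)
  paint("reg", enhancers, enhancers$latent, flank_bins = 3L)

  # two tracks per activity type, gains at realistic fold enrichments
  response <- rbind(body1 = c(12, 0,  0),
                    body2 = c(9,  0,  0),
                    prom1 = c(0,  20, 0),
                    prom2 = c(0,  15, 0),
                    reg1  = c(0,  0,  12),
                    reg2  = c(0,  0,  9))
  signal <- act %*% t(response) +
    matrix(stats::rnorm(nrow(bins) * nrow(response), 0, signal_noise_sd),
           nrow(bins))
  signal <- pmax(signal, 0)

  track_paths <- stats::setNames(
    file.path(dir, "tracks", paste0(rownames(response), ".bedGraph")),
    rownames(response))
  for (tr in rownames(response)) {
    writeLines(sprintf("%s\t%d\t%d\t%.6f", bins$chrom, bins$start, bins$end,
                       signal[, tr]), track_paths[[tr]])
  }
  paths <- list(
    chrom_sizes = file.path(dir, "chrom.sizes"),
    genes = file.path(dir, "genes.tsv"),
    enhancers = file.path(dir, "enhancers.tsv"),
    promoters = file.path(dir, "promoters.bed"),
    tracks = track_paths)
  writeLines(sprintf("%s\t%d", chroms, sizes), paths$chrom_sizes)
  readr::write_tsv(genes[, c("chrom", "start", "end", "id", "expression",
                             "strand")], paths$genes)
  readr::write_tsv(enhancers[, c("chrom", "start", "end", "id", "activity")],
                   paths$enhancers)
  writeLines(sprintf("%s\t%d\t%d\t%s", promoters$chrom, promoters$start,
                     promoters$end, promoters$id), paths$promoters)
  invisible(list(paths = paths, genes = genes, enhancers = enhancers,
                 promoters = promoters, tracks = rownames(response),
                 bins = bins))
}
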