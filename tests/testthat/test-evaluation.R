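# helpers building tiny annotated genomes in memory
toy_annotation <- function(n_bins = 500, K = 2, chrom = "chr1",
                           bin_size = 200) {
  bins <- make_bins(setNames(n_bins * bin_size, chrom), bin_size)
  feats <- matrix(0, n_bins, K, dimnames = list(NULL, paste0("F", 1:K)))
  dplyr::bind_cols(bins, tibble::as_tibble(feats))
}

test_that("gene sub-bins follow the 5+10+5 strand-oriented layout", {
  g <- tibble::tibble(chrom = "chr1", start = 10000L, end = 12000L,
                      id = "g1", strand = "+")
  eb <- element_bins(g, "gene")
  expect_equal(nrow(eb), 20L)
  expect_equal(eb$region, rep(c("upstream", "body", "downstream"),
                              c(5, 10, 5)))
  body <- eb[eb$region == "body", ]
  expect_true(all(body$end - body$start == 200L))
  up <- eb[eb$region == "upstream", ]
  expect_equal(up$start, seq(5000L, 9000L, 1000L))

  # minus strand: bin 1 is the 5'-most bin, i.e. upstream of the gene end
  gm <- dplyr::mutate(g, strand = "-")
  ebm <- element_bins(gm, "gene")
  expect_equal(ebm$start[1], 16000L)
  expect_equal(ebm$region[1], "upstream")
  expect_equal(ebm$start[20], 5000L)

  e <- tibble::tibble(chrom = "chr1", start = 1000L, end = 2000L, id = "e1")
  ebe <- element_bins(e, "enhancer")
  expect_equal(nrow(ebe), 10L)
  expect_true(all(ebe$end - ebe$start == 100L))

  expect_warning(element_bins(tibble::tibble(chrom = "chr1", start = 0L,
                                             end = 5L, id = "tiny",
                                             strand = "+"), "gene"),
                 "Skipping")
})

test_that("featurization averages per sub-bin, bin-major, one-hot for labels", {
  ann <- toy_annotation(300, K = 3)
  ann$F1 <- 1.5; ann$F2 <- 0.25; ann$F3 <- 2
  g <- tibble::tibble(chrom = "chr1", start = 20000L, end = 24000L,
                      id = "g1", strand = "+")
  X <- featurize_elements(ann, element_bins(g, "gene"))
  expect_equal(ncol(X) - 1L, 60L)           # 20 bins x 3 features
  expect_equal(names(X)[2:4], c("bin01_F1", "bin01_F2", "bin01_F3"))
  expect_true(all(abs(as.matrix(X[, grep("F1$", names(X))]) - 1.5) < 1e-12))

  # discrete annotation: fraction of each sub-bin under each label
  dann <- toy_annotation(300, K = 1)
  dann$F1 <- NULL
  dann$label <- rep(c("A", "B"), length.out = 300)
  e <- tibble::tibble(chrom = "chr1", start = 20000L, end = 22000L, id = "e")
  Xd <- featurize_elements(dann, element_bins(e, "enhancer"))
  expect_equal(ncol(Xd) - 1L, 20L)          # 10 bins x 2 labels
  expect_equal(as.numeric(Xd[1, c("bin01_LA", "bin01_LB")]), c(1, 0))
  expect_equal(as.numeric(Xd[1, c("bin02_LA", "bin02_LB")]), c(0, 1))
})

test_that("adjusted R-squared follows the printed formula", {
  expect_equal(adjusted_r2(0.5, 101, 10), 0.44444, tolerance = 1e-4)
  expect_equal(adjusted_r2(0.5, 101, 10), 1 - (1 - 0.5) * 100 / 90)
  expect_equal(adjusted_r2(0.73, 50, 0), 0.73)
  expect_equal(adjusted_r2(1, 40, 7), 1)
  expect_error(adjusted_r2(0.5, 11, 10), "n > p")
  # strictly decreasing in p for fixed r2 < 1
  vals <- sapply(0:5, function(p) adjusted_r2(0.8, 100, p))
  expect_true(all(diff(vals) < 0))
  # never exceeds the unadjusted value
  expect_true(all(vals <= 0.8))
})

planted_genome <- function(seed, n_genes = 60, noise = 0.1) {
  withr::local_seed(seed)
  n_bins <- 3000L
  ann <- toy_annotation(n_bins, K = 2)
  starts <- seq(40L, n_bins - 80L, length.out = n_genes)
  genes <- tibble::tibble(
    chrom = "chr1",
    start = as.integer(round(starts)) * 200L,
    end = (as.integer(round(starts)) + 20L) * 200L,
    id = sprintf("g%03d", seq_len(n_genes)),
    strand = "+",
    activity = runif(n_genes, 0.5, 3))
  for (i in seq_len(n_genes)) {
    rows <- which(ann$start >= genes$start[i] & ann$end <= genes$end[i])
    ann$F1[rows] <- genes$activity[i]
  }
  ann$F2 <- abs(rnorm(n_bins, 0, 0.5))
  genes$expression <- sinh(2 * genes$activity + rnorm(n_genes, 0, noise))
  list(ann = ann, genes = genes)
}

test_that("whole-gene regression: perfect fits, null responses, planted signal", {
  pg <- planted_genome(1)
  # planted: asinh(expression) = 2 * body F1 + small noise
  # planted F1 is constant across a gene's body bins, so most bin columns
  # are collinear and get dropped from p
  res <- suppressWarnings(eval_expression_whole_gene(pg$ann, pg$genes))
  expect_gte(res$adj_r2, 0.95)
  expect_lte(res$p, 20L)
  expect_equal(res$n, nrow(pg$genes))

  # perfectly linear response, no noise
  pg2 <- planted_genome(2, noise = 0)
  pg2$genes$expression <- sinh(1.3 * pg2$genes$activity)
  res2 <- suppressWarnings(eval_expression_whole_gene(pg2$ann, pg2$genes))
  expect_equal(res2$adj_r2, 1.0, tolerance = 1e-10)

  # response independent of features
  pg3 <- planted_genome(3)
  pg3$genes$expression <- abs(rnorm(nrow(pg3$genes), 0, 1))
  res3 <- suppressWarnings(eval_expression_whole_gene(pg3$ann, pg3$genes))
  expect_lt(abs(res3$adj_r2), 0.25)

  # single-average reading: one K-slot vector per gene
  res4 <- suppressWarnings(
    eval_expression_whole_gene(pg$ann, pg$genes, single_average = TRUE))
  expect_equal(res4$p, 2L)
  expect_gte(res4$adj_r2, 0.95)
})

test_that("region-specific profile localizes signal to the gene body", {
  pg <- planted_genome(4)
  prof <- suppressWarnings(eval_expression_profile(pg$ann, pg$genes))
  expect_equal(nrow(prof), 20L)
  expect_equal(prof$region, rep(c("upstream", "body", "downstream"),
                                c(5, 10, 5)))
  body_r2 <- prof$adj_r2[prof$region == "body"]
  flank_r2 <- prof$adj_r2[prof$region != "body"]
  expect_gt(min(body_r2), max(flank_r2))

  # identical annotation in all bins -> flat profile
  flat <- pg
  flat$ann$F1 <- 1; flat$ann$F2 <- 2
  flat$genes$expression <- abs(rnorm(nrow(flat$genes)))
  prof_flat <- suppressWarnings(eval_expression_profile(flat$ann, flat$genes))
  expect_lt(diff(range(prof_flat$adj_r2)), 1e-10)

  # translation invariance: shifting every coordinate leaves the profile alone
  sh <- 200L * 7L
  ann_s <- dplyr::mutate(pg$ann, start = start + sh, end = end + sh)
  genes_s <- dplyr::mutate(pg$genes, start = start + sh, end = end + sh)
  prof_s <- suppressWarnings(eval_expression_profile(ann_s, genes_s))
  expect_equal(prof_s$adj_r2, prof$adj_r2, tolerance = 1e-10)
})

test_that("enhancer regression mirrors the whole-gene protocol on 10 bins", {
  withr::local_seed(11)
  ann <- toy_annotation(2000, K = 2)
  n <- 80L
  starts <- as.integer(seq(10L, 1980L, length.out = n)) * 200L
  enh <- tibble::tibble(chrom = "chr1", start = starts,
                        end = starts + 1000L,
                        id = sprintf("e%03d", 1:n),
                        latent = runif(n, 0.5, 3))
  for (i in seq_len(n)) {
    rows <- which(ann$start >= enh$start[i] & ann$end <= enh$end[i])
    ann$F2[rows] <- enh$latent[i]
  }
  enh$activity <- sinh(1.5 * enh$latent + rnorm(n, 0, 0.1))
  res <- suppressWarnings(eval_enhancers(ann, enh))
  expect_gte(res$adj_r2, 0.9)
  expect_equal(res$n, n)

  enh_null <- dplyr::mutate(enh, activity = abs(rnorm(n)))
  expect_lt(abs(suppressWarnings(eval_enhancers(ann, enh_null))$adj_r2), 0.25)
})

test_that("discrete one-hot regression is invariant to label renumbering", {
  withr::local_seed(12)
  ann <- toy_annotation(2000, K = 1)
  ann$F1 <- NULL
  lab <- sample(1:3, 2000, replace = TRUE)
  genes <- tibble::tibble(
    chrom = "chr1", start = as.integer(seq(20, 1900, length.out = 40)) * 200L,
    id = sprintf("g%02d", 1:40), strand = "+")
  genes$end <- genes$start + 4000L
  genes$expression <- abs(rnorm(40) + 2)
  ann$label <- lab
  r1 <- suppressWarnings(eval_expression_whole_gene(ann, genes))
  # p = 10 bins x (L - 1) after dropping collinear one-hot columns, plus kept
  expect_equal(r1$n, 40L)
  ann2 <- ann
  ann2$label <- c(2L, 3L, 1L)[lab]            # renumber labels
  r2 <- suppressWarnings(eval_expression_whole_gene(ann2, genes))
  expect_equal(r2$r2, r1$r2, tolerance = 1e-10)
})
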