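# Annotation-quality evaluations: how well do the chromatin state features
# over an element predict that element's measured activity?

#' Adjusted coefficient of determination
#'
#' `1 - (1 - r2) * (n - 1) / (n - p - 1)`: the standard adjustment that
#' penalizes regressor complexity, so models with different feature counts
#' are comparable.
#'
#' @param r2 Unadjusted R-squared.
#' @param n Number of observations.
#' @param p Number of regression features (excluding the intercept).
#' @return The adjusted R-squared.
#' @export
#' @examples
#' adjusted_r2(0.5, 101, 10)
adjusted_r2 <- function(r2, n, p) {
  if (any(n <= p + 1)) {
    rlang::abort("adjusted_r2() requires n > p + 1.")
  }
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

# OLS of response on a design matrix; collinear columns are dropped (with a
# warning) and do not count toward p.
fit_eval_lm <- function(X, y) {
  df <- data.frame(y = y, X, check.names = TRUE)
  fit <- stats::lm(y ~ ., data = df)
  coefs <- stats::coef(fit)[-1L]
  if (anyNA(coefs)) {
    rlang::warn(sprintf("Dropped %d collinear design column(s).",
                        sum(is.na(coefs))))
  }
  p <- sum(!is.na(coefs))
  r2 <- summary(fit)$r.squared
  tibble::tibble(n = length(y), p = p, r2 = r2,
                 adj_r2 = adjusted_r2(r2, length(y), p))
}

#' Whole-gene expression evaluation
#'
#' Averages each feature over the 10 gene-body sub-bins, concatenates them
#' into one vector per gene (10K slots; or a single K-slot average with
#' `single_average = TRUE`), and regresses arcsinh-transformed RPKM on it
#' with ordinary least squares. Reports in-sample adjusted R-squared; the
#' adjustment controls for regressor complexity across models of different
#' K.
#'
#' @param annotation Feature annotation tibble ([annotate_features()]) or a
#'   discrete annotation with a `label` column.
#' @param genes Gene tibble ([read_genes()]): `chrom`, `start`, `end`, `id`,
#'   `expression`, `strand`.
#' @param single_average Collapse the body to one average vector per gene
#'   instead of 10 concatenated bins.
#' @param transform_response arcsinh-transform the expression values
#'   (default; set `FALSE` if already transformed).
#' @return A one-row tibble: `protocol`, `n`, `p`, `r2`, `adj_r2`.
#' @export
eval_expression_whole_gene <- function(annotation, genes,
                                       single_average = FALSE,
                                       transform_response = TRUE) {
  eb <- element_bins(genes, "gene")
  eb <- eb[eb$region == "body", , drop = FALSE]
  eb$bin <- eb$bin - min(eb$bin) + 1L
  X <- featurize_elements(annotation, eb)
  design <- as.matrix(X[, -1L, drop = FALSE])
  if (single_average) {
    feat <- sub("^bin\\d+_", "", colnames(design))
    design <- sapply(unique(feat), function(f) {
      rowMeans(design[, feat == f, drop = FALSE])
    })
  }
  y <- genes$expression[match(X$id, genes$id)]
  if (transform_response) y <- asinh_transform(y)
  out <- fit_eval_lm(design, y)
  dplyr::bind_cols(tibble::tibble(protocol = "whole_gene"), out)
}

#' Region-specific expression evaluation
#'
#' Fits one independent regression per sub-bin of the
#' `[TSS - 5 kb, TTS + 5 kb]` layout (5 upstream + 10 body + 5 downstream
#' bins), each using only that bin's K feature averages, and reports the 20
#' adjusted R-squared values in 5' to 3' order. The resulting profile shows
#' *where* relative to a gene the annotation is informative about
#' expression.
#'
#' @inheritParams eval_expression_whole_gene
#' @return A 20-row tibble: `bin`, `region`, `n`, `p`, `r2`, `adj_r2`.
#' @export
eval_expression_profile <- function(annotation, genes,
                                    transform_response = TRUE) {
  eb <- element_bins(genes, "gene")
  X <- featurize_elements(annotation, eb)
  y_all <- genes$expression[match(X$id, genes$id)]
  if (transform_response) y_all <- asinh_transform(y_all)
  region_of <- c(rep("upstream", 5), rep("body", 10), rep("downstream", 5))
  purrr::map_dfr(1:20, function(b) {
    cols <- grep(sprintf("^bin%02d_", b), names(X), value = TRUE)
    out <- fit_eval_lm(as.matrix(X[, cols, drop = FALSE]), y_all)
    dplyr::bind_cols(tibble::tibble(bin = b, region = region_of[b]), out)
  })
}

#' Enhancer activity evaluation
#'
#' Mirrors the whole-gene protocol on enhancers: each enhancer is split into
#' 10 equal sub-bins, per-bin feature averages are concatenated, and
#' arcsinh-transformed activity (TPM) is regressed on them.
#'
#' @param annotation Feature annotation tibble or discrete (`label`)
#'   annotation.
#' @param enhancers Enhancer tibble ([read_enhancers()]): `chrom`, `start`,
#'   `end`, `id`, `activity`.
#' @param transform_response arcsinh-transform the activity values.
#' @return A one-row tibble: `protocol`, `n`, `p`, `r2`, `adj_r2`.
#' @export
eval_enhancers <- function(annotation, enhancers, transform_response = TRUE) {
  eb <- element_bins(enhancers, "enhancer")
  X <- featurize_elements(annotation, eb)
  y <- enhancers$activity[match(X$id, enhancers$id)]
  if (transform_response) y <- asinh_transform(y)
  out <- fit_eval_lm(as.matrix(X[, -1L, drop = FALSE]), y)
  dplyr::bind_cols(tibble::tibble(protocol = "enhancer"), out)
}
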