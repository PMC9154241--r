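#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the emission matrix of a fitted model
#'
#' One row per (track, feature) entry of `Z`: how strongly each chromatin
#' state feature emits into each input track — the numbers behind the
#' emission heatmap.
#'
#' @param x An `epigenome_ssm` fit.
#' @param ... Unused.
#' @return A tibble (`track`, `feature`, `emission`).
#' @method tidy epigenome_ssm
#' @export
tidy.epigenome_ssm <- function(x, ...) {
  tibble::tibble(
    track = rep(rownames(x$Z), times = ncol(x$Z)),
    feature = rep(colnames(x$Z), each = nrow(x$Z)),
    emission = as.vector(x$Z))
}

#' One-row summary of a fitted model
#'
#' @param x An `epigenome_ssm` fit.
#' @param ... Unused.
#' @return A tibble with `K`, `E`, `variant`, `iterations`, `converged`,
#'   final `loglik` and `objective`, and `min_Z`.
#' @method glance epigenome_ssm
#' @export
glance.epigenome_ssm <- function(x, ...) {
  tibble::tibble(
    K = x$K, E = x$E, variant = x$variant,
    iterations = x$iterations, converged = x$converged,
    loglik = utils::tail(x$history$loglik, 1),
    objective = utils::tail(x$history$objective, 1),
    min_Z = min(x$Z))
}

#' Emission heatmap of a fitted model
#'
#' Tracks on the y axis, chromatin state features on the x axis, fill = the
#' emission weight: the panel used to read off what kind of activity each
#' feature represents.
#'
#' @param object An `epigenome_ssm` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot epigenome_ssm
#' @export
autoplot.epigenome_ssm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$track,
                                   fill = .data$emission)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "chromatin state feature", y = "input track",
                  fill = "emission") +
    ggplot2::theme_minimal()
}
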