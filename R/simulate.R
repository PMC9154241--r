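#' Simulate observations from the state space model
#'
#' Draws latent feature trajectories and observations from the generative
#' model itself — \eqn{\alpha_1 \sim N(0, I)},
#' \eqn{\alpha_{g+1} = T\alpha_g + v_g}, \eqn{y_g = Z\alpha_g + \epsilon_g}
#' — one independent chain per synthetic chromosome, returning the ground
#' truth so recovery tests can compare fitted parameters and features
#' against it. With `truncate = TRUE` the latent states are clamped at zero
#' after every step (a non-negative ground truth for the constrained
#' variants). Deterministic for a fixed seed.
#'
#' @param G Bins per chain.
#' @param K,E Latent feature and track counts.
#' @param Z True emission matrix (E x K); default Uniform(0, 1) draws.
#' @param T_mat True transition matrix (K x K); default `0.8 * I`. A
#'   spectral radius above 1 triggers a warning (non-stationary dynamics).
#' @param n_chains Number of independent chains (synthetic chromosomes).
#' @param seed RNG seed (required).
#' @param obs_noise_sd,state_noise_sd Noise scales (model convention is 1).
#' @param truncate Clamp simulated latent states at 0.
#' @param bin_size Bin width used for the synthetic coordinates.
#' @return A list: `signal` (tibble of bins + track columns), `truth`
#'   (tibble of bins + true latent features), `bins`, `Z`, `T`.
#' @export
simulate_ssm <- function(G, K, E, Z = NULL, T_mat = NULL, n_chains = 1L,
                         seed, obs_noise_sd = 1, state_noise_sd = 1,
                         truncate = FALSE, bin_size = 200L) {
  stopifnot(G >= 1, K >= 1, E >= 1)
  withr::local_seed(as.integer(seed))
  if (is.null(Z)) Z <- matrix(stats::runif(E * K), E, K)
  if (is.null(T_mat)) T_mat <- diag(K) * 0.8
  stopifnot(nrow(Z) == E, ncol(Z) == K, all(dim(T_mat) == K))
  if (max(Mod(eigen(T_mat, only.values = TRUE)$values)) > 1 + 1e-12) {
    rlang::warn("Spectral radius of T exceeds 1: simulated states will drift.")
  }
  bins <- make_bins(stats::setNames(rep(G * bin_size, n_chains),
                                    paste0("chr", seq_len(n_chains))),
                    bin_size = bin_size)
  alpha <- matrix(0, n_chains * G, K)
  Y <- matrix(0, n_chains * G, E)
  row <- 0L
  for (ch in seq_len(n_chains)) {
    a <- stats::rnorm(K)
    if (truncate) a <- pmax(a, 0)
    for (g in seq_len(G)) {
      row <- row + 1L
      alpha[row, ] <- a
      Y[row, ] <- drop(Z %*% a) + obs_noise_sd * stats::rnorm(E)
      a <- drop(T_mat %*% a) + state_noise_sd * stats::rnorm(K)
      if (truncate) a <- pmax(a, 0)
    }
  }
  colnames(Y) <- paste0("track", seq_len(E))
  colnames(alpha) <- paste0("F", seq_len(K))
  list(signal = dplyr::bind_cols(bins, tibble::as_tibble(Y)),
       truth = dplyr::bind_cols(bins, tibble::as_tibble(alpha)),
       bins = bins, Z = Z, T = T_mat)
}

#' Greedy matching of estimated to true emission columns
#'
#' Features are identified only up to permutation (and scale), so recovery
#' is scored by greedily pairing each estimated emission column with the
#' best-correlated remaining true column.
#'
#' @param Z_hat,Z_true Emission matrices with the same number of rows.
#' @return A tibble (`estimated`, `truth`, `correlation`), one row per
#'   matched column pair.
#' @export
match_emission_columns <- function(Z_hat, Z_true) {
  C <- suppressWarnings(stats::cor(Z_hat, Z_true))
  C[!is.finite(C)] <- -1
  out <- list()
  for (i in seq_len(min(ncol(Z_hat), ncol(Z_true)))) {
    best <- arrayInd(which.max(C), dim(C))
    out[[i]] <- tibble::tibble(estimated = best[1L], truth = best[2L],
                               correlation = C[best])
    C[best[1L], ] <- -Inf
    C[, best[2L]] <- -Inf
  }
  dplyr::bind_rows(out)
}
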