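variant_code <- function(variant) {
  switch(variant, unconstrained = 0L, nonneg = 1L, sumone = 2L,
         rlang::abort(sprintf("Unknown variant '%s'.", variant)))
}

#' Initialize state space model parameters
#'
#' The emission matrix `Z` (tracks x features) is drawn i.i.d. Uniform(0, 1)
#' and the transition matrix `T` starts at the identity, so features begin
#' as persistent, non-negatively emitting components. Initialization is
#' deterministic for a fixed seed.
#'
#' @param E Number of observed tracks.
#' @param K Number of chromatin state features.
#' @param seed Integer RNG seed.
#' @param lambda1,lambda2 Non-negative L2 (squared Frobenius) regularization
#'   weights on `Z` and `T`.
#' @param variant One of `"unconstrained"`, `"nonneg"` (non-negative `Z` and
#'   features), `"sumone"` (additionally caps each feature vector's sum at 1).
#' @return An object of class `ssm_params`: list with `Z`, `T`, `lambda1`,
#'   `lambda2`, `variant`, `K`, `E`.
#' @export
init_params <- function(E, K, seed = 1L, lambda1 = 0.01, lambda2 = 0.01,
                        variant = c("nonneg", "unconstrained", "sumone")) {
  variant <- match.arg(variant)
  stopifnot(E >= 1, K >= 1, lambda1 >= 0, lambda2 >= 0)
  if (K > E) {
    rlang::warn(sprintf(
      "K = %d features exceed E = %d tracks: the model is over-complete.",
      K, E))
  }
  Z <- withr::with_seed(as.integer(seed),
                        matrix(stats::runif(E * K), nrow = E, ncol = K))
  dimnames(Z) <- list(paste0("track", seq_len(E)), paste0("F", seq_len(K)))
  structure(
    list(Z = Z, T = diag(K), lambda1 = lambda1, lambda2 = lambda2,
         variant = variant, K = as.integer(K), E = as.integer(E),
         seed = as.integer(seed)),
    class = "ssm_params")
}

#' Forward Kalman filter over one chain
#'
#' Runs the standard predict/update recursion for the linear-Gaussian model
#' \eqn{y_g = Z\alpha_g + \epsilon_g}, \eqn{\alpha_{g+1} = T\alpha_g + v_g}
#' with unit noise covariances and prior \eqn{\alpha_1 \sim N(0, I)}. When
#' `project` is on (the default for constrained variants), each filtered
#' mean is replaced by its projection onto the variant's constraint set
#' before the next prediction. The returned log-likelihood always uses the
#' pre-projection innovations (a pseudo-likelihood under constrained
#' variants).
#'
#' @param chain A numeric G x E matrix of observations for one contiguous
#'   chain (rows = bins), or a signal tibble containing a single chain.
#' @param params An `ssm_params` object.
#' @param project Override the variant's projection (`TRUE`/`FALSE`).
#' @return A list of class `ssm_filter` with `mu_pred`, `mu_filt` (G x K),
#'   `P_pred`, `P_filt` (K x K x G), `loglik`, and the inputs.
#' @export
kalman_filter <- function(chain, params, project = NULL) {
  Y <- chain_matrix(chain, params)
  code <- filter_code(params, project)
  res <- ssm_kalman_cpp(Y, params$Z, params$T, code, FALSE, TRUE, TRUE)
  structure(
    list(mu_pred = res$mu_pred, mu_filt = res$mu_filt,
         P_pred = res$P_pred, P_filt = res$P_filt,
         loglik = res$loglik, Y = Y, project = code, params = params),
    class = "ssm_filter")
}

filter_code <- function(params, project) {
  if (is.null(project)) return(variant_code(params$variant))
  if (isTRUE(project)) {
    if (params$variant == "unconstrained") 1L else variant_code(params$variant)
  } else 0L
}

chain_matrix <- function(chain, params) {
  if (is.data.frame(chain)) chain <- signal_matrix(chain)
  Y <- as.matrix(chain)
  if (nrow(Y) == 0L) rlang::abort("Chain is empty.")
  if (!all(is.finite(Y))) {
    rlang::abort(paste0("Non-finite observations in chain: remove masked ",
                        "bins first (see drop_masked_bins())."))
  }
  if (ncol(Y) != nrow(params$Z)) {
    rlang::abort(sprintf(
      "Chain has %d tracks but the model emits %d.", ncol(Y), nrow(params$Z)))
  }
  Y
}

#' Rauch–Tung–Striebel smoother over one chain
#'
#' Backward message passing that conditions every state on the whole chain,
#' producing smoothed means, covariances and the exact lag-one
#' cross-covariances \eqn{Cov(\alpha_g, \alpha_{g-1} \mid Y)} needed by the
#' EM sufficient statistics. Under constrained variants the smoothed means
#' are re-projected onto the constraint set.
#'
#' @param filter_state An `ssm_filter` from [kalman_filter()].
#' @param params Parameters; defaults to those stored in `filter_state`.
#' @return A list of class `ssm_posterior` with `mu_smooth` (G x K,
#'   projected under constrained variants), `mu_smooth_raw`, `P_smooth`
#'   (K x K x G), `C_lag` (K x K x G; slice g holds
#'   \eqn{Cov(\alpha_g, \alpha_{g-1})}, slice 1 is zero), `loglik`.
#' @export
kalman_smooth <- function(filter_state, params = filter_state$params) {
  stopifnot(inherits(filter_state, "ssm_filter"))
  res <- ssm_kalman_cpp(filter_state$Y, params$Z, params$T,
                        filter_state$project, TRUE, TRUE, TRUE)
  structure(
    list(mu_smooth = res$mu_smooth, mu_smooth_raw = res$mu_smooth_raw,
         P_smooth = res$P_smooth, C_lag = res$C_lag,
         mu_filt = res$mu_filt, loglik = res$loglik, Y = filter_state$Y),
    class = "ssm_posterior")
}

#' Accumulate EM sufficient statistics from a smoothed posterior
#'
#' Collects the moment sums the M-step needs:
#' \eqn{\sum_g E[\alpha_g\alpha_g^\top]},
#' \eqn{\sum_{g\ge 2} E[\alpha_g\alpha_{g-1}^\top]} (and the matching
#' previous-position sum), \eqn{\sum_g y_g E[\alpha_g]^\top},
#' \eqn{\sum_g y_g y_g^\top} and the bin count. Second moments are
#' mean outer products plus posterior covariances (lag-one covariances for
#' the cross terms). Statistics from independent chains add.
#'
#' @param posterior An `ssm_posterior` from [kalman_smooth()].
#' @param observations Chain observations; default those stored alongside.
#' @param projected Use the projected smoothed means (default) or the raw
#'   Gaussian means in the moments.
#' @return A list of class `ssm_stats` with `S_aa`, `S_cross`, `S_prev`,
#'   `S_ya`, `S_yy`, `G`.
#' @export
accumulate_stats <- function(posterior, observations = posterior$Y,
                             projected = TRUE) {
  stopifnot(inherits(posterior, "ssm_posterior"))
  Y <- as.matrix(observations)
  mu <- if (projected) posterior$mu_smooth else posterior$mu_smooth_raw
  G <- nrow(mu)
  K <- ncol(mu)
  S_aa <- matrix(0, K, K); S_cross <- matrix(0, K, K)
  S_prev <- matrix(0, K, K)
  for (g in seq_len(G)) {
    S_aa <- S_aa + posterior$P_smooth[, , g] + tcrossprod(mu[g, ])
    if (g > 1L) {
      S_cross <- S_cross + posterior$C_lag[, , g] +
        tcrossprod(mu[g, ], mu[g - 1L, ])
      S_prev <- S_prev + posterior$P_smooth[, , g - 1L] +
        tcrossprod(mu[g - 1L, ])
    }
  }
  new_stats(S_aa, S_cross, S_prev, crossprod(Y, mu), crossprod(Y), G)
}

new_stats <- function(S_aa, S_cross, S_prev, S_ya, S_yy, G) {
  structure(list(S_aa = S_aa, S_cross = S_cross, S_prev = S_prev,
                 S_ya = S_ya, S_yy = S_yy, G = G),
            class = "ssm_stats")
}

#' @export
`+.ssm_stats` <- function(e1, e2) {
  new_stats(e1$S_aa + e2$S_aa, e1$S_cross + e2$S_cross,
            e1$S_prev + e2$S_prev, e1$S_ya + e2$S_ya,
            e1$S_yy + e2$S_yy, e1$G + e2$G)
}

#' Penalized model objective
#'
#' The quantity EM ascends: the marginal Gaussian log-likelihood of the data
#' under the current parameters minus the squared-Frobenius ridge penalties,
#' \eqn{\log P(Y \mid Z, T) - \lambda_1\|Z\|_F^2 - \lambda_2\|T\|_F^2}.
#' Larger is better. Under constrained variants the likelihood term is the
#' pre-projection pseudo-likelihood and monotone ascent is not guaranteed.
#'
#' @param params An `ssm_params` object.
#' @param data A signal tibble (chains taken from its `chain` column) or a
#'   single numeric chain matrix.
#' @return A scalar objective value.
#' @export
penalized_objective <- function(params, data) {
  ll <- sum(purrr::map_dbl(data_chains(data, params), function(Y) {
    ssm_kalman_cpp(Y, params$Z, params$T, variant_code(params$variant),
                   FALSE, TRUE, FALSE)$loglik
  }))
  ll - params$lambda1 * sum(params$Z^2) - params$lambda2 * sum(params$T^2)
}

data_chains <- function(data, params) {
  if (is.data.frame(data)) {
    m <- signal_matrix(data)
    unname(lapply(split(seq_len(nrow(m)), data$chain),
                  function(i) m[i, , drop = FALSE]))
  } else {
    list(chain_matrix(data, params))
  }
}
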