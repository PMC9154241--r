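#' Fit the chromatin state feature model by EM
#'
#' Alternates an E-step (Kalman filter + smoother + sufficient statistics
#' over every chain, chains contributing additively) with an M-step
#' ([update_Z()], [update_T()]). The emission matrix starts Uniform(0, 1),
#' the transition matrix at the identity. Iteration stops when the relative
#' change of the penalized objective drops below `tol` or at `max_iter`.
#' For the `nonneg`/`sumone` variants the filtered and smoothed means are
#' projected onto the constraint set and the emission update runs the
#' active-set solver, so the learned `Z` and all annotated features are
#' non-negative; the reported objective is then a pseudo-likelihood and is
#' not guaranteed monotone (it is for `unconstrained`).
#'
#' @param signal A signal tibble from [load_signal()] (arcsinh-transform it
#'   first with [transform_signal()]) with a `chain` column, or a plain
#'   numeric G x E matrix treated as a single chain.
#' @param K Number of chromatin state features (the paper-scale default in
#'   the command-line tool is 5; choose per dataset).
#' @param variant `"nonneg"` (default), `"unconstrained"` or `"sumone"`.
#' @param lambda1,lambda2 Squared-Frobenius penalties on `Z` and `T`.
#' @param seed Seed for the emission initialization.
#' @param max_iter,tol EM stopping rule: iteration cap and relative
#'   objective-change threshold.
#' @param projected_stats Use projected posterior means in the sufficient
#'   statistics (default) or the raw Gaussian means.
#' @return An object of class `epigenome_ssm`: the fitted parameters plus a
#'   per-iteration `history` tibble (`iter`, `loglik`, `objective`),
#'   convergence info and the final active-set multipliers. Methods:
#'   [tidy.epigenome_ssm()], [glance.epigenome_ssm()],
#'   [autoplot.epigenome_ssm()], `print`.
#' @export
em_fit <- function(signal, K, variant = c("nonneg", "unconstrained", "sumone"),
                   lambda1 = 0.01, lambda2 = 0.01, seed = 1L,
                   max_iter = 100L, tol = 1e-6, projected_stats = TRUE) {
  variant <- match.arg(variant)
  chains <- em_chains(signal)
  E <- ncol(chains[[1L]])
  if (!any(vapply(chains, nrow, 1L) >= 2L)) {
    rlang::abort("At least one chain of length >= 2 is needed to estimate T.")
  }
  params <- init_params(E, K, seed = seed, lambda1 = lambda1,
                        lambda2 = lambda2, variant = variant)
  track_names <- em_track_names(signal, E)
  dimnames(params$Z) <- list(track_names, paste0("F", seq_len(K)))
  code <- variant_code(variant)

  history <- vector("list", max_iter)
  multipliers <- matrix(0, E, K)
  prev_obj <- -Inf
  iter_done <- 0L
  for (iter in seq_len(max_iter)) {
    passes <- lapply(chains, function(Y) {
      ssm_kalman_cpp(Y, params$Z, params$T, code, TRUE, projected_stats, FALSE)
    })
    loglik <- sum(vapply(passes, `[[`, 0, "loglik"))
    objective <- loglik - lambda1 * sum(params$Z^2) - lambda2 * sum(params$T^2)
    if (!is.finite(objective)) {
      rlang::abort(sprintf(
        "Non-finite objective at EM iteration %d; the model diverged.", iter))
    }
    history[[iter]] <- tibble::tibble(iter = iter, loglik = loglik,
                                      objective = objective)
    iter_done <- iter
    stats <- Reduce(`+`, lapply(passes, function(p) {
      new_stats(p$S_aa, p$S_cross, p$S_prev, p$S_ya, p$S_yy, p$G)
    }))
    Znew <- update_Z(stats, lambda1, variant)
    multipliers <- attr(Znew, "multipliers")
    attr(Znew, "multipliers") <- NULL
    dimnames(Znew) <- dimnames(params$Z)
    params$Z <- Znew
    params$T <- update_T(stats, lambda2)
    if (is.finite(prev_obj) &&
        abs(objective - prev_obj) < tol * (abs(prev_obj) + tol)) break
    prev_obj <- objective
  }
  history <- dplyr::bind_rows(history[seq_len(iter_done)])
  structure(
    list(Z = params$Z, T = params$T, lambda1 = lambda1, lambda2 = lambda2,
         variant = variant, K = as.integer(K), E = as.integer(E),
         tracks = track_names, seed = as.integer(seed),
         projected_stats = projected_stats,
         history = history, iterations = iter_done,
         converged = iter_done < max_iter,
         multipliers = multipliers),
    class = c("epigenome_ssm", "ssm_params"))
}

em_chains <- function(signal) {
  if (is.data.frame(signal)) {
    m <- signal_matrix(signal)
    if (!all(is.finite(m))) {
      rlang::abort(paste0("Signal contains non-finite values; run ",
                          "drop_masked_bins() first."))
    }
    unname(lapply(split(seq_len(nrow(m)), signal$chain),
                  function(i) m[i, , drop = FALSE]))
  } else {
    m <- as.matrix(signal)
    if (!all(is.finite(m))) rlang::abort("Signal matrix has non-finite values.")
    list(m)
  }
}

em_track_names <- function(signal, E) {
  if (is.data.frame(signal)) signal_track_names(signal)
  else if (!is.null(colnames(signal))) colnames(signal)
  else paste0("track", seq_len(E))
}

#' Annotate bins with chromatin state features
#'
#' Runs the filter and smoother of a fitted model over every chain of a
#' (transformed) signal tibble and returns the smoothed posterior mean of
#' the latent feature vector at every bin — the continuous chromatin state
#' feature annotation. Constrained variants project the features onto their
#' constraint set, so `nonneg` features are all `>= 0`. This is the same
#' code path as the EM E-step.
#'
#' @param signal A signal tibble (same tracks, same transform as training).
#' @param fit A fitted `epigenome_ssm` (or any `ssm_params`).
#' @param smoother Use the smoother (default) or, if `FALSE`, the filtered
#'   means only (causal, uses no downstream evidence).
#' @return A tibble of the bin columns plus one feature column `F1..FK`.
#' @export
annotate_features <- function(signal, fit, smoother = TRUE) {
  stopifnot(is.data.frame(signal))
  tracks <- signal_track_names(signal)
  if (length(tracks) != fit$E) {
    rlang::abort(sprintf(
      "Signal has %d tracks but the model was trained on %d.",
      length(tracks), fit$E))
  }
  m <- signal_matrix(signal)
  if (!all(is.finite(m))) {
    rlang::abort("Signal contains non-finite values; run drop_masked_bins().")
  }
  code <- variant_code(fit$variant)
  idx <- split(seq_len(nrow(m)), signal$chain)
  feats <- matrix(NA_real_, nrow(m), fit$K)
  for (i in idx) {
    res <- ssm_kalman_cpp(m[i, , drop = FALSE], fit$Z, fit$T, code,
                          smoother, TRUE, FALSE)
    feats[i, ] <- if (smoother) res$mu_smooth else {
      full <- ssm_kalman_cpp(m[i, , drop = FALSE], fit$Z, fit$T, code,
                             FALSE, TRUE, TRUE)
      full$mu_filt
    }
  }
  colnames(feats) <- paste0("F", seq_len(fit$K))
  dplyr::bind_cols(signal[, intersect(c("chrom", "start", "end", "chain"),
                                      names(signal)), drop = FALSE],
                   tibble::as_tibble(feats))
}

#' @export
print.epigenome_ssm <- function(x, ...) {
  cat(sprintf("<epigenome_ssm> %s variant, K = %d features, E = %d tracks\n",
              x$variant, x$K, x$E))
  cat(sprintf("  EM: %d iteration(s), %s; final objective %.4f\n",
              x$iterations, if (x$converged) "converged" else "iteration cap",
              utils::tail(x$history$objective, 1)))
  cat("  Emission matrix Z (tracks x features):\n")
  print(round(x$Z, 3))
  invisible(x)
}

#' Save a fitted model as structured JSON
#'
#' Serializes the emission and transition matrices, penalties, variant,
#' dimensions, track names, seed and the EM objective history into a single
#' JSON file that [read_ssm_model()] restores exactly.
#'
#' @param fit An `epigenome_ssm` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_ssm_model <- function(fit, path) {
  payload <- list(
    format = "epigenome-ssm-model", version = 1L,
    K = fit$K, E = fit$E, variant = fit$variant,
    lambda1 = fit$lambda1, lambda2 = fit$lambda2,
    seed = fit$seed, tracks = fit$tracks,
    Z = fit$Z, T = fit$T,
    iterations = fit$iterations, converged = fit$converged,
    history = fit$history)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read a fitted model written by [write_ssm_model()]
#' @param path JSON model file path.
#' @return An `epigenome_ssm` object.
#' @export
read_ssm_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "epigenome-ssm-model")) {
    rlang::abort(sprintf("'%s' is not an epigenome-ssm model file.", path))
  }
  Z <- if (is.matrix(p$Z)) p$Z else matrix(unlist(p$Z), p$E, p$K, byrow = TRUE)
  Tm <- if (is.matrix(p$T)) p$T else matrix(unlist(p$T), p$K, p$K, byrow = TRUE)
  dimnames(Z) <- list(p$tracks, paste0("F", seq_len(p$K)))
  structure(
    list(Z = Z, T = Tm, lambda1 = p$lambda1,
         lambda2 = p$lambda2, variant = p$variant, K = as.integer(p$K),
         E = as.integer(p$E), tracks = p$tracks, seed = as.integer(p$seed),
         history = tibble::as_tibble(p$history),
         iterations = as.integer(p$iterations),
         converged = isTRUE(p$converged),
         multipliers = NULL),
    class = c("epigenome_ssm", "ssm_params"))
}
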