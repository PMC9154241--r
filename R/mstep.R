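# M-step solvers. The expected complete-data log-likelihood is, up to
# constants, -0.5 tr(Z S_aa Z') + tr(Z S_ya') for the emission part and
# -0.5 tr(T S_prev T') + tr(T S_cross') for the transition part; with the
# squared-Frobenius penalties this gives ridge normal equations
# Z (S_aa + 2*lambda1 I) = S_ya and T (S_prev + 2*lambda2 I) = S_cross.
# Rows of Z decouple, so the non-negative update is E independent K-dim
# quadratic programs solved by an active-set method of Lagrange multipliers.

#' Update the emission matrix from sufficient statistics
#'
#' Unconstrained variant: the ridge normal-equation solve. Non-negative and
#' sum-to-one variants: each track's row of `Z` is a non-negative quadratic
#' program solved by an active-set method — step toward the unconstrained
#' optimum of the free entries by the largest feasible step, pin every entry
#' that hits zero (ties pin together), recompute the Lagrange multipliers of
#' the pinned set, and release entries whose multiplier turns negative.
#' Complementary slackness (`multiplier * entry == 0`) holds at exit; the
#' multipliers are returned in the `"multipliers"` attribute.
#'
#' @param stats An `ssm_stats` object (possibly summed over chains).
#' @param lambda1 Squared-Frobenius penalty weight on `Z`.
#' @param variant Model variant; `"nonneg"` and `"sumone"` constrain all
#'   entries of `Z` to be non-negative.
#' @return The E x K emission matrix; constrained solves carry a
#'   `"multipliers"` attribute (zero on free entries, KKT multiplier on
#'   pinned ones).
#' @export
update_Z <- function(stats, lambda1 = 0.01,
                     variant = c("nonneg", "unconstrained", "sumone")) {
  variant <- match.arg(variant)
  K <- ncol(stats$S_aa)
  A <- stats$S_aa + 2 * lambda1 * diag(K)
  if (rcond_safe(A) < 1e-12) {
    if (lambda1 == 0) {
      rlang::abort(paste0("Sufficient statistics are singular with ",
                          "lambda1 = 0; set lambda1 > 0."))
    }
    rlang::abort("Emission update system is numerically singular.")
  }
  B <- stats$S_ya                                 # E x K
  if (variant == "unconstrained") {
    Z <- t(solve(A, t(B)))
    attr(Z, "multipliers") <- matrix(0, nrow(Z), ncol(Z))
    return(Z)
  }
  Z <- matrix(0, nrow(B), K)
  Lam <- matrix(0, nrow(B), K)
  for (e in seq_len(nrow(B))) {
    sol <- nnqp_active_set(A, B[e, ])
    Z[e, ] <- sol$z
    Lam[e, ] <- sol$multipliers
  }
  dimnames(Z) <- dimnames(B)
  attr(Z, "multipliers") <- Lam
  Z
}

# Minimize 0.5 z'Az - b'z subject to z >= 0 (A symmetric positive definite).
# Active-set with Lagrange multipliers: pinned entries sit at zero with
# multiplier = gradient; free entries solve the reduced normal equations.
nnqp_active_set <- function(A, b, max_iter = 100L, tol = 1e-10) {
  K <- length(b)
  z <- numeric(K)
  pinned <- rep(TRUE, K)
  for (iter in seq_len(max_iter)) {
    grad <- drop(A %*% z) - b
    viol <- which(pinned & grad < -tol)
    if (length(viol) == 0L) break
    pinned[viol[which.min(grad[viol])]] <- FALSE   # release worst multiplier
    # inner loop: drive the free entries to their reduced optimum, pinning
    # any entry the largest feasible step takes to zero
    repeat {
      free <- which(!pinned)
      zstar <- numeric(K)
      zstar[free] <- solve(A[free, free, drop = FALSE], b[free])
      if (all(zstar[free] >= -tol)) {
        z <- pmax(zstar, 0)
        z[pinned] <- 0
        break
      }
      s <- zstar - z                               # direction to optimum
      shrink <- free[s[free] < 0 & zstar[free] < 0]
      tau_max <- min(z[shrink] / (z[shrink] - zstar[shrink]))
      z <- z + tau_max * s
      hit <- free[z[free] <= tol]                  # ties: pin all that hit 0
      z[hit] <- 0
      pinned[hit] <- TRUE
    }
  }
  grad <- drop(A %*% z) - b
  multipliers <- ifelse(pinned, grad, 0)
  list(z = z, multipliers = multipliers, active = pinned)
}

rcond_safe <- function(A) {
  out <- tryCatch(rcond(A), error = function(e) 0)
  if (!is.finite(out)) 0 else out
}

#' Update the transition matrix from sufficient statistics
#'
#' Ridge normal-equation solve
#' `T = S_cross (S_prev + 2*lambda2 I)^{-1}` from the lag-one and
#' previous-position second moments.
#'
#' @param stats An `ssm_stats` object with lag-one cross terms.
#' @param lambda2 Squared-Frobenius penalty weight on `T`.
#' @return The K x K transition matrix.
#' @export
update_T <- function(stats, lambda2 = 0.01) {
  K <- ncol(stats$S_prev)
  A <- stats$S_prev + 2 * lambda2 * diag(K)
  if (rcond_safe(A) < 1e-12) {
    if (lambda2 == 0) {
      rlang::abort(paste0("Sufficient statistics are singular with ",
                          "lambda2 = 0; set lambda2 > 0."))
    }
    rlang::abort("Transition update system is numerically singular.")
  }
  t(solve(A, t(stats$S_cross)))
}
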