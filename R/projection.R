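#' Project a state vector onto the non-negative orthant
#'
#' The constrained filtered estimate solves
#' \eqn{\min_\alpha \{(\alpha-\hat\alpha)^\top(\alpha-\hat\alpha) : A\alpha = 0\}}
#' where \eqn{A} has one row per violated coordinate (\eqn{A_{ij} = 1} iff
#' \eqn{i = j} and \eqn{\hat\alpha_i < 0}), with closed form
#' \eqn{\hat\alpha - A^\top (A A^\top)^{-1} A \hat\alpha}. Because the rows of
#' \eqn{A} are distinct standard basis vectors this zeroes exactly the
#' negative coordinates and leaves the rest untouched; the projection is
#' idempotent.
#'
#' @param alpha_hat Numeric vector (a single state estimate).
#' @return The projected vector, all entries `>= 0`.
#' @export
#' @examples
#' project_nonneg(c(1.5, -0.3))
project_nonneg <- function(alpha_hat) {
  stopifnot(is.numeric(alpha_hat), all(is.finite(alpha_hat)))
  neg <- which(alpha_hat < 0)
  if (length(neg) == 0L) return(alpha_hat)
  K <- length(alpha_hat)
  A <- matrix(0, nrow = length(neg), ncol = K)
  A[cbind(seq_along(neg), neg)] <- 1
  out <- alpha_hat - drop(t(A) %*% solve(A %*% t(A), A %*% alpha_hat))
  # selection rows make the formula an exact coordinate zeroing; snap any
  # floating residue on the pinned coordinates
  out[neg] <- 0
  out
}

#' Project a state vector onto the capped simplex
#'
#' Euclidean projection onto \eqn{\{\alpha \ge 0, \sum_k \alpha_k \le 1\}},
#' the constraint set of the sum-to-one model variant (non-negativity plus a
#' unit cap on the total feature mass). If clamping the negative coordinates
#' already satisfies the cap that clamp is the projection; otherwise the
#' vector is projected onto the probability simplex by the standard
#' sort-and-threshold rule.
#'
#' @param alpha_hat Numeric vector.
#' @return Projected vector with `min >= 0` and `sum <= 1`.
#' @export
#' @examples
#' project_sumone(c(2, 0))
project_sumone <- function(alpha_hat) {
  stopifnot(is.numeric(alpha_hat), all(is.finite(alpha_hat)))
  drop(project_sumone_cpp(alpha_hat))
}
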