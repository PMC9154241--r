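# Independent oracles used across the suite.

# Exact posterior of all latent states of one chain by explicit joint-Gaussian
# conditioning: build Cov((alpha_1..alpha_G, y_1..y_G)) from the generative
# equations and condition on the stacked observations. Brute force, O((GK)^3).
joint_gaussian_posterior <- function(Y, Z, Tm) {
  G <- nrow(Y); K <- ncol(Z)
  idx <- function(g) ((g - 1) * K + 1):(g * K)
  vars <- vector("list", G)
  vars[[1]] <- diag(K)
  if (G > 1) for (g in 2:G) vars[[g]] <- Tm %*% vars[[g - 1]] %*% t(Tm) + diag(K)
  Sa <- matrix(0, G * K, G * K)
  for (h in seq_len(G)) {
    block <- vars[[h]]
    Sa[idx(h), idx(h)] <- block
    if (h < G) for (g in (h + 1):G) {
      block <- Tm %*% block                  # Cov(a_g, a_h) = T^(g-h) Var(a_h)
      Sa[idx(g), idx(h)] <- block
      Sa[idx(h), idx(g)] <- t(block)
    }
  }
  M <- kronecker(diag(G), Z)                 # stacked emission map
  Sy <- M %*% Sa %*% t(M) + diag(nrow(M))
  Cay <- Sa %*% t(M)
  yvec <- as.vector(t(Y))
  mu <- Cay %*% solve(Sy, yvec)
  Pc <- Sa - Cay %*% solve(Sy, t(Cay))
  list(
    mean = matrix(mu, ncol = K, byrow = TRUE),
    cov = lapply(seq_len(G), function(g) Pc[idx(g), idx(g), drop = FALSE]),
    lag1 = lapply(seq_len(G), function(g) {
      if (g == 1) matrix(0, K, K) else Pc[idx(g), idx(g - 1), drop = FALSE]
    }))
}

# Non-negative QP oracle: minimize 0.5 z'Az - b'z, z >= 0, by exhaustive
# enumeration of pinned-coordinate subsets (feasible KKT point of an SPD
# quadratic is the global optimum; we take the feasible candidate with the
# lowest objective for robustness).
nnqp_oracle <- function(A, b) {
  K <- length(b)
  best <- NULL; best_obj <- Inf
  for (code in 0:(2^K - 1)) {
    pinned <- as.logical(bitwAnd(code, 2^(0:(K - 1))))
    z <- numeric(K)
    free <- which(!pinned)
    if (length(free) > 0) {
      z[free] <- tryCatch(solve(A[free, free, drop = FALSE], b[free]),
                          error = function(e) rep(NA_real_, length(free)))
    }
    if (anyNA(z) || any(z < -1e-9)) next
    obj <- 0.5 * drop(t(z) %*% A %*% z) - sum(b * z)
    if (obj < best_obj - 1e-15) { best_obj <- obj; best <- z }
  }
  best
}

random_spd <- function(K, jitter = 0.1) {
  M <- matrix(rnorm(K * K), K)
  crossprod(M) + jitter * diag(K)
}

# small random model for filter/smoother oracle tests
random_instance <- function(G, K, E) {
  list(Y = matrix(rnorm(G * E), G, E),
       Z = matrix(rnorm(E * K), E, K),
       Tm = matrix(rnorm(K * K, sd = 0.5), K, K))
}

ssm_params_from <- function(Z, Tm, variant = "unconstrained",
                            lambda1 = 0, lambda2 = 0) {
  structure(list(Z = Z, T = Tm, lambda1 = lambda1, lambda2 = lambda2,
                 variant = variant, K = ncol(Z), E = nrow(Z), seed = 1L),
            class = "ssm_params")
}
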