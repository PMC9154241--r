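test_that("init_params is seeded, uniform, and starts T at the identity", {
  p1 <- init_params(3, 2, seed = 42)
  p2 <- init_params(3, 2, seed = 42)
  expect_identical(p1$Z, p2$Z)
  expect_identical(p1$T, diag(2))
  expect_true(all(p1$Z >= 0 & p1$Z < 1))
  expect_warning(init_params(2, 3, seed = 1), "over-complete")
})

test_that("zero emission makes the filter ignore the data", {
  p <- ssm_params_from(matrix(0, 1, 1), matrix(0.7, 1, 1))
  f <- kalman_filter(matrix(c(5, -3, 2), 3, 1), p)
  expect_equal(f$mu_filt, f$mu_pred)
  expect_equal(f$mu_pred[1, 1], 0)
})

test_that("single-step scalar filter matches the conjugate Gaussian update", {
  p <- ssm_params_from(matrix(1, 1, 1), matrix(1, 1, 1))
  f <- kalman_filter(matrix(2, 1, 1), p)
  expect_equal(f$mu_filt[1, 1], 1.0)
  expect_equal(f$P_filt[1, 1, 1], 0.5)
})

test_that("filter and smoother match brute-force joint-Gaussian conditioning", {
  withr::local_seed(11)
  for (rep in 1:5) {
    G <- sample(2:5, 1); K <- sample(1:3, 1); E <- sample(1:3, 1)
    inst <- random_instance(G, K, E)
    oracle <- joint_gaussian_posterior(inst$Y, inst$Z, inst$Tm)
    p <- ssm_params_from(inst$Z, inst$Tm)
    f <- kalman_filter(inst$Y, p)
    s <- kalman_smooth(f)
    # last filtered state is the conditional of alpha_G given all data
    expect_equal(f$mu_filt[G, ], oracle$mean[G, ], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(s$mu_smooth, oracle$mean, tolerance = 1e-8,
                 ignore_attr = TRUE)
    for (g in seq_len(G)) {
      expect_equal(s$P_smooth[, , g], oracle$cov[[g]], tolerance = 1e-8,
                   ignore_attr = TRUE)
      if (g > 1) {
        expect_equal(s$C_lag[, , g], oracle$lag1[[g]], tolerance = 1e-8,
                     ignore_attr = TRUE)
      }
    }
  }
})

test_that("smoother boundary cases: G = 1 and T = 0", {
  p <- ssm_params_from(matrix(c(1, 0.5), 2, 1), matrix(0.9, 1, 1))
  f <- kalman_filter(matrix(c(1, 2), 1, 2), p)
  s <- kalman_smooth(f)
  expect_equal(s$mu_smooth[1, ], f$mu_filt[1, ])

  # with T = 0 states are conditionally independent given their own bin
  inst <- random_instance(4, 2, 2)
  p0 <- ssm_params_from(inst$Z, matrix(0, 2, 2))
  f0 <- kalman_filter(inst$Y, p0)
  s0 <- kalman_smooth(f0)
  expect_equal(s0$mu_smooth, f0$mu_filt, tolerance = 1e-10)
  oracle <- joint_gaussian_posterior(inst$Y, inst$Z, matrix(0, 2, 2))
  expect_equal(s0$mu_smooth, oracle$mean, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("non-finite observations are rejected with guidance", {
  p <- ssm_params_from(matrix(1, 1, 1), matrix(1, 1, 1))
  expect_error(kalman_filter(matrix(c(1, NA), 2, 1), p), "masked")
})

test_that("project_nonneg equals coordinate clamping and is idempotent", {
  expect_equal(project_nonneg(c(1.5, -0.3)), c(1.5, 0))
  expect_equal(project_nonneg(c(2.0, 0.1)), c(2.0, 0.1))
  expect_equal(project_nonneg(c(-1, -2, 3)), c(0, 0, 3))
  expect_equal(project_nonneg(project_nonneg(c(-1, -2, 3))),
               project_nonneg(c(-1, -2, 3)))
  withr::local_seed(3)
  for (i in 1:50) {
    v <- rnorm(sample(1:6, 1), sd = 2)
    expect_equal(project_nonneg(v), pmax(v, 0))
  }
})

test_that("project_sumone is the Euclidean projection onto the capped simplex", {
  expect_equal(project_sumone(c(0.2, 0.3)), c(0.2, 0.3))
  expect_equal(project_sumone(c(2, 0)), c(1, 0))
  # brute-force grid oracle in K = 2
  withr::local_seed(7)
  grid <- expand.grid(a = seq(0, 1, 5e-4), b = seq(0, 1, 5e-4))
  grid <- grid[grid$a + grid$b <= 1, ]
  for (i in 1:5) {
    v <- rnorm(2, sd = 1.2)
    p <- project_sumone(v)
    d_grid <- min((grid$a - v[1])^2 + (grid$b - v[2])^2)
    expect_lte(sum((p - v)^2), d_grid + 1e-5)
    expect_true(min(p) >= 0 && sum(p) <= 1 + 1e-9)
  }
  for (i in 1:100) {
    p <- project_sumone(rnorm(sample(1:5, 1), sd = 2))
    expect_gte(min(p), 0)
    expect_lte(sum(p), 1 + 1e-9)
    expect_equal(project_sumone(p), p, tolerance = 1e-12)
  }
})

test_that("projected filtering keeps stored means inside the constraint set", {
  withr::local_seed(5)
  inst <- random_instance(50, 3, 2)
  p <- ssm_params_from(inst$Z, 0.5 * diag(3), variant = "nonneg")
  f <- kalman_filter(inst$Y, p)
  expect_gte(min(f$mu_filt), 0)
  s <- kalman_smooth(f)
  expect_gte(min(s$mu_smooth), 0)
  p1 <- ssm_params_from(inst$Z, 0.5 * diag(3), variant = "sumone")
  s1 <- kalman_smooth(kalman_filter(inst$Y, p1))
  expect_gte(min(s1$mu_smooth), 0)
  expect_lte(max(rowSums(s1$mu_smooth)), 1 + 1e-9)
})

test_that("sufficient statistics accumulate posterior moments additively", {
  K <- 2; G <- 4
  # hand-built posterior: zero means, identity covariances
  post <- structure(list(
    mu_smooth = matrix(0, G, K), mu_smooth_raw = matrix(0, G, K),
    P_smooth = array(diag(K), c(K, K, G)),
    C_lag = array(0, c(K, K, G)),
    Y = matrix(1, G, 3)), class = "ssm_posterior")
  st <- accumulate_stats(post)
  expect_equal(st$S_aa, G * diag(K))
  expect_equal(st$S_cross, matrix(0, K, K))

  # deterministic posterior (zero covariance): S_aa is the Gram matrix
  mu <- matrix(rnorm(G * K), G, K)
  post2 <- structure(list(
    mu_smooth = mu, mu_smooth_raw = mu,
    P_smooth = array(0, c(K, K, G)), C_lag = array(0, c(K, K, G)),
    Y = matrix(rnorm(G * 3), G, 3)), class = "ssm_posterior")
  st2 <- accumulate_stats(post2)
  expect_equal(st2$S_aa, crossprod(mu))

  # additivity across chains
  tot <- st + st2
  expect_equal(tot$S_aa, st$S_aa + st2$S_aa)
  expect_equal(tot$G, st$G + st2$G)

  # matches the C++ accumulation on a real chain
  withr::local_seed(9)
  inst <- random_instance(6, 2, 2)
  p <- ssm_params_from(inst$Z, inst$Tm)
  s <- kalman_smooth(kalman_filter(inst$Y, p))
  st3 <- accumulate_stats(s)
  cpp <- chromfeat:::ssm_kalman_cpp(inst$Y, inst$Z, inst$Tm, 0L, TRUE,
                                    TRUE, FALSE)
  expect_equal(st3$S_aa, cpp$S_aa, tolerance = 1e-10)
  expect_equal(st3$S_cross, cpp$S_cross, tolerance = 1e-10)
  expect_equal(st3$S_ya, cpp$S_ya, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("penalized objective equals the closed-form likelihood minus penalties", {
  # G = 2, K = E = 1: y is bivariate normal with
  # Var(y1) = Z^2 + 1, Var(y2) = Z^2 (T^2 + 1) + 1, Cov = Z^2 T
  Z <- 0.8; Tm <- 0.6
  y <- c(1.3, -0.4)
  S <- matrix(c(Z^2 + 1, Z^2 * Tm, Z^2 * Tm, Z^2 * (Tm^2 + 1) + 1), 2)
  closed <- -log(2 * pi) - 0.5 * log(det(S)) -
    0.5 * drop(t(y) %*% solve(S, y))
  p0 <- ssm_params_from(matrix(Z, 1, 1), matrix(Tm, 1, 1))
  expect_equal(penalized_objective(p0, matrix(y, 2, 1)), closed,
               tolerance = 1e-10)

  # with penalties: subtract lambda * squared Frobenius norms
  p1 <- ssm_params_from(matrix(Z, 1, 1), matrix(Tm, 1, 1),
                        lambda1 = 0.3, lambda2 = 0.2)
  expect_equal(penalized_objective(p1, matrix(y, 2, 1)),
               closed - 0.3 * Z^2 - 0.2 * Tm^2, tolerance = 1e-10)
  expect_lt(penalized_objective(p1, matrix(y, 2, 1)),
            penalized_objective(p0, matrix(y, 2, 1)))
})
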