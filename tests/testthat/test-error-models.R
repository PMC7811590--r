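test_that("neural-network kernel is symmetric, bounded and matches hand value", {
  set.seed(1)
  t1 <- runif(20, 0, 0.11); t2 <- runif(20, 0, 0.11)
  k12 <- nn_kernel(t1, t2, w = 5.39e4, b = 138)
  k21 <- nn_kernel(t2, t1, w = 5.39e4, b = 138)
  expect_equal(k12, k21, tolerance = 1e-14)
  expect_true(all(abs(k12) <= 1))
  ## k(0, 0) with b = 138: (2/pi) asin(276/277)
  expect_equal(nn_kernel(0, 0, w = 5.39e4, b = 138), 0.9458889,
               tolerance = 1e-6)
  ## saturation: large b + w t^2 drives the diagonal to 1
  expect_equal(nn_kernel(5, 5, w = 1e8, b = 1e6), 1, tolerance = 1e-3)
})

test_that("error covariance is PD with smallest eigenvalue above sigma_n2", {
  tt <- seq(0, 0.11, length.out = 50)
  for (w in c(1.5e4, 5e4, 8.9e4)) {
    for (b in c(2, 138, 480)) {
      gp <- gp_mismatch(w, b, sigma_n2 = 0.05)
      C <- build_covariance(tt, gp)
      ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), 0.05 * (1 - 1e-8))
    }
  }
  ## kernel vanishes as w, b -> 0: C -> sigma_n2 I
  gp0 <- gp_mismatch(1e-12, 1e-12, sigma_n2 = 0.3)
  C0 <- build_covariance(tt, gp0)
  expect_lt(max(abs(C0 - diag(0.3, 50))), 1e-9)
  ## n = 1
  g1 <- gp_mismatch(5e4, 138, 0.05)
  C1 <- build_covariance(0.05, g1)
  expect_equal(as.numeric(C1), nn_kernel(0.05, 0.05, 5e4, 138) + 0.05)
  ## PD holds on a long grid too
  t2k <- seq(0, 0.11, length.out = 600)
  expect_silent(C2 <- build_covariance(t2k, g1))
})

test_that("iid log-likelihood matches the closed form", {
  expect_equal(loglik_iid(c(1, -1), c(0, 0), 1), -(log(2 * pi) + 1),
               tolerance = 1e-12)
  y <- rnorm(10); expect_equal(loglik_iid(y, y, 0.5),
                               -(10 / 2) * log(2 * pi * 0.5))
  ## sigma2 maximizing the likelihood is SSR/n
  set.seed(2)
  r <- rnorm(40)
  s_hat <- optimize(function(s) loglik_iid(r, rep(0, 40), s),
                    c(0.01, 10), maximum = TRUE)$maximum
  expect_equal(s_hat, mean(r^2), tolerance = 1e-3)
  expect_error(loglik_iid(1:3, 1:2, 1), "equal length")
})

test_that("correlated log-likelihood agrees with hand and iid reductions", {
  ## 2x2 hand example: Mahalanobis 2/3
  C <- matrix(c(2, 1, 1, 2), 2)
  ll <- loglik_correlated(c(1, 1), c(0, 0), C)
  expect_equal(ll, -log(2 * pi) - 0.5 * log(3) - 1 / 3, tolerance = 1e-12)
  ## C = sigma2 I reduces to the iid likelihood
  set.seed(3)
  y <- rnorm(25); m <- rnorm(25)
  expect_equal(loglik_correlated(y, m, diag(0.7, 25)),
               loglik_iid(y, m, 0.7), tolerance = 1e-8)
  ## scale invariance of the Mahalanobis part
  ll1 <- loglik_correlated(c(1, 1), c(0, 0), C)
  ll4 <- loglik_correlated(c(2, 2), c(0, 0), 4 * C)
  maha1 <- -2 * (ll1 + 0.5 * determinant(2 * pi * C)$modulus[1])
  maha4 <- -2 * (ll4 + 0.5 * determinant(2 * pi * 4 * C)$modulus[1])
  expect_equal(maha1, maha4, tolerance = 1e-10)
  ## block-diagonal multi-vessel form equals the sum of blocks
  tt <- seq(0, 0.11, length.out = 20)
  gp <- gp_mismatch(5e4, 138, 0.05)
  Cb <- build_covariance(tt, gp)
  ys <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  ms <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  joint <- loglik_correlated(ys, ms, rep(list(Cb), 3))
  parts <- sum(mapply(function(y, m) loglik_correlated(y, m, Cb), ys, ms))
  expect_equal(joint, parts, tolerance = 1e-8)
  ## pointwise conditional terms sum exactly to the joint value
  pw <- loglik_correlated(ys, ms, rep(list(Cb), 3), pointwise = TRUE)
  expect_equal(sum(pw$pointwise), joint, tolerance = 1e-10)
  expect_length(pw$pointwise, 60)
})

test_that("draws from the error covariance whiten correctly", {
  tt <- seq(0, 0.11, length.out = 120)
  gp <- gp_mismatch(5.39e4, 138, 0.05)
  C <- build_covariance(tt, gp)
  R <- attr(C, "chol")
  set.seed(4)
  for (i in 1:5) {
    draw <- drop(crossprod(R, rnorm(120)))
    white <- backsolve(R, draw, transpose = TRUE)
    expect_lt(abs(var(white) - 1), 3 / sqrt(120))
  }
})

test_that("mismatch posterior prediction obeys the GP conditioning limits", {
  tt <- seq(0, 0.1, length.out = 10)
  gp <- gp_mismatch(5e4, 100, 1e-8)
  y <- sin(20 * tt); m <- rep(0, 10)
  ## zero residual: predictive mean identically zero
  p0 <- mismatch_predict(tt, m, m, gp)
  expect_equal(max(abs(p0$mean)), 0, tolerance = 1e-10)
  ## noise-free limit interpolates the residuals at the training points
  pi_ <- mismatch_predict(tt, y, m, gp, tstar = tt)
  expect_equal(pi_$mean, y - m, tolerance = 1e-4)
  ## brute-force conditioning oracle via solve() on a small grid
  gp2 <- gp_mismatch(3e4, 50, 0.2)
  ts <- c(0.02, 0.55)
  pred <- mismatch_predict(tt, y, m, gp2, tstar = ts)
  C <- outer(tt, tt, nn_kernel, w = 3e4, b = 50) + diag(0.2, 10)
  Ks <- outer(tt, ts, nn_kernel, w = 3e4, b = 50)
  Kss <- outer(ts, ts, nn_kernel, w = 3e4, b = 50)
  expect_equal(pred$mean, drop(t(Ks) %*% solve(C, y - m)),
               tolerance = 1e-8)
  expect_equal(pred$cov, Kss - t(Ks) %*% solve(C, Ks), tolerance = 1e-8)
  ## predictive variance grows away from the data but never exceeds the
  ## prior variance at that input
  far <- mismatch_predict(tt, y, m, gp2, tstar = c(0.05, 0.55),
                          noise = TRUE)
  v_near <- far$cov[1, 1]; v_far <- far$cov[2, 2]
  prior_far <- gp2$scale * (nn_kernel(0.55, 0.55, 3e4, 50) + 0.2)
  expect_gt(v_far, v_near)
  expect_lte(v_far, prior_far + 1e-10)
})
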