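test_that("noise-free standard generation satisfies the model identity", {
  des <- standard_design(var_e = 0, sd_slope = 0, var_u0 = 0,
                         gamma00 = 0, gamma01 = 1, gamma10 = 0.3,
                         n_clusters = 10, n_per_cluster = 5)
  p <- simulate_standard(des, seed = 11)
  tr <- cluster_truth(p)
  xbar <- tr$xbar[match(p$cluster, tr$cluster)]
  expect_equal(p$y, xbar + 0.3 * (p$x - xbar), tolerance = 1e-12)
})

test_that("simulation is deterministic under a fixed seed", {
  d1 <- simulate_standard(standard_design(n_clusters = 2, n_per_cluster = 3),
                          seed = 5)
  d2 <- simulate_standard(standard_design(n_clusters = 2, n_per_cluster = 3),
                          seed = 5)
  expect_identical(d1$y, d2$y)
  expect_identical(d1$x, d2$x)
  a1 <- simulate_ar(tiny_ar(sd_phi = 0.1, var_mu = 3, var_e = 3), seed = 9)
  a2 <- simulate_ar(tiny_ar(sd_phi = 0.1, var_mu = 3, var_e = 3), seed = 9)
  expect_identical(a1$y, a2$y)
  expect_identical(cluster_truth(a1), cluster_truth(a2))
  z1 <- simulate_ar_z(ar_design_z(n_clusters = 8, n_per_cluster = 5), seed = 3)
  z2 <- simulate_ar_z(ar_design_z(n_clusters = 8, n_per_cluster = 5), seed = 3)
  expect_identical(z1, z2)
})

test_that("white-noise limit has negligible pooled lag-1 autocorrelation", {
  des <- ar_design(grand_mean = 5, phi_mean = 0, sd_phi = 0, var_mu = 0,
                   var_e = 1, n_clusters = 200, n_per_cluster = 50)
  p <- simulate_ar(des, seed = 21)
  expect_equal(mean(p$y), 5, tolerance = 0.05)
  r <- ols_within(build_lag(p), "lag_y", "y")$estimate
  # truth 0 minus O(1/T) demeaning bias, with MC noise
  expect_lt(abs(r - within_bias_approx(0, 50)), 0.03)
})

test_that("simulated series attain the stationary AR(1) variance", {
  Tn <- 1e5
  des <- ar_design(phi_mean = 0.3, sd_phi = 0, var_mu = 0, var_e = 1,
                   n_clusters = 2, n_per_cluster = Tn)
  p <- simulate_ar(des, seed = 31)
  v <- var(p$y[p$cluster == 1])
  v_true <- 1 / (1 - 0.09)
  # 3 x approximate MC SE of the sample variance of a Gaussian AR(1)
  tol <- 3 * v_true * sqrt(2 / Tn * (1 + 0.09) / (1 - 0.09))
  expect_lt(abs(v - v_true), tol)
})

test_that("lag-k autocovariance follows phi^k * var_e / (1 - phi^2)", {
  Tn <- 1e5
  phi <- 0.5
  p <- simulate_ar(ar_design(phi_mean = phi, sd_phi = 0, var_mu = 0,
                             var_e = 2, n_clusters = 2,
                             n_per_cluster = Tn), seed = 41)
  y <- p$y[p$cluster == 1]
  g0 <- 2 / (1 - phi^2)
  for (k in 1:3) {
    ghat <- mean((y[-(1:k)] - mean(y)) * (y[seq_len(Tn - k)] - mean(y)))
    expect_equal(ghat, phi^k * g0, tolerance = 0.08)
  }
})

test_that("cluster-mean variance of the predictor is recovered at large N", {
  des <- standard_design(n_clusters = 1e4, n_per_cluster = 3, var_xbar = 1)
  p <- simulate_standard(des, seed = 51)
  xb <- tapply(p$x, p$cluster, mean)
  # var(xbar_hat) = var_xbar + var_x_within / T
  expect_equal(var(xb), 1 + 1 / 3, tolerance = 3 * sqrt(2 / 1e4) * (4 / 3))
  expect_equal(var(cluster_truth(p)$xbar), 1, tolerance = 3 * sqrt(2 / 1e4))
})

test_that("retained truth replays the generated series exactly", {
  p <- simulate_ar(tiny_ar(sd_phi = 0.1, var_mu = 2, var_e = 1.5), seed = 61)
  tr <- cluster_truth(p)
  for (cl in unique(p$cluster)) {
    y <- p$y[p$cluster == cl]
    mu <- tr$mu_true[tr$cluster == cl]
    phi <- tr$phi_true[tr$cluster == cl]
    e <- (y[-1] - mu) - phi * (y[-length(y)] - mu)
    # rebuild the series from the first deviation and the recovered shocks
    a <- Reduce(function(prev, ee) phi * prev + ee, e,
                init = y[1] - mu, accumulate = TRUE)
    expect_equal(mu + a, y, tolerance = 1e-12)
  }
})

test_that("phi draws are truncated to the stationary region and counted", {
  des <- ar_design(phi_mean = 0.9, sd_phi = 0.5, var_mu = 1, var_e = 1,
                   n_clusters = 200, n_per_cluster = 3)
  p <- simulate_ar(des, seed = 71)
  expect_true(all(abs(cluster_truth(p)$phi_true) < 1))
  expect_gt(attr(p, "phi_redraws"), 0)
  # at realistic dispersion redraws are (essentially) never needed
  p2 <- simulate_ar(ar_design(phi_mean = 0.3, sd_phi = 0.1,
                              n_clusters = 500, n_per_cluster = 3), seed = 72)
  expect_identical(attr(p2, "phi_redraws"), 0L)
})

test_that("level-2 predictor design yields the stated correlations empirically", {
  des <- ar_design_z(n_clusters = 2e4, n_per_cluster = 2)
  p <- simulate_ar_z(des, seed = 81)
  tr <- cluster_truth(p)
  expect_lt(abs(cor(tr$phi_true, tr$z) - 0.371), 0.02)
  expect_lt(abs(cor(tr$mu_true, tr$z) - 0.37), 0.02)
  expect_lt(abs(cor(tr$mu_true, tr$phi_true) - 0.14), 0.02)
  # null cross-level effect: no phi-z correlation
  d0 <- ar_design_z(gamma11_z = 0, n_clusters = 2e4, n_per_cluster = 2)
  t0 <- cluster_truth(simulate_ar_z(d0, seed = 82))
  expect_lt(abs(cor(t0$phi_true, t0$z)), 0.02)
})
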