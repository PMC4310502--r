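test_that("between-cluster OLS recovers exact lines through cluster means", {
  p <- tibble::tibble(cluster = rep(1:3, each = 2), t = rep(1:2, 3),
                      x = c(-1, 1, 0, 2, 1, 3), y = c(-2, 2, 1, 3, 3, 5))
  # cluster means: x = (0, 1, 2), y = (0, 2, 4)
  expect_equal(ols_between(p, "x", "y")$estimate, 2, tolerance = 1e-12)
  # identical cluster means give slope 1
  expect_equal(ols_between(p, "x", "x")$estimate, 1, tolerance = 1e-12)
  expect_error(ols_between(p[p$cluster < 3, ], "x", "y"), "3 clusters")
  p0 <- p; p0$x <- rep(c(-1, 1), 3)
  expect_error(ols_between(p0, "x", "y"), "zero variance")
})

test_that("within-cluster OLS recovers an exact within slope and guards degeneracy", {
  p <- simulate_standard(standard_design(n_clusters = 10, n_per_cluster = 6,
                                         var_e = 0, sd_slope = 0),
                         seed = 1)
  p$y2 <- p$x   # outcome identical to predictor within clusters
  expect_equal(ols_within(p, "x", "y2")$estimate, 1, tolerance = 1e-12)
  pz <- p; pz$x <- rep(1, nrow(pz))
  expect_error(ols_within(pz, "x", "y"), "within-cluster variance")
})

test_that("empirical-Bayes means match the Gaussian posterior-mean oracle", {
  des <- ar_design(grand_mean = 2, phi_mean = 0, sd_phi = 0, var_mu = 2,
                   var_e = 1, n_clusters = 40, n_per_cluster = 8)
  p <- simulate_ar(des, seed = 2)
  ef <- fit_empty(p)
  expect_true(ef$converged)
  # oracle: lme4's conditional modes are the Gaussian posterior means
  blup <- ef$gamma00 + lme4::ranef(ef$model)$cluster[["(Intercept)"]]
  expect_equal(ef$eb$mu_hat, unname(blup), tolerance = 1e-6)
  # shrinkage limits of the closed form itself
  e0 <- eb_means(ybar = c(1, 5), n_i = c(8, 8), gamma00 = 3,
                 var_u0 = 0, var_e = 1)
  expect_equal(e0$mu_hat, c(3, 3))
  e1 <- eb_means(ybar = c(1, 5), n_i = c(1e9, 1e9), gamma00 = 3,
                 var_u0 = 2, var_e = 1)
  expect_equal(e1$mu_hat, c(1, 5), tolerance = 1e-6)
})

test_that("mixed-model slope recovers the generating slope on noise-free data", {
  des <- standard_design(var_e = 1e-8, var_u0 = 0, sd_slope = 0,
                         gamma10 = 0.3, n_clusters = 30, n_per_cluster = 10)
  p <- simulate_standard(des, seed = 3)
  cc <- apply_centering(p, "x", "CMC_sample")
  fit <- fit_lmm(cc, "x_c")
  g10 <- tidy(fit)$estimate[tidy(fit)$param == "gamma10"]
  expect_equal(g10, 0.3, tolerance = 1e-4)
})

test_that("fixed-slope CMC mixed fit tracks the pooled within-OLS slope", {
  p <- build_lag(simulate_ar(ar_design(phi_mean = 0.3, sd_phi = 0,
                                       var_mu = 1, var_e = 1), seed = 4))
  ow <- ols_within(p, "lag_y", "y")$estimate
  cc <- apply_centering(p, "lag_y", "CMC_sample")
  g10 <- tidy(fit_lmm(cc, "lag_y_c"))
  g10 <- g10$estimate[g10$param == "gamma10"]
  expect_equal(g10, ow, tolerance = 0.02)
})

test_that("grand-mean centering is a pure reparameterization of no centering", {
  # a tightly converged optimizer, so the reparameterization identity is
  # checked at close to machine precision rather than optimizer slack
  ctrl <- lme4::lmerControl(optimizer = "bobyqa",
                            check.conv.singular = "ignore",
                            optCtrl = list(rhoend = 1e-10))
  for (rs in c(FALSE, TRUE)) {
    p <- build_lag(simulate_ar(ar_design(phi_mean = 0.3,
                                         sd_phi = if (rs) 0.1 else 0,
                                         var_mu = 3, var_e = 3,
                                         n_clusters = 50), seed = 5 + rs))
    fn <- fit_lmm(apply_centering(p, "lag_y", "NC"), "lag_y_c",
                  random_slope = rs, control = ctrl)
    fg <- fit_lmm(apply_centering(p, "lag_y", "GMC"), "lag_y_c",
                  random_slope = rs, control = ctrl)
    sn <- tidy(fn); sg <- tidy(fg)
    expect_equal(sg$estimate[sg$param == "gamma10"],
                 sn$estimate[sn$param == "gamma10"], tolerance = 1e-6)
    expect_equal(fg$logLik, fn$logLik, tolerance = 1e-6)
    # intercepts differ by slope x grand mean
    g <- mean(p$lag_y, na.rm = TRUE)
    expect_equal(sg$estimate[sg$param == "gamma00"],
                 sn$estimate[sn$param == "gamma00"] +
                   sn$estimate[sn$param == "gamma10"] * g,
                 tolerance = 1e-5)
  }
})

test_that("contextual fixed-slope NC and CMC fits are equivalent models", {
  p <- simulate_standard(standard_design(n_clusters = 50, n_per_cluster = 10),
                         seed = 6)
  fn <- fit_lmm(apply_centering(p, "x", "NC"), "x_c", contextual = TRUE)
  fc <- fit_lmm(apply_centering(p, "x", "CMC_sample"), "x_c",
                contextual = TRUE)
  sn <- tidy(fn); sc <- tidy(fc)
  g10n <- sn$estimate[sn$param == "gamma10"]
  g10c <- sc$estimate[sc$param == "gamma10"]
  g01n <- sn$estimate[sn$param == "gamma01"]
  g01c <- sc$estimate[sc$param == "gamma01"]
  expect_equal(g10n, g10c, tolerance = 1e-4)
  expect_equal(g01n, g01c - g10c, tolerance = 1e-4)
  expect_equal(fn$logLik, fc$logLik, tolerance = 1e-4)
})

test_that("contextual random-slope NC and CMC fits are no longer equivalent", {
  des <- standard_design(sd_slope = 0.3, n_clusters = 60, n_per_cluster = 10)
  p <- simulate_standard(des, seed = 7)
  fn <- fit_lmm(apply_centering(p, "x", "NC"), "x_c", contextual = TRUE,
                random_slope = TRUE)
  fc <- fit_lmm(apply_centering(p, "x", "CMC_sample"), "x_c",
                contextual = TRUE, random_slope = TRUE)
  expect_gt(abs(fn$logLik - fc$logLik), 1e-4)
})

test_that("uncentered slope on standard data blends within and between slopes", {
  # within slope 0.3, between slope 1; the blend moves toward the between
  # slope as the intercept variance shrinks relative to the noise
  ests <- vapply(list(c(1, 1), c(0, 1), c(0, 3)), function(v) {
    des <- standard_design(var_u0 = v[1], var_e = v[2])
    est <- numeric(5)
    for (r in 1:5) {
      p <- simulate_standard(des, seed = 100 * v[1] + 10 * v[2] + r)
      f <- tidy(fit_lmm(apply_centering(p, "x", "NC"), "x_c"))
      est[r] <- f$estimate[f$param == "gamma10"]
    }
    mean(est)
  }, numeric(1))
  expect_true(all(ests > 0.3) && all(ests < 1))
  expect_true(ests[1] < ests[2] && ests[2] < ests[3])
})

test_that("between-cluster slope on AR panels is essentially 1", {
  p <- build_lag(simulate_ar(ar_design(phi_mean = 0.3, sd_phi = 0.1,
                                       var_mu = 3, var_e = 3,
                                       n_clusters = 200,
                                       n_per_cluster = 20), seed = 8))
  expect_equal(ols_between(p, "lag_y", "y")$estimate, 1, tolerance = 0.05)
})

test_that("implied grand mean transform inverts the intercept parameterization", {
  des <- ar_design(grand_mean = 3.5, phi_mean = 0.35, sd_phi = 0,
                   var_mu = 1, var_e = 1, n_clusters = 200,
                   n_per_cluster = 50)
  p <- build_lag(simulate_ar(des, seed = 9))
  fn <- fit_lmm(apply_centering(p, "lag_y", "NC"), "lag_y_c")
  tr <- transform_nc_params(fn)
  expect_equal(tr$implied_mean, 3.5, tolerance = 0.1)
  expect_true(tr$conf_low < tr$implied_mean &&
                tr$implied_mean < tr$conf_high)
  # zero intercept maps to zero mean
  f0 <- fit_lmm(apply_centering(
    build_lag(simulate_ar(tiny_ar(), seed = 10)), "lag_y", "NC"), "lag_y_c")
  f0$fixed$estimate[f0$fixed$param == "gamma00"] <- 0
  expect_equal(transform_nc_params(f0)$implied_mean, 0)
})

test_that("transform rejects non-stationary fits", {
  p <- build_lag(simulate_ar(tiny_ar(), seed = 11))
  f <- fit_lmm(apply_centering(p, "lag_y", "NC"), "lag_y_c")
  f$fixed$estimate[f$fixed$param == "gamma10"] <- 1.01
  expect_error(transform_nc_params(f), "undefined")
})

test_that("tidy and glance expose estimates, intervals and flags", {
  p <- build_lag(simulate_ar(tiny_ar(sd_phi = 0.1, var_mu = 3, var_e = 3),
                             seed = 12))
  f <- fit_lmm(apply_centering(p, "lag_y", "CMC_sample"), "lag_y_c",
               random_slope = TRUE)
  td <- tidy(f)
  expect_setequal(td$param, c("gamma00", "gamma10"))
  expect_true(all(td$conf_low <= td$estimate & td$estimate <= td$conf_high))
  expect_true(all(td$std_error > 0))
  gl <- glance(f)
  expect_true(gl$var_u0 >= 0 && gl$sigma2_e >= 0)
  expect_identical(gl$criterion, "REML")
  expect_equal(gl$n_rows, 20 * 9)
})

test_that("cross-level interaction terms are labelled gamma01 and gamma11", {
  p <- build_lag(simulate_ar_z(ar_design_z(n_clusters = 40), seed = 13))
  f <- fit_lmm(apply_centering(p, "lag_y", "CMC_sample"), "lag_y_c",
               random_slope = TRUE, z = "z")
  expect_setequal(tidy(f)$param, c("gamma00", "gamma10", "gamma01", "gamma11"))
})
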