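#' @importFrom rlang .data
#' @importFrom stats rnorm sd var coef logLik qnorm cor
NULL

new_panel <- function(tbl, truth, design, seed) {
  attr(tbl, "truth") <- truth
  attr(tbl, "design") <- design
  attr(tbl, "seed") <- seed
  class(tbl) <- c("inertia_panel", class(tbl))
  tbl
}

#' Per-cluster generating truth of a simulated panel
#'
#' Simulated panels carry the cluster-level quantities used to generate
#' them (true means, slopes/inertias, covariates). These are needed for
#' true-mean centering and for bias computation in Monte-Carlo runs.
#'
#' @param panel A panel returned by one of the `simulate_*()` functions.
#' @return A tibble with one row per cluster, or `NULL` for panels that
#'   were read from disk without a truth file.
#' @export
cluster_truth <- function(panel) attr(panel, "truth")

# Draw (u0, u1) with the given covariance structure; phi rows violating
# |phi_mean + u1| < 1 - tol are redrawn jointly so the retained draws are
# the truncated bivariate normal.
draw_level2_ar <- function(n, phi_mean, var_mu, sd_phi, cov_mu_phi,
                           tol = 1e-6, max_tries = 1000L) {
  rho <- if (var_mu > 0 && sd_phi > 0) {
    cov_mu_phi / (sqrt(var_mu) * sd_phi)
  } else 0
  draw <- function(m) {
    z1 <- rnorm(m); z2 <- rnorm(m)
    u0 <- sqrt(var_mu) * z1
    u1 <- sd_phi * (rho * z1 + sqrt(max(0, 1 - rho^2)) * z2)
    cbind(u0, u1)
  }
  u <- draw(n)
  redraws <- 0L
  bad <- which(abs(phi_mean + u[, 2]) >= 1 - tol)
  tries <- 0L
  while (length(bad) > 0L) {
    tries <- tries + 1L
    if (tries > max_tries) stop("could not draw |phi_i| < 1; check sd_phi")
    redraws <- redraws + length(bad)
    u[bad, ] <- draw(length(bad))
    bad <- bad[abs(phi_mean + u[bad, 2]) >= 1 - tol]
  }
  list(u0 = u[, 1], u1 = u[, 2], redraws = redraws)
}

# Stationary AR(1) series per cluster: a_1 from the stationary
# distribution, then a_t = phi_i a_{t-1} + e_t. Returns the N x T matrix.
gen_ar_series <- function(phi_i, var_e, n_per) {
  n <- length(phi_i)
  a <- matrix(0, n, n_per)
  a[, 1] <- rnorm(n, 0, sqrt(var_e / (1 - phi_i^2)))
  for (t in seq_len(n_per)[-1]) {
    a[, t] <- phi_i * a[, t - 1] + rnorm(n, 0, sqrt(var_e))
  }
  a
}

#' Simulate from the standard two-level model
#'
#' Generates a balanced panel in which the between-cluster slope
#' (`gamma01`) and the (average) within-cluster slope (`gamma10`) of a
#' level-1 predictor `x` differ; see [standard_design()] for the model.
#'
#' @param design A [standard_design()].
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return A tibble with columns `cluster`, `t`, `x`, `y` (N*T rows,
#'   occasions consecutive within cluster), carrying the per-cluster truth
#'   (`xbar`, `beta_i`, `u0`) retrievable with [cluster_truth()].
#' @examples
#' p <- simulate_standard(standard_design(n_clusters = 5, n_per_cluster = 4),
#'                        seed = 1)
#' cluster_truth(p)
#' @export
simulate_standard <- function(design, seed = NULL) {
  stopifnot(inherits(design, "standard_design"))
  if (!is.null(seed)) set.seed(seed)
  N <- design$n_clusters; Tn <- design$n_per_cluster
  xbar <- rnorm(N, 0, sqrt(design$var_xbar))
  beta_i <- rnorm(N, design$gamma10, design$sd_slope)
  u0 <- rnorm(N, 0, sqrt(design$var_u0))
  w <- matrix(rnorm(N * Tn, 0, sqrt(design$var_x_within)), N, Tn)
  e <- matrix(rnorm(N * Tn, 0, sqrt(design$var_e)), N, Tn)
  x <- xbar + w
  y <- design$gamma00 + design$gamma01 * xbar + beta_i * w + u0 + e
  tbl <- tibble::tibble(
    cluster = rep(seq_len(N), each = Tn),
    t = rep(seq_len(Tn), N),
    x = as.vector(t(x)),
    y = as.vector(t(y))
  )
  truth <- tibble::tibble(cluster = seq_len(N), xbar = xbar,
                          beta_i = beta_i, u0 = u0)
  new_panel(tbl, truth, design, seed)
}

#' Simulate from the multilevel AR(1) model
#'
#' Generates a balanced panel of stationary AR(1) series around random
#' cluster means, with (optionally) random inertia; see [ar_design()].
#' The first occasion of each series is drawn from its stationary
#' distribution \eqn{N(0, \sigma^2_e / (1 - \phi_i^2))}, so no burn-in is
#' needed. Draws with \eqn{|\phi_i| \ge 1} are redrawn (the count is kept
#' in the `"phi_redraws"` attribute); at the dispersions used in practice
#' (`sd_phi` of about 0.1) redraws are vanishingly rare.
#'
#' @param design An [ar_design()].
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return A tibble with columns `cluster`, `t`, `y`; [cluster_truth()]
#'   returns the generating `mu_true` and `phi_true` per cluster.
#' @examples
#' p <- simulate_ar(ar_design(phi_mean = 0.3, n_clusters = 4,
#'                            n_per_cluster = 6), seed = 2)
#' head(p)
#' @export
simulate_ar <- function(design, seed = NULL) {
  stopifnot(inherits(design, "ar_design"))
  if (inherits(design, "ar_design_z")) return(simulate_ar_z(design, seed))
  if (!is.null(seed)) set.seed(seed)
  N <- design$n_clusters; Tn <- design$n_per_cluster
  lvl2 <- draw_level2_ar(N, design$phi_mean, design$var_mu, design$sd_phi,
                         design$cov_mu_phi)
  mu_i <- design$grand_mean + lvl2$u0
  phi_i <- design$phi_mean + lvl2$u1
  a <- gen_ar_series(phi_i, design$var_e, Tn)
  tbl <- tibble::tibble(
    cluster = rep(seq_len(N), each = Tn),
    t = rep(seq_len(Tn), N),
    y = as.vector(t(mu_i + a))
  )
  truth <- tibble::tibble(cluster = seq_len(N), mu_true = mu_i,
                          phi_true = phi_i)
  out <- new_panel(tbl, truth, design, seed)
  attr(out, "phi_redraws") <- lvl2$redraws
  out
}

#' Simulate from the multilevel AR(1) model with a level-2 predictor
#'
#' As [simulate_ar()], but cluster means and inertias are first regressed
#' on a centered level-2 covariate \eqn{z_i}; see [ar_design_z()].
#'
#' @param design An [ar_design_z()].
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return A tibble with columns `cluster`, `t`, `y`, `z` (z constant
#'   within cluster); [cluster_truth()] returns `mu_true`, `phi_true`, `z`.
#' @export
simulate_ar_z <- function(design, seed = NULL) {
  stopifnot(inherits(design, "ar_design_z"))
  if (!is.null(seed)) set.seed(seed)
  N <- design$n_clusters; Tn <- design$n_per_cluster
  z <- rnorm(N, 0, sqrt(design$var_z))
  u0 <- rnorm(N, 0, sqrt(design$resid_var_mu))
  u1 <- rnorm(N, 0, sqrt(design$resid_var_phi))
  phi_i <- design$phi_mean + design$gamma11_z * z + u1
  redraws <- 0L
  bad <- which(abs(phi_i) >= 1 - 1e-6)
  while (length(bad) > 0L) {
    redraws <- redraws + length(bad)
    u1[bad] <- rnorm(length(bad), 0, sqrt(design$resid_var_phi))
    phi_i[bad] <- design$phi_mean + design$gamma11_z * z[bad] + u1[bad]
    bad <- bad[abs(phi_i[bad]) >= 1 - 1e-6]
  }
  mu_i <- design$grand_mean + design$gamma01_z * z + u0
  a <- gen_ar_series(phi_i, design$var_e, Tn)
  tbl <- tibble::tibble(
    cluster = rep(seq_len(N), each = Tn),
    t = rep(seq_len(Tn), N),
    y = as.vector(t(mu_i + a)),
    z = rep(z, each = Tn)
  )
  truth <- tibble::tibble(cluster = seq_len(N), mu_true = mu_i,
                          phi_true = phi_i, z = z)
  out <- new_panel(tbl, truth, design, seed)
  attr(out, "phi_redraws") <- redraws
  out
}
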