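#' Design objects for the panel simulators
#'
#' A design bundles every constant of a data-generating condition: fixed
#' effects, random-effect (co)variances, residual variances, and the panel
#' dimensions (number of clusters N and occasions per cluster T). The
#' defaults reproduce the baseline conditions of the package's Monte-Carlo
#' study; see `vignette("centering-inertia")`.
#'
#' @name designs
NULL

check_scalar <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  ok <- if (strict_min) x > min else x >= min
  if (!ok) {
    stop("`", name, "` must be ", if (strict_min) "> " else ">= ", min,
         " (got ", x, ")", call. = FALSE)
  }
  as.numeric(x)
}

#' Standard two-level design with distinct within- and between-cluster slopes
#'
#' Specifies the data-generating model
#' \deqn{y_{ti} = \gamma_{00} + \gamma_{01}\bar x_{\cdot i} +
#'   \beta_i (x_{ti} - \bar x_{\cdot i}) + u_{0i} + e_{ti}}
#' with \eqn{\bar x_{\cdot i} \sim N(0, \sigma^2_{\bar x})},
#' \eqn{x_{ti} = \bar x_{\cdot i} + w_{ti}},
#' \eqn{w_{ti} \sim N(0, \sigma^2_{xw})},
#' \eqn{\beta_i \sim N(\gamma_{10}, \mathrm{sd\_slope}^2)},
#' \eqn{u_{0i} \sim N(0, \sigma^2_{u0})} and
#' \eqn{e_{ti} \sim N(0, \sigma^2_e)}. The within-cluster slope
#' (\eqn{\beta_W = \gamma_{10}}) and the between-cluster slope
#' (\eqn{\beta_B = \gamma_{01}}) can differ, which is what makes the choice
#' of centering for \eqn{x_{ti}} consequential.
#'
#' @param gamma00 Grand intercept.
#' @param gamma10 Fixed (average) within-cluster slope \eqn{\beta_W}.
#' @param gamma01 Between-cluster slope \eqn{\beta_B}.
#' @param sd_slope Standard deviation of the random within-cluster slope
#'   \eqn{\beta_i}; 0 gives a fixed-slope model.
#' @param var_u0 Level-2 residual variance of the intercept
#'   \eqn{\sigma^2_{u0}}.
#' @param var_e Level-1 residual variance \eqn{\sigma^2_e}.
#' @param var_x_within Within-cluster variance of the predictor.
#' @param var_xbar Variance of the cluster means of the predictor.
#' @param n_clusters Number of clusters N (>= 2).
#' @param n_per_cluster Occasions per cluster T (>= 2).
#' @return An object of class `standard_design`.
#' @seealso [simulate_standard()]
#' @examples
#' standard_design(var_u0 = 0, var_e = 3)
#' @export
standard_design <- function(gamma00 = 0, gamma10 = 0.3, gamma01 = 1,
                            sd_slope = 0, var_u0 = 1, var_e = 1,
                            var_x_within = 1, var_xbar = 1,
                            n_clusters = 100, n_per_cluster = 20) {
  d <- list(
    gamma00 = check_scalar(gamma00, "gamma00"),
    gamma10 = check_scalar(gamma10, "gamma10"),
    gamma01 = check_scalar(gamma01, "gamma01"),
    sd_slope = check_scalar(sd_slope, "sd_slope", min = 0),
    var_u0 = check_scalar(var_u0, "var_u0", min = 0),
    var_e = check_scalar(var_e, "var_e", min = 0),
    var_x_within = check_scalar(var_x_within, "var_x_within", min = 0),
    var_xbar = check_scalar(var_xbar, "var_xbar", min = 0),
    n_clusters = as.integer(check_scalar(n_clusters, "n_clusters", min = 2)),
    n_per_cluster = as.integer(check_scalar(n_per_cluster, "n_per_cluster", min = 2))
  )
  structure(d, class = c("standard_design", "inertia_design"))
}

#' Multilevel AR(1) design with random means and random inertia
#'
#' Specifies the stationary two-level autoregressive model
#' \deqn{y_{ti} = \mu_i + a_{ti}, \quad
#'       a_{ti} = \phi_i a_{t-1,i} + e_{ti}}
#' with \eqn{\mu_i = \mu + u_{0i}}, \eqn{\phi_i = \phi + u_{1i}}, and
#' \eqn{(u_{0i}, u_{1i})} jointly mean-zero Gaussian with variances
#' `var_mu`, `sd_phi^2` and covariance `cov_mu_phi`. The autoregressive
#' parameter \eqn{\phi_i} is the cluster's *inertia*: the carryover of a
#' deviation from equilibrium to the next occasion.
#'
#' @param grand_mean Grand mean \eqn{\mu}.
#' @param phi_mean Average autoregressive parameter \eqn{\phi}
#'   (must satisfy |phi_mean| < 1).
#' @param sd_phi Standard deviation of \eqn{\phi_i}; 0 gives fixed inertia.
#' @param var_mu Level-2 variance of the cluster means \eqn{\sigma^2_{u0}}.
#' @param var_e Innovation variance \eqn{\sigma^2_e} (> 0).
#' @param cov_mu_phi Covariance between \eqn{u_{0i}} and \eqn{u_{1i}}.
#' @param n_clusters,n_per_cluster Panel dimensions N and T.
#' @return An object of class `ar_design`.
#' @seealso [simulate_ar()]
#' @examples
#' ar_design(phi_mean = 0.3, sd_phi = 0.1, var_mu = 3, var_e = 3)
#' @export
ar_design <- function(grand_mean = 0, phi_mean = 0.3, sd_phi = 0,
                      var_mu = 1, var_e = 1, cov_mu_phi = 0,
                      n_clusters = 100, n_per_cluster = 20) {
  d <- list(
    grand_mean = check_scalar(grand_mean, "grand_mean"),
    phi_mean = check_scalar(phi_mean, "phi_mean"),
    sd_phi = check_scalar(sd_phi, "sd_phi", min = 0),
    var_mu = check_scalar(var_mu, "var_mu", min = 0),
    var_e = check_scalar(var_e, "var_e", min = 0, strict_min = TRUE),
    cov_mu_phi = check_scalar(cov_mu_phi, "cov_mu_phi"),
    n_clusters = as.integer(check_scalar(n_clusters, "n_clusters", min = 2)),
    n_per_cluster = as.integer(check_scalar(n_per_cluster, "n_per_cluster", min = 2))
  )
  if (abs(d$phi_mean) >= 1) {
    stop("`phi_mean` must lie strictly inside (-1, 1) for a stationary process",
         call. = FALSE)
  }
  # 2x2 random-effect covariance must be positive semi-definite
  det2 <- d$var_mu * d$sd_phi^2 - d$cov_mu_phi^2
  if (det2 < -1e-12) {
    stop("random-effect covariance matrix implied by (var_mu, sd_phi^2, ",
         "cov_mu_phi) is not positive semi-definite", call. = FALSE)
  }
  structure(d, class = c("ar_design", "inertia_design"))
}

#' Multilevel AR(1) design with a level-2 predictor of mean and inertia
#'
#' Extends [ar_design()] with a centered level-2 covariate \eqn{z_i \sim
#' N(0, \mathrm{var\_z})} that enters both level-2 equations:
#' \deqn{\mu_i = \mu + \gamma_{01} z_i + u_{0i}, \quad
#'       \phi_i = \phi + \gamma_{11} z_i + u_{1i},}
#' with \eqn{u_{0i} \sim N(0, \mathrm{resid\_var\_mu})} and
#' \eqn{u_{1i} \sim N(0, \mathrm{resid\_var\_phi})} independent of each
#' other and of \eqn{z_i}. \eqn{\gamma_{11}} is the cross-level
#' interaction: the effect of the covariate on a cluster's inertia.
#'
#' The defaults give var\eqn{(\phi_i)} = 0.0116 and var\eqn{(\mu_i)} = 3,
#' so that \eqn{\mu_i} and \eqn{\phi_i} each correlate 0.37 with
#' \eqn{z_i} and 0.14 with each other — a deliberately weak, realistic
#' level-2 signal (see the package vignette).
#'
#' @inheritParams ar_design
#' @param var_z Variance of the level-2 predictor \eqn{z_i}.
#' @param gamma01_z Effect of \eqn{z_i} on the cluster mean \eqn{\mu_i}.
#' @param gamma11_z Effect of \eqn{z_i} on the inertia \eqn{\phi_i}
#'   (the cross-level interaction \eqn{\gamma_{11}}).
#' @param resid_var_mu Residual level-2 variance of \eqn{\mu_i} given z.
#' @param resid_var_phi Residual level-2 variance of \eqn{\phi_i} given z.
#' @return An object of class `ar_design_z`.
#' @seealso [simulate_ar_z()]
#' @export
ar_design_z <- function(grand_mean = 0, phi_mean = 0.3, var_z = 0.01,
                        gamma01_z = 6.408, gamma11_z = 0.4,
                        resid_var_mu = 3 - gamma01_z^2 * var_z,
                        resid_var_phi = 0.01, var_e = 3,
                        n_clusters = 100, n_per_cluster = 20) {
  base <- ar_design(grand_mean = grand_mean, phi_mean = phi_mean,
                    sd_phi = sqrt(check_scalar(resid_var_phi, "resid_var_phi", min = 0)),
                    var_mu = check_scalar(resid_var_mu, "resid_var_mu", min = 0),
                    var_e = var_e, cov_mu_phi = 0,
                    n_clusters = n_clusters, n_per_cluster = n_per_cluster)
  d <- c(unclass(base), list(
    var_z = check_scalar(var_z, "var_z", min = 0),
    gamma01_z = check_scalar(gamma01_z, "gamma01_z"),
    gamma11_z = check_scalar(gamma11_z, "gamma11_z"),
    resid_var_mu = check_scalar(resid_var_mu, "resid_var_mu", min = 0),
    resid_var_phi = check_scalar(resid_var_phi, "resid_var_phi", min = 0)
  ))
  structure(d, class = c("ar_design_z", "ar_design", "inertia_design"))
}

#' @export
print.inertia_design <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  flds <- unclass(x)
  for (nm in names(flds)) cat(sprintf("  %-14s %s\n", nm, format(flds[[nm]])))
  invisible(x)
}

#' Total implied level-2 moments of an `ar_design_z`
#'
#' Returns the marginal variances of \eqn{\mu_i} and \eqn{\phi_i} and the
#' three pairwise correlations among \eqn{(\mu_i, \phi_i, z_i)} implied by
#' the variance decomposition of the design.
#'
#' @param design An [ar_design_z()] object.
#' @return A one-row tibble with columns `var_mu_total`, `var_phi_total`,
#'   `cor_mu_z`, `cor_phi_z`, `cor_mu_phi`.
#' @examples
#' implied_moments(ar_design_z())
#' @export
implied_moments <- function(design) {
  stopifnot(inherits(design, "ar_design_z"))
  vmu <- design$gamma01_z^2 * design$var_z + design$resid_var_mu
  vph <- design$gamma11_z^2 * design$var_z + design$resid_var_phi
  tibble::tibble(
    var_mu_total = vmu,
    var_phi_total = vph,
    cor_mu_z = design$gamma01_z * sqrt(design$var_z) / sqrt(vmu),
    cor_phi_z = design$gamma11_z * sqrt(design$var_z) / sqrt(vph),
    cor_mu_phi = design$gamma01_z * design$gamma11_z * design$var_z /
      sqrt(vmu * vph)
  )
}
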