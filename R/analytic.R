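#' First-order approximation to the demeaned-AR(1) slope bias
#'
#' When each series is centered at its own sample mean before the AR(1)
#' slope is estimated, the estimator is biased downward by O(1/T) — the
#' dynamic-panel (Nickell-type) bias. The classical first-order
#' approximation to the expectation bias is
#' \deqn{E[\hat\phi] - \phi \approx -\frac{1 + \phi}{T - 1}.}
#' The bias is negative for every stationary \eqn{\phi}, more severe for
#' positive \eqn{\phi}, and vanishes as T grows. The approximation
#' degrades at very small T (T below about 10); see [within_bias_sim()]
#' for a brute-force check of its validity range.
#'
#' @param phi Autoregressive parameter(s), |phi| < 1.
#' @param T Series length(s), >= 3.
#' @return The approximate bias (vectorized over `phi` and `T`).
#' @examples
#' within_bias_approx(0.3, 20)   # about -0.068
#' @export
within_bias_approx <- function(phi, T) {
  if (any(abs(phi) >= 1)) stop("|phi| must be < 1", call. = FALSE)
  if (any(T < 3)) stop("T must be >= 3", call. = FALSE)
  -(1 + phi) / (T - 1)
}

#' Simulation oracle for the demeaned-AR(1) slope bias
#'
#' Simulates many independent mean-zero stationary AR(1) series of length
#' T, demeans each by its own full sample mean, and computes the pooled
#' OLS slope (cross-products summed over all series and occasions, as in
#' [ols_within()] on a many-cluster panel). Returns the deviation from
#' `phi` with a delta-method Monte-Carlo standard error. This is a
#' brute-force, assumption-free counterpart to [within_bias_approx()].
#' Note the pooled estimator is the relevant one here: the *single*-series
#' demeaned AR(1) estimate has a larger small-sample bias (a
#' ratio-of-sums versus mean-of-ratios distinction).
#'
#' @param phi Autoregressive parameter, |phi| < 1.
#' @param T Series length, >= 3.
#' @param n_series Number of independent series.
#' @param seed Integer seed, or `NULL`.
#' @param var_e Innovation variance (the bias is scale-free; exposed for
#'   completeness).
#' @return A one-row tibble: `phi`, `T`, `bias`, `mc_se`, `n_series`.
#' @examples
#' within_bias_sim(0.3, 20, n_series = 2000, seed = 1)
#' @export
within_bias_sim <- function(phi, T, n_series = 1e4, seed = NULL,
                            var_e = 1) {
  stopifnot(abs(phi) < 1, T >= 3, n_series >= 1)
  if (!is.null(seed)) set.seed(seed)
  y <- gen_ar_series(rep(phi, n_series), var_e, T)
  m <- rowMeans(y)
  yc <- y - m
  num <- rowSums(yc[, 2:T, drop = FALSE] * yc[, 1:(T - 1), drop = FALSE])
  den <- rowSums(yc[, 1:(T - 1), drop = FALSE]^2)
  est <- sum(num) / sum(den)
  # delta-method SE of a ratio of sums of iid per-series contributions
  se <- stats::sd(num - est * den) / (mean(den) * sqrt(n_series))
  tibble::tibble(phi = phi, T = T, bias = est - phi, mc_se = se,
                 n_series = n_series)
}

#' Bias of the demeaned AR(1) estimator over a (phi, T) grid
#'
#' Evaluates either the closed-form approximation or the simulation
#' oracle over a grid, returning a tidy curve suitable for plotting with
#' [autoplot.inertia_bias_curve()] or export with [readr::write_csv()].
#'
#' @param phi Vector of autoregressive parameters.
#' @param T Vector of series lengths.
#' @param method `"approx"` (closed form) or `"sim"` (brute force).
#' @param n_series Series per grid point when `method = "sim"`.
#' @param seed Base seed for `"sim"` (each grid point offsets it).
#' @return A tibble of class `inertia_bias_curve` with columns `phi`,
#'   `T`, `bias`, `method`, and `mc_se` (`NA` for the closed form).
#' @examples
#' bias_curve(phi = c(0, 0.3), T = c(10, 20, 50))
#' @export
bias_curve <- function(phi = c(-0.3, 0, 0.3), T = c(10, 20, 50, 100),
                       method = c("approx", "sim"), n_series = 1e4,
                       seed = 1) {
  method <- match.arg(method)
  grid <- tidyr::expand_grid(phi = phi, T = T)
  out <- if (method == "approx") {
    dplyr::mutate(grid, bias = within_bias_approx(.data$phi, .data$T),
                  mc_se = NA_real_)
  } else {
    dplyr::bind_rows(purrr::pmap(
      dplyr::mutate(grid, i = dplyr::row_number()),
      function(phi, T, i) {
        within_bias_sim(phi, T, n_series = n_series,
                        seed = seed + i)[, c("phi", "T", "bias", "mc_se")]
      }))
  }
  out$method <- method
  class(out) <- c("inertia_bias_curve", class(out))
  out
}
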