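#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

cluster_means <- function(panel, cols, rows = TRUE) {
  cols <- unique(cols)
  sub <- panel[rows, c("cluster", cols)]
  dplyr::summarise(dplyr::group_by(sub, .data$cluster),
                   dplyr::across(dplyr::all_of(cols), mean),
                   .groups = "drop")
}

#' Between-cluster OLS slope
#'
#' Regresses the cluster means of the outcome on the cluster means of the
#' predictor (with intercept), across clusters. For a lagged-outcome
#' predictor in a stationary AR panel this slope is essentially 1: the
#' cluster means of the series and of its lag coincide up to edge terms.
#' Means are taken over the analysis rows (rows with a non-missing
#' predictor value) so predictor and outcome means are computed on the
#' same occasions.
#'
#' @param panel A long-format panel.
#' @param predictor,outcome Column names.
#' @return A one-row tibble: `estimate` (the slope), `intercept`,
#'   `n_clusters`.
#' @examples
#' p <- simulate_standard(standard_design(), seed = 1)
#' ols_between(p, "x", "y")
#' @export
ols_between <- function(panel, predictor = "x", outcome = "y") {
  rows <- !is.na(panel[[predictor]]) & !is.na(panel[[outcome]])
  cm <- cluster_means(panel, c(predictor, outcome), rows)
  if (nrow(cm) < 3) stop("need at least 3 clusters", call. = FALSE)
  xb <- cm[[predictor]]; yb <- cm[[outcome]]
  sxx <- sum((xb - mean(xb))^2)
  if (sxx == 0) stop("cluster means of the predictor have zero variance",
                     call. = FALSE)
  slope <- sum((xb - mean(xb)) * (yb - mean(yb))) / sxx
  tibble::tibble(estimate = slope,
                 intercept = mean(yb) - slope * mean(xb),
                 n_clusters = nrow(cm))
}

#' Pooled within-cluster OLS slope
#'
#' The no-intercept OLS slope of the cluster-centered outcome on the
#' cluster-centered predictor, pooled over all analysis rows. For an
#' ordinary level-1 predictor each variable is centered at its own
#' cluster mean (computed over the analysis rows). For a lagged-outcome
#' predictor (created by [build_lag()]) *both* the outcome and the lagged
#' predictor are centered at the cluster's full-series outcome mean
#' \eqn{\bar y_{\cdot i}} — the sample analogue of the cluster mean
#' \eqn{\mu_i} — which makes this the demeaned AR(1) estimator whose
#' downward O(1/T) bias the package studies (see [within_bias_approx()]).
#'
#' Clusters whose centered predictor has zero variance contribute nothing
#' to either sum; if all do, an error is raised.
#'
#' @inheritParams ols_between
#' @return A one-row tibble: `estimate`, `n_clusters`, `n_rows` (analysis
#'   rows used).
#' @examples
#' p <- build_lag(simulate_ar(ar_design(), seed = 1))
#' ols_within(p, "lag_y", "y")
#' @export
ols_within <- function(panel, predictor = "x", outcome = "y") {
  src <- centering_source(panel, predictor)
  rows <- !is.na(panel[[predictor]]) & !is.na(panel[[outcome]])
  if (src == outcome) {
    # lagged outcome: one centering constant per cluster, the full-series mean
    ctr <- cluster_means(panel, src)
    m <- ctr[[src]][match(panel$cluster, ctr$cluster)]
    xc <- (panel[[predictor]] - m)[rows]
    yc <- (panel[[outcome]] - m)[rows]
  } else {
    ctr <- cluster_means(panel, c(predictor, outcome), rows)
    mx <- ctr[[predictor]][match(panel$cluster, ctr$cluster)]
    my <- ctr[[outcome]][match(panel$cluster, ctr$cluster)]
    xc <- (panel[[predictor]] - mx)[rows]
    yc <- (panel[[outcome]] - my)[rows]
  }
  sxx <- sum(xc^2)
  if (sxx == 0) stop("no within-cluster variance in the predictor",
                     call. = FALSE)
  tibble::tibble(estimate = sum(xc * yc) / sxx,
                 n_clusters = length(unique(panel$cluster[rows])),
                 n_rows = sum(rows))
}

#' Empirical-Bayes (shrinkage) cluster means
#'
#' The posterior mean of a cluster's level given the empty random-intercept
#' model: \eqn{\hat\mu_i = \hat\gamma_{00} + \lambda_i(\bar y_{\cdot i} -
#' \hat\gamma_{00})} with reliability weight
#' \eqn{\lambda_i = \sigma^2_{u0} / (\sigma^2_{u0} + \sigma^2_e / T_i)}.
#'
#' @param ybar Cluster sample means.
#' @param n_i Observations per cluster.
#' @param gamma00 Grand-mean estimate.
#' @param var_u0 Level-2 intercept variance.
#' @param var_e Level-1 residual variance.
#' @return A tibble with columns `ybar`, `n_i`, `lambda`, `mu_hat`.
#' @seealso [fit_empty()]
#' @export
eb_means <- function(ybar, n_i, gamma00, var_u0, var_e) {
  lambda <- if (var_u0 == 0) rep(0, length(ybar)) else {
    var_u0 / (var_u0 + var_e / n_i)
  }
  tibble::tibble(ybar = ybar, n_i = n_i, lambda = lambda,
                 mu_hat = gamma00 + lambda * (ybar - gamma00))
}

#' Fit the empty (random-intercept-only) model
#'
#' Fits \eqn{y_{ti} = \mu + u_{0i} + a_{ti}} by (RE)ML and returns the
#' variance components together with the empirical-Bayes cluster means.
#'
#' @param panel A long-format panel.
#' @param outcome Outcome column name.
#' @param reml Use REML (default) or ML.
#' @return A list with `gamma00`, `var_u0`, `var_e`, `converged`, `eb`
#'   (the [eb_means()] tibble with a `cluster` column) and `model` (the
#'   underlying `merMod`).
#' @export
fit_empty <- function(panel, outcome = "y", reml = TRUE) {
  dat <- data.frame(..y = panel[[outcome]], cluster = panel$cluster)
  res <- quiet_lmer(..y ~ 1 + (1 | cluster), dat, reml = reml)
  vc <- as.data.frame(lme4::VarCorr(res$fit))
  var_u0 <- vc$vcov[vc$grp == "cluster"][1]
  var_e <- vc$vcov[vc$grp == "Residual"][1]
  gamma00 <- unname(lme4::fixef(res$fit)[1])
  cm <- dplyr::summarise(dplyr::group_by(dat, .data$cluster),
                         ybar = mean(.data$..y), n_i = dplyr::n(),
                         .groups = "drop")
  eb <- eb_means(cm$ybar, cm$n_i, gamma00, var_u0, var_e)
  eb <- dplyr::bind_cols(tibble::tibble(cluster = cm$cluster), eb)
  list(gamma00 = gamma00, var_u0 = var_u0, var_e = var_e,
       converged = res$converged, eb = eb, model = res$fit)
}

# lmer with convergence/singularity bookkeeping instead of warnings.
quiet_lmer <- function(formula, data, reml = TRUE, control = NULL) {
  if (is.null(control)) {
    control <- lme4::lmerControl(check.conv.singular = "ignore")
  }
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(formula, data = data, REML = reml, control = control),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  converged <- !any(grepl("failed to converge|convergence code", msgs,
                          ignore.case = TRUE))
  list(fit = fit, converged = converged, messages = msgs)
}

map_params <- function(terms, predictor, z = NULL) {
  out <- rep(NA_character_, length(terms))
  out[terms == "(Intercept)"] <- "gamma00"
  out[terms == predictor] <- "gamma10"
  out[terms == ".xbar"] <- "gamma01"
  if (!is.null(z)) {
    out[terms == z] <- "gamma01"
    out[terms %in% paste0(c(predictor, z), ":", c(z, predictor))] <- "gamma11"
  }
  out
}

#' Fit a two-level linear mixed model for a (possibly centered) predictor
#'
#' Wraps [lme4::lmer()] for the model family the package studies:
#' a level-1 predictor (raw or centered, typically a lagged outcome) with
#' a random intercept and optionally a random slope, optionally the
#' cluster means of the predictor's source as a level-2 covariate
#' (*contextual* model), and optionally a level-2 covariate `z` entering
#' both the intercept and the slope equation (cross-level interaction).
#'
#' Fixed effects are labelled in the two-level notation:
#' `gamma00` (intercept), `gamma10` (level-1 slope), `gamma01`
#' (cluster-mean or z effect on the intercept), `gamma11` (z effect on
#' the slope). 95% confidence intervals are Wald intervals,
#' estimate \eqn{\pm 1.96 \cdot} SE.
#'
#' A singular unstructured random-effect covariance triggers one refit
#' with independent (diagonal) random effects; the fallback is flagged in
#' `glance()`. Convergence failures are flagged, never silently dropped.
#'
#' @param panel A panel, typically from [apply_centering()].
#' @param predictor Level-1 predictor column (e.g. `"lag_y_c"`).
#' @param outcome Outcome column.
#' @param random_slope Give the predictor a random slope?
#' @param contextual Add the predictor source's cluster means as a
#'   level-2 covariate?
#' @param z Name of a level-2 covariate entering intercept and slope
#'   equations, or `NULL`.
#' @param reml Use REML (default) or ML.
#' @param control Optional [lme4::lmerControl()] override.
#' @return An object of class `inertia_fit`; see [tidy.inertia_fit()] and
#'   [glance.inertia_fit()].
#' @examples
#' p <- apply_centering(build_lag(simulate_ar(ar_design(), seed = 1)),
#'                      "lag_y", "CMC_sample")
#' fit <- fit_lmm(p, "lag_y_c")
#' tidy(fit)
#' @export
fit_lmm <- function(panel, predictor, outcome = "y", random_slope = FALSE,
                    contextual = FALSE, z = NULL, reml = TRUE,
                    control = NULL) {
  stopifnot(predictor %in% names(panel), outcome %in% names(panel))
  if (!is.null(z) && !z %in% names(panel)) {
    stop("level-2 covariate column `", z, "` not found", call. = FALSE)
  }
  keep <- c("cluster", outcome, predictor, z)
  dat <- as.data.frame(panel[, keep])
  if (contextual) {
    # cluster means of the *uncentered* source of the predictor
    info <- centering_info(panel)
    raw <- if (!is.null(info) && info$centered == predictor) {
      info$predictor
    } else predictor
    src <- centering_source(panel, raw)
    cm <- cluster_means(panel, src)
    dat$.xbar <- cm[[src]][match(dat$cluster, cm$cluster)]
  }
  rhs <- predictor
  if (contextual) rhs <- c(rhs, ".xbar")
  if (!is.null(z)) rhs <- c(rhs, z, paste0(predictor, ":", z))
  re <- if (random_slope) paste0("(1 + ", predictor, " | cluster)") else
    "(1 | cluster)"
  fml <- stats::as.formula(paste(outcome, "~", paste(c(rhs, re),
                                                     collapse = " + ")))
  dat <- dat[!is.na(dat[[predictor]]), , drop = FALSE]
  res <- quiet_lmer(fml, dat, reml = reml, control = control)
  singular_fallback <- FALSE
  if (random_slope && lme4::isSingular(res$fit)) {
    re2 <- paste0("(1 | cluster) + (0 + ", predictor, " | cluster)")
    fml2 <- stats::as.formula(paste(outcome, "~",
                                    paste(c(rhs, re2), collapse = " + ")))
    res2 <- quiet_lmer(fml2, dat, reml = reml, control = control)
    if (!lme4::isSingular(res2$fit)) {
      res <- res2
      singular_fallback <- TRUE
    }
  }
  fit <- res$fit
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  fixed <- tibble::tibble(
    param = map_params(names(est), predictor, z),
    term = names(est),
    estimate = unname(est),
    std_error = unname(se),
    conf_low = unname(est - 1.96 * se),
    conf_high = unname(est + 1.96 * se)
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_u0 <- sum(vc$vcov[is.na(vc$var2) & vc$var1 == "(Intercept)" &
                          vc$grp != "Residual"], na.rm = TRUE)
  var_u1 <- if (random_slope) {
    sum(vc$vcov[is.na(vc$var2) & vc$var1 == predictor], na.rm = TRUE)
  } else NA_real_
  cov_u01 <- if (random_slope && !singular_fallback) {
    s <- vc$vcov[!is.na(vc$var2)]
    if (length(s)) s[1] else 0
  } else if (random_slope) 0 else NA_real_
  structure(list(
    fixed = fixed,
    var_u0 = var_u0, var_u1 = var_u1, cov_u01 = cov_u01,
    sigma2_e = vc$vcov[vc$grp == "Residual"][1],
    logLik = as.numeric(stats::logLik(fit)),
    criterion = if (reml) "REML" else "ML",
    converged = res$converged,
    singular = lme4::isSingular(fit),
    singular_fallback = singular_fallback,
    random_slope = random_slope, contextual = contextual, z = z,
    predictor = predictor, outcome = outcome,
    scheme = centering_info(panel)$scheme,
    n_clusters = length(unique(dat$cluster)),
    n_rows = nrow(dat),
    model = fit
  ), class = "inertia_fit")
}

#' @export
print.inertia_fit <- function(x, ...) {
  cat("Two-level model fit (", x$criterion, ", ",
      if (x$random_slope) "random" else "fixed", " slope",
      if (!is.null(x$scheme)) paste0(", scheme ", x$scheme) else "",
      ")\n", sep = "")
  cat(x$n_rows, "rows in", x$n_clusters, "clusters;",
      if (x$converged) "converged" else "DID NOT CONVERGE", "\n\n")
  print(as.data.frame(x$fixed), digits = 4, row.names = FALSE)
  cat("\nRandom effects: var_u0 =", format(x$var_u0, digits = 4))
  if (!is.na(x$var_u1)) cat(", var_u1 =", format(x$var_u1, digits = 4))
  cat(", sigma2_e =", format(x$sigma2_e, digits = 4), "\n")
  invisible(x)
}

#' Tidy the fixed effects of an `inertia_fit`
#'
#' @param x An [fit_lmm()] result.
#' @param ... Unused.
#' @return A tibble with one row per fixed effect: `param` (two-level
#'   label `gamma00`/`gamma10`/`gamma01`/`gamma11`), `term`, `estimate`,
#'   `std_error`, `conf_low`, `conf_high` (95% Wald).
#' @export
tidy.inertia_fit <- function(x, ...) x$fixed

#' One-row model summary of an `inertia_fit`
#'
#' @param x An [fit_lmm()] result.
#' @param ... Unused.
#' @return A one-row tibble with variance components, log-likelihood,
#'   criterion, convergence/singularity flags and data dimensions.
#' @export
glance.inertia_fit <- function(x, ...) {
  tibble::tibble(
    var_u0 = x$var_u0, var_u1 = x$var_u1, cov_u01 = x$cov_u01,
    sigma2_e = x$sigma2_e, logLik = x$logLik, criterion = x$criterion,
    converged = x$converged, singular = x$singular,
    singular_fallback = x$singular_fallback,
    n_clusters = x$n_clusters, n_rows = x$n_rows
  )
}

#' Implied grand mean from an uncentered AR fit
#'
#' An AR model fitted without centering parameterizes each cluster by the
#' intercept \eqn{c_i = \mu_i (1 - \phi_i)} rather than its mean. The
#' implied grand mean on the mean scale is
#' \eqn{\hat\gamma_{00} / (1 - \hat\gamma_{10})}, reported here with a
#' delta-method standard error. Note the two parameterizations place the
#' normality assumption on different quantities (\eqn{c_i} vs
#' \eqn{\mu_i}), so they are structurally, not statistically, equivalent.
#'
#' @param fit An [fit_lmm()] result for an uncentered lagged-outcome model.
#' @return A one-row tibble: `implied_mean`, `std_error`, `conf_low`,
#'   `conf_high`.
#' @export
transform_nc_params <- function(fit) {
  stopifnot(inherits(fit, "inertia_fit"))
  fx <- fit$fixed
  g00 <- fx$estimate[fx$param == "gamma00"]
  g10 <- fx$estimate[fx$param == "gamma10"]
  if (!length(g00) || !length(g10)) {
    stop("fit must contain gamma00 and gamma10", call. = FALSE)
  }
  if (abs(g10) >= 1) {
    stop("|gamma10| >= 1: implied mean undefined (non-stationary fit)",
         call. = FALSE)
  }
  V <- as.matrix(stats::vcov(fit$model))
  idx <- match(fx$term[fx$param %in% c("gamma00", "gamma10")], colnames(V))
  grad <- c(1 / (1 - g10), g00 / (1 - g10)^2)
  se <- sqrt(drop(t(grad) %*% V[idx, idx] %*% grad))
  m <- g00 / (1 - g10)
  tibble::tibble(implied_mean = m, std_error = se,
                 conf_low = m - 1.96 * se, conf_high = m + 1.96 * se)
}
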