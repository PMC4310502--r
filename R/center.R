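#' Centering schemes for level-1 predictors
#'
#' The five supported schemes for a level-1 predictor:
#' * `"NC"` — no centering; the predictor enters raw.
#' * `"GMC"` — grand-mean centering; the pooled mean over all analysis
#'   rows is subtracted. A pure reparameterization of NC.
#' * `"CMC_sample"` — cluster-mean centering with each cluster's *sample*
#'   mean. For a lagged outcome the constant is the mean of all T outcome
#'   values of the cluster, not of the T-1 lagged values.
#' * `"CMC_eb"` — cluster-mean centering with the empirical-Bayes
#'   (shrinkage) mean from the empty random-intercept model; see
#'   [fit_empty()].
#' * `"CMC_true"` — cluster-mean centering with the generating cluster
#'   mean; available only for simulated data (via [cluster_truth()] or the
#'   `truth` argument).
#' @export
centering_schemes <- c("NC", "GMC", "CMC_sample", "CMC_eb", "CMC_true")

#' Add the lagged outcome as a level-1 predictor
#'
#' Creates the column `lag_<outcome>` holding the previous occasion's
#' value within each cluster. The first occasion of every cluster gets
#' `NA` in the lag column: it cannot serve as an outcome row (it only
#' contributes as a predictor value), leaving T-1 analysis rows per
#' cluster. Rows may arrive in any order; they are sorted by
#' `cluster`, `t` first. Occasions must be consecutive within cluster.
#'
#' @param panel A long-format panel with columns `cluster`, `t`, and the
#'   outcome.
#' @param outcome Name of the outcome column (default `"y"`).
#' @return The panel, sorted, with an added `lag_<outcome>` column. The
#'   column remembers its source so that centering functions know to use
#'   the full-series cluster mean of the outcome.
#' @examples
#' p <- tibble::tibble(cluster = 1, t = 1:3, y = c(1, 2, 3))
#' build_lag(p)
#' @export
build_lag <- function(panel, outcome = "y") {
  stopifnot(outcome %in% names(panel))
  out <- dplyr::arrange(panel, .data$cluster, .data$t)
  counts <- dplyr::count(out, .data$cluster)
  if (any(counts$n < 2)) {
    stop("every cluster needs at least 2 occasions to build a lag",
         call. = FALSE)
  }
  chk <- dplyr::summarise(dplyr::group_by(out, .data$cluster),
                          ok = all(diff(.data$t) == 1), .groups = "drop")
  if (!all(chk$ok)) {
    stop("occasions must be consecutive within each cluster", call. = FALSE)
  }
  lag_col <- paste0("lag_", outcome)
  out <- dplyr::mutate(dplyr::group_by(out, .data$cluster),
                       !!lag_col := dplyr::lag(.data[[outcome]]))
  out <- dplyr::ungroup(out)
  attr(out, "lag_of") <- stats::setNames(outcome, lag_col)
  for (a in c("truth", "design", "seed")) {
    attr(out, a) <- attr(panel, a)
  }
  out
}

# Source column whose cluster means define the CMC constant for `predictor`:
# the lagged outcome is centered at the full-series outcome mean.
centering_source <- function(panel, predictor) {
  lag_of <- attr(panel, "lag_of")
  if (!is.null(lag_of) && predictor %in% names(lag_of)) {
    unname(lag_of[predictor])
  } else {
    predictor
  }
}

#' Apply a centering scheme to a level-1 predictor
#'
#' Adds `<predictor>_c`, the predictor after centering, and records the
#' per-cluster centering constant. Under `"NC"` the constant is 0; under
#' `"GMC"` it is the pooled mean of the predictor over analysis (non-`NA`)
#' rows; under the CMC variants it is the cluster's sample mean,
#' empirical-Bayes mean, or true generating mean of the *source* column
#' (the outcome itself when the predictor is a lagged outcome, computed
#' over all T observations).
#'
#' @param panel A panel, typically after [build_lag()].
#' @param predictor Name of the level-1 predictor column to center.
#' @param scheme One of [centering_schemes].
#' @param truth Optional per-cluster truth for `"CMC_true"`: a data frame
#'   with columns `cluster` and `mu_true` (or `xbar`). Defaults to the
#'   panel's own [cluster_truth()].
#' @return The panel with an added `<predictor>_c` column; the scheme and
#'   a per-cluster tibble of centering constants are stored in the
#'   `"centering"` attribute (see [centering_info()]).
#' @examples
#' p <- build_lag(simulate_ar(ar_design(n_clusters = 4), seed = 1))
#' pc <- apply_centering(p, "lag_y", "CMC_sample")
#' centering_info(pc)
#' @export
apply_centering <- function(panel, predictor = "lag_y", scheme = "NC",
                            truth = NULL) {
  scheme <- match.arg(scheme, centering_schemes)
  stopifnot(predictor %in% names(panel))
  src <- centering_source(panel, predictor)
  cl <- sort(unique(panel$cluster))
  if (scheme == "NC") {
    centers <- tibble::tibble(cluster = cl, center = 0)
  } else if (scheme == "GMC") {
    g <- mean(panel[[predictor]], na.rm = TRUE)
    centers <- tibble::tibble(cluster = cl, center = g)
  } else if (scheme == "CMC_sample") {
    centers <- dplyr::summarise(
      dplyr::group_by(panel, .data$cluster),
      center = mean(.data[[src]]), .groups = "drop")
  } else if (scheme == "CMC_eb") {
    ef <- fit_empty(panel, outcome = src)
    if (!ef$converged) {
      stop("empty model for empirical-Bayes means did not converge",
           call. = FALSE)
    }
    centers <- tibble::tibble(cluster = ef$eb$cluster, center = ef$eb$mu_hat)
  } else { # CMC_true
    if (is.null(truth)) truth <- cluster_truth(panel)
    if (is.null(truth)) {
      stop("CMC_true requires generating truth (per-cluster means)",
           call. = FALSE)
    }
    mu_col <- intersect(c("mu_true", "xbar"), names(truth))[1]
    if (is.na(mu_col)) stop("truth must contain `mu_true` or `xbar`",
                            call. = FALSE)
    centers <- tibble::tibble(cluster = truth$cluster,
                              center = truth[[mu_col]])
  }
  out <- dplyr::left_join(panel, dplyr::rename(centers, ..ctr = "center"),
                          by = "cluster")
  cc <- paste0(predictor, "_c")
  out[[cc]] <- out[[predictor]] - out$..ctr
  out$..ctr <- NULL
  for (a in c("truth", "design", "seed", "lag_of")) {
    attr(out, a) <- attr(panel, a)
  }
  attr(out, "centering") <- list(scheme = scheme, predictor = predictor,
                                 centered = cc, centers = centers)
  out
}

#' Centering metadata of a centered panel
#'
#' @param panel A panel returned by [apply_centering()].
#' @return A list with elements `scheme`, `predictor`, `centered` (the
#'   name of the centered column) and `centers` (per-cluster constants).
#' @export
centering_info <- function(panel) attr(panel, "centering")
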