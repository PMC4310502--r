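#' Read and write panels as plain CSV
#'
#' Panels are serialized as long-format CSV with header
#' `cluster,t,y[,x][,z]`; simulated panels get a companion truth file
#' (`cluster,mu_true,phi_true,...`) next to the panel, suffixed
#' `_truth.csv`, plus a small JSON metadata sidecar (suffixed
#' `_meta.json`) recording the design and seed so the file can be
#' regenerated exactly.
#'
#' A centered panel (from [apply_centering()]) keeps its `<predictor>_c`
#' column and gets a `_centering.json` sidecar with the scheme and the
#' per-cluster centering constants.
#'
#' @param panel A panel tibble.
#' @param path Output CSV path.
#' @return `write_panel()` returns the paths written, invisibly;
#'   `read_panel()` returns the panel with any truth and centering
#'   metadata re-attached.
#' @export
write_panel <- function(panel, path) {
  info <- centering_info(panel)
  keep_extra <- if (is.null(info)) character() else info$centered
  drop <- grepl("_c$|^lag_", names(panel)) &
    !names(panel) %in% c("cluster", "t", "y", "x", "z", keep_extra)
  readr::write_csv(panel[, !drop, drop = FALSE], path)
  paths <- path
  if (!is.null(info)) {
    cp <- sub("\\.csv$", "_centering.json", path)
    jsonlite::write_json(info, cp, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    paths <- c(paths, cp)
  }
  truth <- cluster_truth(panel)
  if (!is.null(truth)) {
    tp <- sub("\\.csv$", "_truth.csv", path)
    readr::write_csv(truth, tp)
    paths <- c(paths, tp)
  }
  design <- attr(panel, "design")
  if (!is.null(design)) {
    mp <- sub("\\.csv$", "_meta.json", path)
    meta <- list(design_class = class(design)[1],
                 design = unclass(design), seed = attr(panel, "seed"))
    jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA,
                         null = "null")
    paths <- c(paths, mp)
  }
  invisible(paths)
}

#' @rdname write_panel
#' @param truth_path Optional truth CSV; defaults to the `_truth.csv`
#'   sidecar if it exists.
#' @export
read_panel <- function(path, truth_path = NULL) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("cluster", "t", "y")
  if (!all(need %in% names(tbl))) {
    stop("panel CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(truth_path)) {
    cand <- sub("\\.csv$", "_truth.csv", path)
    if (file.exists(cand)) truth_path <- cand
  }
  truth <- if (!is.null(truth_path)) {
    readr::read_csv(truth_path, show_col_types = FALSE)
  } else NULL
  out <- new_panel(tibble::as_tibble(tbl), truth, NULL, NULL)
  cp <- sub("\\.csv$", "_centering.json", path)
  if (file.exists(cp)) {
    info <- jsonlite::read_json(cp, simplifyVector = TRUE)
    info$centers <- tibble::as_tibble(info$centers)
    attr(out, "centering") <- info
  }
  out
}

design_fields <- list(
  standard_design = c("gamma00", "gamma10", "gamma01", "sd_slope",
                      "var_u0", "var_e", "var_x_within", "var_xbar",
                      "n_clusters", "n_per_cluster"),
  ar_design = c("grand_mean", "phi_mean", "sd_phi", "var_mu", "var_e",
                "cov_mu_phi", "n_clusters", "n_per_cluster"),
  ar_design_z = c("grand_mean", "phi_mean", "var_z", "gamma01_z",
                  "gamma11_z", "resid_var_mu", "resid_var_phi", "var_e",
                  "n_clusters", "n_per_cluster")
)

#' Read a simulation design from a YAML or JSON config file
#'
#' The file holds one flat mapping whose keys are the arguments of
#' [standard_design()], [ar_design()] or [ar_design_z()]; the
#' constructor is chosen with the mandatory `design` key
#' (`"standard"`, `"ar"` or `"ar_z"`). Unknown keys are an error, so
#' typos cannot silently fall back to defaults.
#'
#' @param path A `.json`, `.yml` or `.yaml` file.
#' @return A validated design object.
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeLines('{"design": "ar", "phi_mean": 0.3, "n_clusters": 10}', f)
#' read_design(f)
#' @export
read_design <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$design)) {
    stop("config must have a `design` key (standard | ar | ar_z)",
         call. = FALSE)
  }
  kind <- match.arg(cfg$design, c("standard", "ar", "ar_z"))
  ctor <- switch(kind, standard = "standard_design", ar = "ar_design",
                 ar_z = "ar_design_z")
  cfg$design <- NULL
  unknown <- setdiff(names(cfg), design_fields[[ctor]])
  if (length(unknown)) {
    stop("unknown design key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(ctor, cfg)
}

#' Serialize a fitted model to JSON
#'
#' Writes the fixed effects (estimates, standard errors, Wald intervals),
#' variance components, criterion value and flags of an [fit_lmm()]
#' result as a JSON object.
#'
#' @param fit An `inertia_fit`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "inertia_fit"))
  obj <- list(fixed = fit$fixed,
              random = list(var_u0 = fit$var_u0, var_u1 = fit$var_u1,
                            cov_u01 = fit$cov_u01,
                            sigma2_e = fit$sigma2_e),
              logLik = fit$logLik, criterion = fit$criterion,
              converged = fit$converged, singular = fit$singular,
              singular_fallback = fit$singular_fallback,
              scheme = fit$scheme, predictor = fit$predictor,
              n_clusters = fit$n_clusters, n_rows = fit$n_rows)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  invisible(path)
}

#' Write a Monte-Carlo summary as CSV with a metadata header
#'
#' The first line is a `#`-prefixed JSON object with the base seed,
#' replication count and estimation criterion; the remainder is ordinary
#' CSV (readable with `readr::read_csv(path, comment = "#")`).
#'
#' @param mc An `inertia_mc` summary.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mc_csv <- function(mc, path) {
  meta <- list(base_seed = attr(mc, "base_seed"),
               reml = attr(mc, "reml"),
               package_version = as.character(utils::packageVersion("inertia")))
  header <- paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                          null = "null"))
  writeLines(header, path)
  readr::write_csv(as.data.frame(mc), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}
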