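# Small designs reused across tests.

tiny_ar <- function(...) {
  ar_design(n_clusters = 20, n_per_cluster = 10, ...)
}

# Per-cluster loop oracle for the lag construction: independent of the
# vectorised implementation in build_lag().
lag_oracle <- function(panel, outcome = "y") {
  panel <- panel[order(panel$cluster, panel$t), ]
  out <- lapply(split(panel, panel$cluster), function(d) {
    d[[paste0("lag_", outcome)]] <- c(NA, d[[outcome]][-nrow(d)])
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  tibble::as_tibble(res)
}
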