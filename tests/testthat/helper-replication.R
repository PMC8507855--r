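# The synthetic replication of the comparison experiment is expensive
# (two-year series, trained networks), so the acceptance tests share one
# cached run: the comparison at the 30-day gap and the 30/60-day cross-gap
# protocol, both at the study conditions (default generator, s = 14,
# hidden 64, <= 200 epochs with early stopping, fixed seed).

replication_env <- new.env(parent = emptyenv())

replication_comparison <- function() {
  if (is.null(replication_env$cmp)) {
    replication_env$cmp <- suppressWarnings(run_comparison(
      scenario_config(gap_days = 30L),
      methods = c("bilstm_i", "kalman_struct", "kalman_arima",
                  "climatology", "linear"),
      seeds = 1L))
  }
  replication_env$cmp
}

replication_cross_gap <- function() {
  if (is.null(replication_env$cross)) {
    replication_env$cross <- suppressWarnings(run_cross_gap(
      scenario_config(gap_days = c(30L, 60L)), seed = 1L))
  }
  replication_env$cross
}
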