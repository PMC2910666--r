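summary_schema_version <- "1.0"

# Shortest decimal representation that round-trips to the same double.
fmt_full <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)

#' Write a trajectory as CSV
#'
#' One row per sample with header `t,N,T,u,kill_N,kill_T` (populations in
#' cells, `u` the drug level, `kill_*` the per-capita kill rates). Numbers
#' are written at full precision, so re-reading the file reproduces the
#' sampled trajectory exactly; output is deterministic for a fixed
#' trajectory.
#'
#' @param traj A [simulate_model()] trajectory.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_timeseries()]
#' @export
write_timeseries <- function(traj, path) {
  stopifnot(inherits(traj, "conjoint_trajectory"))
  df <- data.frame(t = fmt_full(traj$times), N = fmt_full(traj$N),
                   `T` = fmt_full(traj$T), u = fmt_full(traj$u),
                   kill_N = fmt_full(traj$kill_N),
                   kill_T = fmt_full(traj$kill_T), check.names = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a trajectory CSV back as a data.frame
#'
#' @param path Path written by [write_timeseries()].
#' @return data.frame with numeric columns `t, N, T, u, kill_N, kill_T`.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "numeric")
  expected <- c("t", "N", "T", "u", "kill_N", "kill_T")
  if (!identical(names(df), expected))
    stop(sprintf("unexpected columns in %s", path), call. = FALSE)
  df
}

#' Write a scenario summary as JSON
#'
#' Versioned JSON document with the scenario's derived metrics and its
#' fully resolved configuration. `tcrit_crossing` and `inhibition_delay`
#' are `null` when undefined (threshold never reached; no untreated twin);
#' an inhibition delay censored at the simulation horizon is written as the
#' string `"censored"`.
#'
#' @param result A [run_scenario()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary <- function(result, path) {
  stopifnot(inherits(result, "conjoint_scenario"))
  delay <- result$inhibition_delay
  doc <- list(
    schema_version = summary_schema_version,
    preset = result$name,
    metrics = list(
      tcrit_crossing = if (is.na(result$tcrit_crossing)) NULL else result$tcrit_crossing,
      normal_peak_time = result$normal_peak$time,
      normal_peak_value = result$normal_peak$value,
      terminal_N = unname(result$terminal["N"]),
      terminal_T = unname(result$terminal["T"]),
      inhibition_delay = if (is.na(delay)) NULL
                         else if (is.infinite(delay)) "censored" else delay),
    config = result$config)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
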