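# Tabular reporting. One formatting path: the summary tibble produced by
# cua_summary() is what gets printed and what gets written to CSV, so
# console and file can never disagree.

#' Cost-utility summary table
#'
#' The conventional results-table layout: one row per strategy with
#' discounted lifetime cost and QALYs, and the incremental block (delta
#' cost, delta QALYs, ICER or dominance classification) on the comparator
#' row. Currency is rounded to 2 decimal places and QALYs to 3 for display;
#' internal arithmetic is full precision.
#'
#' @param result A `cea_result` from [run_cua()] or [incremental()].
#' @return A `cea_summary` tibble.
#' @examples
#' cua_summary(run_cua(als_edaravone_spec()))
#' @export
cua_summary <- function(result) {
  td <- tidy(result)
  out <- dplyr::mutate(
    td,
    cost = round(.data$cost, 2),
    qaly = round(.data$qaly, 3),
    delta_cost = round(.data$delta_cost, 2),
    delta_qaly = round(.data$delta_qaly, 3),
    icer = round(.data$icer, 2)
  )
  attr(out, "currency") <- result$currency %||% ""
  class(out) <- c("cea_summary", class(out))
  out
}

#' @export
print.cea_summary <- function(x, ...) {
  cur <- attr(x, "currency")
  if (nzchar(cur %||% "")) cat("costs in", cur, "\n")
  NextMethod()
}

#' Export deterministic CUA artifacts to CSV
#'
#' Writes `summary.csv` (the [cua_summary()] table) and `trace.csv` (the
#' cohort trace via [export_trace()]) into a directory. Outputs are pure
#' functions of the model specification, so regeneration is byte-identical.
#'
#' @param result A `cea_result` from [run_cua()] (must carry its trace).
#' @param dir Output directory (created if needed).
#' @return The file paths, invisibly.
#' @export
export_cua <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summary_path <- file.path(dir, "summary.csv")
  trace_path <- file.path(dir, "trace.csv")
  readr::write_csv(as_tibble(cua_summary(result)), summary_path)
  trace <- attr(result, "trace")
  if (is.null(trace)) stop("result carries no trace; build it with run_cua()")
  export_trace(trace, trace_path)
  invisible(c(summary_path, trace_path))
}
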