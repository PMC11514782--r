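#' Incremental cost-effectiveness analysis of two valued arms
#'
#' Computes incremental cost and QALYs (comparator minus reference), the
#' ICER, the dominance classification, and net monetary benefit at a
#' willingness-to-pay threshold. The ICER is reported only in the trade-off
#' quadrants; a dominant or dominated comparator prints its classification
#' instead (the ratio is not informative there). A QALY difference below
#' 1e-12 in magnitude makes the ICER an undefined flag (`NA`), never a
#' division blow-up.
#'
#' @param comparator,reference `cea_arm_valuation` objects from the same
#'   model horizon.
#' @param wtp Willingness to pay per QALY; the default is 3 x the 2023
#'   Chinese per-capita GDP of 89,358 CNY (an external benchmark constant).
#' @return A `cea_result` with `delta_cost`, `delta_qaly`, `icer`,
#'   `dominance` (`"dominant"`, `"dominated"`, or `"tradeoff"`), and `nmb`
#'   at `wtp`.
#' @examples
#' spec <- als_edaravone_spec()
#' tr <- run_trace(spec)
#' incremental(value_arm(tr, spec$arms$comparator, spec),
#'             value_arm(tr, spec$arms$reference, spec))
#' @export
incremental <- function(comparator, reference, wtp = .default_wtp) {
  dc <- comparator$total_cost - reference$total_cost
  dq <- comparator$total_qaly - reference$total_qaly
  dominance <- if (dc < 0 && dq > 0) "dominant"
    else if (dc > 0 && dq < 0) "dominated"
    else "tradeoff"
  icer <- if (abs(dq) < 1e-12 || dominance != "tradeoff") NA_real_ else dc / dq
  structure(
    list(
      comparator = comparator, reference = reference,
      delta_cost = dc, delta_qaly = dq,
      icer = icer, dominance = dominance,
      wtp = wtp, nmb = wtp * dq - dc
    ),
    class = "cea_result"
  )
}

#' Net monetary benefit of a CEA result
#'
#' `wtp x delta_qaly - delta_cost`, positive iff the comparator is
#' cost-effective at that threshold. Affine and strictly increasing in
#' `wtp` whenever `delta_qaly > 0`, with its unique root at the ICER.
#'
#' @param result A `cea_result`.
#' @param wtp Willingness to pay per QALY (vectorized, >= 0).
#' @export
net_monetary_benefit <- function(result, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0")
  wtp * result$delta_qaly - result$delta_cost
}

#' Run the full cost-utility analysis of a model
#'
#' Convenience pipeline: cohort trace, valuation of both arms, incremental
#' analysis. This is the main entry point for a deterministic (base-case or
#' scenario) analysis.
#'
#' @param spec A validated `cea_model_spec`.
#' @param wtp Willingness-to-pay threshold passed to [incremental()].
#' @return A `cea_result` (see [incremental()]); the underlying trace is
#'   attached as attribute `"trace"`.
#' @examples
#' run_cua(als_edaravone_spec())
#' @export
run_cua <- function(spec, wtp = .default_wtp) {
  trace <- run_trace(spec)
  res <- incremental(
    comparator = value_arm(trace, spec$arms$comparator, spec),
    reference = value_arm(trace, spec$arms$reference, spec),
    wtp = wtp
  )
  res$model_name <- spec$name
  res$currency <- spec$currency
  attr(res, "trace") <- trace
  res
}

#' @export
print.cea_result <- function(x, ...) {
  cur <- x$currency %||% ""
  cat("<cea_result>", if (!is.null(x$model_name)) x$model_name else "", "\n")
  cat(sprintf("  %-12s cost %14.2f   QALYs %7.3f\n",
              x$comparator$arm_name, x$comparator$total_cost, x$comparator$total_qaly))
  cat(sprintf("  %-12s cost %14.2f   QALYs %7.3f\n",
              x$reference$arm_name, x$reference$total_cost, x$reference$total_qaly))
  cat(sprintf("  incremental: %.2f %s, %.3f QALYs\n", x$delta_cost, cur, x$delta_qaly))
  if (x$dominance == "tradeoff" && !is.na(x$icer)) {
    cat(sprintf("  ICER: %.2f %s/QALY\n", x$icer, cur))
  } else {
    cat("  comparator is", x$dominance, "\n")
  }
  cat(sprintf("  NMB at WTP %.0f: %.2f\n", x$wtp, x$nmb))
  invisible(x)
}

#' @describeIn incremental Tidy summary table, one row per arm with the
#'   incremental block on the comparator row (the conventional layout of
#'   cost-utility results tables).
#' @param x A `cea_result`.
#' @param ... Unused.
#' @method tidy cea_result
#' @export
tidy.cea_result <- function(x, ...) {
  tibble(
    group = c(x$comparator$arm_name, x$reference$arm_name),
    cost = c(x$comparator$total_cost, x$reference$total_cost),
    qaly = c(x$comparator$total_qaly, x$reference$total_qaly),
    delta_cost = c(x$delta_cost, NA),
    delta_qaly = c(x$delta_qaly, NA),
    icer = c(x$icer, NA),
    dominance = c(x$dominance, NA)
  )
}

#' @method glance cea_result
#' @export
glance.cea_result <- function(x, ...) {
  tibble(
    delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
    icer = x$icer, dominance = x$dominance,
    wtp = x$wtp, nmb = x$nmb
  )
}
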