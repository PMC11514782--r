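#' Deterministic perturbation range for one parameter
#'
#' Cost parameters are varied by +/- `cost_fraction` (default 20%), effect
#' parameters (transition probabilities, health utilities) by +/-
#' `effect_fraction` (default 10%). Parameters constrained to \[0, 1\] are
#' clamped after perturbation: values exceeding 1 are set to 1. The discount
#' rate uses an absolute policy window (0 to `discount_range[2]`, default
#' 8%), shrunk proportionally when `effect_fraction` is reduced so that zero
#' fractions always reproduce the base value.
#'
#' @param base_value Base-case value (finite).
#' @param kind `"cost"`, `"effect"`, or `"discount"`.
#' @param clamp_unit Clamp the range to \[0, 1\]?
#' @param cost_fraction,effect_fraction Relative perturbation sizes.
#' @param discount_range Absolute window for `kind = "discount"`.
#' @return `c(low, high)`.
#' @examples
#' perturbation_range(2600, "cost") # 2080, 3120
#' perturbation_range(0.95, "effect", clamp_unit = TRUE) # high clamped to 1
#' @export
perturbation_range <- function(base_value,
                               kind = c("cost", "effect", "discount"),
                               clamp_unit = FALSE,
                               cost_fraction = 0.2, effect_fraction = 0.1,
                               discount_range = c(0, 0.08)) {
  kind <- match.arg(kind)
  if (!is.finite(base_value)) stop("base_value must be finite")
  r <- switch(kind,
    cost = base_value * c(1 - cost_fraction, 1 + cost_fraction),
    effect = base_value * c(1 - effect_fraction, 1 + effect_fraction),
    discount = {
      scale <- min(effect_fraction / 0.1, 1)
      base_value + scale * (discount_range - base_value)
    }
  )
  if (clamp_unit) r <- pmin(1, pmax(0, r))
  sort(r)
}

owsa_outcome <- function(spec, id, value, wtp) {
  set <- spec_set_param(spec, id, value)
  if (!set$feasible) {
    return(tibble(feasible = FALSE, icer = NA_real_, nmb = NA_real_,
                  delta_cost = NA_real_, delta_qaly = NA_real_))
  }
  ok <- tryCatch({ validate_model_spec(set$spec); TRUE },
                 error = function(e) FALSE)
  if (!ok) {
    return(tibble(feasible = FALSE, icer = NA_real_, nmb = NA_real_,
                  delta_cost = NA_real_, delta_qaly = NA_real_))
  }
  r <- run_cua(set$spec, wtp = wtp)
  tibble(feasible = TRUE, icer = r$icer, nmb = r$nmb,
         delta_cost = r$delta_cost, delta_qaly = r$delta_qaly)
}

#' One-way deterministic sensitivity analysis
#'
#' Rebuilds the model with one parameter at a time set to the low and high
#' end of its [perturbation_range()], reruns the full trace-valuation-
#' incremental pipeline, and records the ICER and net monetary benefit under
#' each. Transition perturbations are absorbed by the same-state (diagonal)
#' entry so rows stay stochastic; a perturbation that would drive the
#' diagonal negative (or otherwise break a model invariant) is flagged
#' infeasible, never silently renormalized.
#'
#' Items are sorted by descending `span`, the absolute NMB swing. NMB is
#' used as the tornado ordering metric because ICER ordering is unstable
#' when the QALY difference changes sign inside a range; both outcomes are
#' reported.
#'
#' @param spec A validated `cea_model_spec`.
#' @param parameters Parameter universe, default [spec_parameters()];
#'   a tibble with `parameter_id`, `kind`, `base_value`, `clamp_unit`.
#' @param wtp Willingness-to-pay threshold for NMB.
#' @param cost_fraction,effect_fraction Perturbation sizes (see
#'   [perturbation_range()]).
#' @return A `cea_owsa` tibble, one row per parameter, with the base-case
#'   `cea_result` attached as attribute `"base"`.
#' @examples
#' ow <- run_owsa(als_edaravone_spec())
#' head(ow, 3)
#' @export
run_owsa <- function(spec, parameters = spec_parameters(spec),
                     wtp = .default_wtp,
                     cost_fraction = 0.2, effect_fraction = 0.1) {
  base <- run_cua(spec, wtp = wtp)
  out <- purrr::pmap_dfr(
    parameters,
    function(parameter_id, kind, base_value, clamp_unit) {
      rng <- perturbation_range(base_value, kind, clamp_unit,
                                cost_fraction, effect_fraction)
      lo <- owsa_outcome(spec, parameter_id, rng[1], wtp)
      hi <- owsa_outcome(spec, parameter_id, rng[2], wtp)
      tibble(
        parameter_id = parameter_id, kind = kind, base_value = base_value,
        low_value = rng[1], high_value = rng[2],
        feasible = lo$feasible && hi$feasible,
        icer_low = lo$icer, icer_high = hi$icer,
        nmb_low = lo$nmb, nmb_high = hi$nmb,
        delta_cost_low = lo$delta_cost, delta_cost_high = hi$delta_cost,
        delta_qaly_low = lo$delta_qaly, delta_qaly_high = hi$delta_qaly,
        span = abs(hi$nmb - lo$nmb)
      )
    }
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$span))
  attr(out, "base") <- base
  attr(out, "wtp") <- wtp
  class(out) <- c("cea_owsa", class(out))
  out
}

#' @method tidy cea_owsa
#' @export
tidy.cea_owsa <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cea_owsa")
  attr(out, "base") <- NULL
  attr(out, "wtp") <- NULL
  out
}

#' Tornado diagram of a one-way sensitivity analysis
#'
#' Horizontal bars span the net monetary benefit reached at the low and high
#' end of each parameter's range, ordered by impact; the vertical line marks
#' the base-case NMB.
#'
#' @param object A `cea_owsa` from [run_owsa()].
#' @param n_top Number of parameters shown.
#' @param ... Unused.
#' @method autoplot cea_owsa
#' @export
autoplot.cea_owsa <- function(object, n_top = 12, ...) {
  base_nmb <- attr(object, "base")$nmb
  df <- tidy(object) |>
    dplyr::filter(.data$feasible) |>
    dplyr::slice_head(n = n_top) |>
    dplyr::mutate(parameter_id = factor(.data$parameter_id,
                                        levels = rev(.data$parameter_id)))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter_id)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$nmb_low, xend = .data$nmb_high,
                   yend = .data$parameter_id),
      linewidth = 4, colour = "steelblue"
    ) +
    ggplot2::geom_vline(xintercept = base_nmb, linetype = 2) +
    ggplot2::labs(x = "Net monetary benefit", y = NULL) +
    ggplot2::theme_minimal()
}

#' Export a tornado table to CSV
#'
#' @param owsa A `cea_owsa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_owsa <- function(owsa, path) {
  readr::write_csv(tidy(owsa), path)
  invisible(path)
}
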