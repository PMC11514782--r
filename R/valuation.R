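#' Cost of one treatment course
#'
#' Drug acquisition (administration days x doses/day x unit price) plus
#' per-course device maintenance plus the amortized share of annually
#' replaced devices (insertion cost x insertions/year divided by the yearly
#' course count).
#'
#' @param schedule A [treatment_schedule()].
#' @param costs A [cost_model()].
#' @param first `TRUE` for the initial course (more administration days).
#' @return Currency per course.
#' @examples
#' # sublingual arm of the bundled model: 10 x 2 x 130 = 2600 per course
#' arm <- als_edaravone_spec()$arms$comparator
#' course_cost(arm$schedule, arm$costs)
#' @export
course_cost <- function(schedule, costs, first = FALSE) {
  admin_days <- if (first) schedule$first_course_admin_days else
    schedule$subsequent_course_admin_days
  admin_days * schedule$doses_per_day * costs$unit_drug_price +
    costs$maintenance_events_per_course * costs$device_maintenance_cost +
    costs$device_insertion_cost * costs$device_insertions_per_year /
      schedule$courses_per_year_for_amortization
}

#' Expected adverse-event cost per course
#'
#' Probability-weighted sum of event treatment costs.
#'
#' @param profile An [adverse_event_profile()].
#' @return Currency per course.
#' @export
expected_ae_cost <- function(profile) {
  ev <- profile$events
  if (!nrow(ev)) return(0)
  sum(ev$probability * ev$cost)
}

#' Productivity loss per care visit
#'
#' `employment_rate x hours_lost_per_visit x hourly_wage`: the expected wage
#' loss a single care encounter causes the (partially employed) cohort.
#'
#' @param params An [indirect_cost_params()].
#' @return Currency per visit.
#' @export
indirect_cost_per_visit <- function(params) {
  params$employment_rate * params$hours_lost_per_visit * params$hourly_wage
}

#' Per-cycle treatment cost of an arm
#'
#' The steady-state cost per alive cohort member per cycle:
#' `courses_per_cycle x (subsequent course cost + expected AE cost +
#' visit-derived productivity and transport costs per course)`. The
#' first-course premium (first minus subsequent course cost) is added once,
#' in cycle 1, reflecting that the initial course happens exactly once per
#' patient. Treatment continues for every living patient over the whole
#' horizon (no stopping rule).
#'
#' @param arm An [arm_spec()].
#' @param cycle_index Cycle number(s), 1-based; vectorized.
#' @return Currency per alive cohort member for each requested cycle.
#' @export
cycle_cost <- function(arm, cycle_index) {
  sch <- arm$schedule
  cm <- arm$costs
  vp <- cm$visit_policy
  per_course <- course_cost(sch, cm) +
    expected_ae_cost(cm$ae_profile) +
    vp$productivity_visits_per_course * indirect_cost_per_visit(cm$indirect) +
    vp$transport_visits_per_course * cm$transport_cost_per_visit
  premium <- course_cost(sch, cm, first = TRUE) - course_cost(sch, cm)
  sch$courses_per_cycle * per_course + ifelse(cycle_index == 1L, premium, 0)
}

#' Utility weight of a state under an arm
#'
#' The stage utility, multiplied by the comparator adjustment coefficient
#' when the arm is the comparator. The absorbing (death) state contributes
#' zero.
#'
#' @param state State label.
#' @param arm An [arm_spec()].
#' @param utilities A [utility_model()].
#' @param absorbing_state Label of the absorbing state.
#' @export
arm_utility <- function(state, arm, utilities, absorbing_state = "death") {
  if (identical(state, absorbing_state)) return(0)
  if (!state %in% names(utilities$stage_utilities)) {
    stop("unknown state label: '", state, "'")
  }
  u <- utilities$stage_utilities[[state]]
  if (arm$role == "comparator") u * utilities$comparator_adjustment_coefficient else u
}

arm_utility_vector <- function(spec, arm) {
  u <- c(spec$utilities$stage_utilities, 0)
  names(u) <- spec$states
  if (arm$role == "comparator") {
    u <- u * spec$utilities$comparator_adjustment_coefficient
  }
  u
}

#' Value an arm over a cohort trace
#'
#' Accumulates discounted lifetime cost and QALYs. Both accrue on half-cycle
#' corrected person-time for internal consistency: for cycle k,
#' \deqn{QALY_k = \sum_{s\ living} \bar{o}_k(s)\, u_a(s)\, L\, w_k, \qquad
#'       Cost_k = \Big(\sum_{s\ living} \bar{o}_k(s)\Big)\, c_a(k)\, w_k,}
#' with corrected occupancy \eqn{\bar o}, arm utility \eqn{u_a}, cycle
#' length \eqn{L} years, per-cycle cost \eqn{c_a(k)} ([cycle_cost()]) and
#' discount weight \eqn{w_k} ([discount_factor()]).
#'
#' @param trace The `cea_trace` computed from `spec` (or an empirical trace
#'   from [microsimulate()]).
#' @param arm One of `spec$arms`.
#' @param spec The `cea_model_spec` the trace came from.
#' @return A `cea_arm_valuation`: `total_cost`, `total_qaly`, and a
#'   `per_cycle` tibble (cycle, alive person-time, discounted cost and QALY
#'   contributions).
#' @examples
#' spec <- als_edaravone_spec()
#' value_arm(run_trace(spec), spec$arms$reference, spec)
#' @export
value_arm <- function(trace, arm, spec) {
  n <- trace$n_cycles
  k <- seq_len(n)
  living <- seq_len(length(spec$states) - 1L)
  w <- discount_factor(k, spec$discount_rate_annual, spec$cycle_length_years,
                       from = spec$discount_from)
  u <- arm_utility_vector(spec, arm)
  qaly_k <- as.numeric(trace$corrected_occupancy %*% u) *
    spec$cycle_length_years * w
  alive_k <- rowSums(trace$corrected_occupancy[, living, drop = FALSE])
  cost_k <- alive_k * cycle_cost(arm, k) * w
  structure(
    list(
      arm_name = arm$name,
      role = arm$role,
      total_cost = sum(cost_k),
      total_qaly = sum(qaly_k),
      per_cycle = tibble(cycle = k, alive = unname(alive_k),
                         cost = unname(cost_k), qaly = unname(qaly_k))
    ),
    class = "cea_arm_valuation"
  )
}

#' @export
print.cea_arm_valuation <- function(x, ...) {
  cat(sprintf("<cea_arm_valuation> %s (%s): cost %.2f, QALYs %.4f\n",
              x$arm_name, x$role, x$total_cost, x$total_qaly))
  invisible(x)
}

#' @method tidy cea_arm_valuation
#' @export
tidy.cea_arm_valuation <- function(x, ...) x$per_cycle

#' @method glance cea_arm_valuation
#' @export
glance.cea_arm_valuation <- function(x, ...) {
  tibble(arm = x$arm_name, role = x$role,
         total_cost = x$total_cost, total_qaly = x$total_qaly)
}
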