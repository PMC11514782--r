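#' Build a transition matrix from a printed table
#'
#' Published transition tables are printed in one of two orientations: rows
#' index the from-state (row-stochastic) or columns index the from-state
#' (column-stochastic). The engine's canonical convention is row-stochastic,
#' so a column-oriented table is transposed on load. Orientation is always
#' explicit: a silently mis-oriented kernel is the classic way to wreck a
#' cohort model.
#'
#' @param raw_table Square numeric matrix of per-cycle transition
#'   probabilities, as printed.
#' @param orientation `"rows-are-from"` (already row-stochastic) or
#'   `"columns-are-from"` (transpose on load).
#' @param state_names Optional character vector of state labels; defaults to
#'   existing dimnames or `s1..sK`.
#' @return A row-stochastic matrix with state dimnames, class
#'   `cea_transition`.
#' @examples
#' raw <- matrix(c(0.9, 0, 0.1, 1), 2, 2) # columns sum to 1
#' orient_transition_table(t(raw), "columns-are-from")
#' @export
orient_transition_table <- function(raw_table,
                                    orientation = c("rows-are-from", "columns-are-from"),
                                    state_names = NULL) {
  orientation <- match.arg(orientation)
  raw_table <- as.matrix(raw_table)
  if (nrow(raw_table) != ncol(raw_table)) {
    stop("transition table must be square, got ", nrow(raw_table), " x ", ncol(raw_table))
  }
  if (any(raw_table < 0 | raw_table > 1)) {
    stop("transition probabilities must lie in [0, 1]")
  }
  mat <- if (orientation == "columns-are-from") t(raw_table) else raw_table
  rs <- rowSums(mat)
  if (any(abs(rs - 1) > 1e-9)) {
    stop(
      "matrix is not row-stochastic under orientation '", orientation, "': ",
      "row sums (from-state) = [", paste(format(rowSums(mat), digits = 10), collapse = ", "),
      "], column sums = [", paste(format(colSums(mat), digits = 10), collapse = ", "), "]"
    )
  }
  state_names <- state_names %||% rownames(mat) %||% paste0("s", seq_len(nrow(mat)))
  dimnames(mat) <- list(from = state_names, to = state_names)
  class(mat) <- c("cea_transition", class(mat))
  mat
}

#' Treatment schedule for a strategy arm
#'
#' Describes the periodic course structure of a therapy: how many days of
#' administration a course contains (first course vs subsequent courses),
#' doses per administration day, how many courses fall in one model cycle,
#' and the yearly course count used to amortize annually replaced devices.
#'
#' @param course_length_days Calendar length of one course (administration
#'   plus drug-free period), days.
#' @param first_course_admin_days,subsequent_course_admin_days Administration
#'   days in the first and in every later course.
#' @param doses_per_day Doses taken on each administration day.
#' @param courses_per_cycle Courses accrued per model cycle (positive real;
#'   default one 28-day course per 112/365 of a year, i.e. 365/112 per
#'   quarterly cycle).
#' @param courses_per_year_for_amortization Divisor spreading once-a-year
#'   device costs over courses.
#' @export
treatment_schedule <- function(course_length_days = 28,
                               first_course_admin_days = 14,
                               subsequent_course_admin_days = 10,
                               doses_per_day = 2,
                               courses_per_cycle = 365 / (4 * 28),
                               courses_per_year_for_amortization = 13) {
  out <- list(
    course_length_days = course_length_days,
    first_course_admin_days = first_course_admin_days,
    subsequent_course_admin_days = subsequent_course_admin_days,
    doses_per_day = doses_per_day,
    courses_per_cycle = courses_per_cycle,
    courses_per_year_for_amortization = courses_per_year_for_amortization
  )
  structure(out, class = "cea_schedule")
}

#' Adverse-event profile
#'
#' @param events Data frame (or tibble) with columns `name`, `probability`
#'   (per course) and `cost` (treatment cost per event).
#' @export
adverse_event_profile <- function(events = data.frame(name = character(),
                                                      probability = numeric(),
                                                      cost = numeric())) {
  events <- as_tibble(events)
  stopifnot(all(c("name", "probability", "cost") %in% names(events)))
  structure(list(events = events), class = "cea_ae_profile")
}

#' Indirect (productivity-loss) cost parameters
#'
#' Productivity loss per care visit is `employment_rate` x
#' `hours_lost_per_visit` x `hourly_wage`.
#'
#' @param employment_rate Fraction of patients in work, in \[0, 1\].
#' @param hours_lost_per_visit Hours of work lost per visit.
#' @param hourly_wage Currency per hour.
#' @export
indirect_cost_params <- function(employment_rate = 0,
                                 hours_lost_per_visit = 0,
                                 hourly_wage = 0) {
  structure(
    list(
      employment_rate = employment_rate,
      hours_lost_per_visit = hours_lost_per_visit,
      hourly_wage = hourly_wage
    ),
    class = "cea_indirect"
  )
}

#' Visit policy: care encounters incurred per treatment course
#'
#' The model prices a visit (productivity loss, transport) but the number of
#' visits a course generates is a modelling choice. Counts are integer knobs
#' so alternative care settings can be represented and calibrated.
#'
#' @param productivity_visits_per_course Visits per course that incur the
#'   indirect (productivity-loss) cost.
#' @param transport_visits_per_course Visits per course that incur the
#'   per-visit transport cost.
#' @export
visit_policy <- function(productivity_visits_per_course = 0,
                         transport_visits_per_course = 0) {
  structure(
    list(
      productivity_visits_per_course = productivity_visits_per_course,
      transport_visits_per_course = transport_visits_per_course
    ),
    class = "cea_visit_policy"
  )
}

#' Cost model for a strategy arm
#'
#' @param unit_drug_price Currency per dose.
#' @param device_insertion_cost Currency per device insertion (0 when no
#'   device is used).
#' @param device_insertions_per_year Insertions per year (amortized over
#'   `courses_per_year_for_amortization` courses).
#' @param device_maintenance_cost Currency per maintenance event.
#' @param maintenance_events_per_course Maintenance events per course.
#' @param ae_profile An [adverse_event_profile()].
#' @param indirect An [indirect_cost_params()].
#' @param transport_cost_per_visit Currency per transport round trip.
#' @param visit_policy A [visit_policy()].
#' @export
cost_model <- function(unit_drug_price,
                       device_insertion_cost = 0,
                       device_insertions_per_year = 1,
                       device_maintenance_cost = 0,
                       maintenance_events_per_course = 0,
                       ae_profile = adverse_event_profile(),
                       indirect = indirect_cost_params(),
                       transport_cost_per_visit = 0,
                       visit_policy = cohortcea::visit_policy()) {
  structure(
    list(
      unit_drug_price = unit_drug_price,
      device_insertion_cost = device_insertion_cost,
      device_insertions_per_year = device_insertions_per_year,
      device_maintenance_cost = device_maintenance_cost,
      maintenance_events_per_course = maintenance_events_per_course,
      ae_profile = ae_profile,
      indirect = indirect,
      transport_cost_per_visit = transport_cost_per_visit,
      visit_policy = visit_policy
    ),
    class = "cea_cost_model"
  )
}

#' Strategy arm definition
#'
#' An arm couples a treatment schedule with a cost model, an administration
#' setting and the route-specific utility adjustment factor. The `role`
#' ("reference" or "comparator") determines which arm receives the
#' comparator utility adjustment coefficient of the [utility_model()].
#'
#' @param name Display label.
#' @param role `"reference"` or `"comparator"`.
#' @param schedule A [treatment_schedule()].
#' @param costs A [cost_model()].
#' @param utility_route_factor Route-of-administration utility factor
#'   (strictly positive), e.g. 0.99 for oral and 0.97 for intravenous
#'   therapy; used by the probabilistic sampler to draw the comparator
#'   coefficient as a ratio of factors.
#' @param administration_setting `"home"` or `"hospital"`.
#' @export
arm_spec <- function(name, role = c("reference", "comparator"),
                     schedule, costs,
                     utility_route_factor = 1,
                     administration_setting = c("home", "hospital")) {
  role <- match.arg(role)
  administration_setting <- match.arg(administration_setting)
  structure(
    list(
      name = name, role = role, schedule = schedule, costs = costs,
      utility_route_factor = utility_route_factor,
      administration_setting = administration_setting
    ),
    class = "cea_arm"
  )
}

#' Health-state utility model
#'
#' @param stage_utilities Named numeric vector of utilities for the living
#'   states, in model state order; must be strictly decreasing with disease
#'   stage and lie in (0, 1\].
#' @param comparator_adjustment_coefficient Multiplier applied to every
#'   living-state utility in the comparator arm (> 0). Values above 1 encode
#'   a quality-of-life advantage of the comparator's route or setting of
#'   administration.
#' @export
utility_model <- function(stage_utilities, comparator_adjustment_coefficient = 1) {
  structure(
    list(
      stage_utilities = stage_utilities,
      comparator_adjustment_coefficient = comparator_adjustment_coefficient
    ),
    class = "cea_utility_model"
  )
}

#' Assemble a cohort decision-model specification
#'
#' The full decision problem: ordered health states with one terminal
#' absorbing state, a per-cycle row-stochastic transition kernel, timing
#' (cycle length and horizon), discounting, a start distribution, a utility
#' model and exactly two strategy arms (reference and comparator). The
#' cohort is normalized to size 1; scale only in reports.
#'
#' @param states Character vector of state labels, absorbing state last.
#' @param transition A `cea_transition` from [orient_transition_table()] (or
#'   a row-stochastic matrix).
#' @param utilities A [utility_model()].
#' @param arms List with elements `reference` and `comparator`, each an
#'   [arm_spec()].
#' @param absorbing_state Label of the absorbing state (default: last).
#' @param start_distribution Probability vector over states (default: all
#'   mass in the first state).
#' @param cycle_length_years Cycle length as a fraction of a year.
#' @param n_cycles Number of cycles in the horizon.
#' @param discount_rate_annual Annual discount rate applied to both costs
#'   and utilities.
#' @param discount_from `"first_cycle"` (cycle 1 accrues undiscounted, a full
#'   year's discount after 1/cycle_length cycles) or `"zero"` (discounting
#'   starts immediately). Conventions differ across tools, so the switch is
#'   explicit.
#' @param start_age_years Cohort age at entry, in years. Metadata only: no
#'   input of the model is age-dependent.
#' @param name,currency Display metadata; `currency` labels reports only,
#'   all monetary fields are unit-free decimals.
#' @return A validated `cea_model_spec`.
#' @export
model_spec <- function(states, transition, utilities, arms,
                       absorbing_state = states[length(states)],
                       start_distribution = c(1, rep(0, length(states) - 1)),
                       cycle_length_years = 0.25,
                       n_cycles = 80,
                       discount_rate_annual = 0.05,
                       discount_from = c("first_cycle", "zero"),
                       start_age_years = NA_real_,
                       name = "cohort decision model",
                       currency = "CNY") {
  discount_from <- match.arg(discount_from)
  if (!inherits(transition, "cea_transition")) {
    transition <- orient_transition_table(transition, "rows-are-from", state_names = states)
  }
  spec <- structure(
    list(
      name = name, currency = currency,
      states = states, absorbing_state = absorbing_state,
      start_distribution = setNames(start_distribution, states),
      transition = transition,
      cycle_length_years = cycle_length_years, n_cycles = n_cycles,
      discount_rate_annual = discount_rate_annual,
      discount_from = discount_from,
      start_age_years = start_age_years,
      utilities = utilities, arms = arms
    ),
    class = "cea_model_spec"
  )
  validate_model_spec(spec)
}

fail_spec <- function(...) stop("invalid model spec: ", ..., call. = FALSE)

#' Validate a model specification
#'
#' Enforces every structural invariant of the decision problem: stochastic
#' start distribution and transition rows, terminal absorbing state listed
#' last, positive timing fields, non-negative discount rate and monetary
#' fields, utilities in (0, 1\] strictly decreasing with stage, and the
#' reference/comparator arm pairing. Errors identify the offending field and
#' value.
#'
#' @param spec A `cea_model_spec`.
#' @return `spec`, invisibly usable in a pipe (returned unchanged).
#' @export
validate_model_spec <- function(spec) {
  s <- spec$states
  n_s <- length(s)
  if (n_s < 2) fail_spec("need at least two states")
  if (anyDuplicated(s)) fail_spec("duplicate state labels")
  if (!identical(spec$absorbing_state, s[n_s])) {
    fail_spec("absorbing_state must be the last listed state, got '", spec$absorbing_state, "'")
  }
  sd <- spec$start_distribution
  if (length(sd) != n_s || any(sd < 0)) {
    fail_spec("start_distribution must be a non-negative vector over the ", n_s, " states")
  }
  if (abs(sum(sd) - 1) > 1e-12) {
    fail_spec("start_distribution sums to ", format(sum(sd), digits = 15), ", not 1")
  }
  if (!is.numeric(spec$n_cycles) || spec$n_cycles < 1 || spec$n_cycles %% 1 != 0) {
    fail_spec("n_cycles must be a positive integer, got ", spec$n_cycles)
  }
  if (spec$cycle_length_years <= 0) fail_spec("cycle_length_years must be > 0")
  if (spec$discount_rate_annual < 0) {
    fail_spec("discount_rate_annual must be >= 0, got ", spec$discount_rate_annual)
  }

  P <- unclass(spec$transition)
  if (!all(dim(P) == n_s)) fail_spec("transition matrix must be ", n_s, " x ", n_s)
  if (any(P < 0 | P > 1)) fail_spec("transition probabilities must lie in [0, 1]")
  bad <- which(abs(rowSums(P) - 1) > 1e-9)
  if (length(bad)) {
    fail_spec(
      "transition row(s) [", paste(s[bad], collapse = ", "), "] sum to [",
      paste(format(rowSums(P)[bad], digits = 12), collapse = ", "), "], not 1"
    )
  }
  ab <- n_s
  unit <- numeric(n_s); unit[ab] <- 1
  if (any(abs(P[ab, ] - unit) > 1e-12)) {
    fail_spec("absorbing state row must be the unit vector on itself")
  }

  u <- spec$utilities$stage_utilities
  if (length(u) != n_s - 1) {
    fail_spec("stage_utilities must cover the ", n_s - 1, " living states, got ", length(u))
  }
  if (any(u <= 0 | u > 1)) fail_spec("stage utilities must lie in (0, 1]")
  if (any(diff(u) >= 0)) fail_spec("stage utilities must be strictly decreasing with stage")
  if (spec$utilities$comparator_adjustment_coefficient <= 0) {
    fail_spec("comparator_adjustment_coefficient must be > 0")
  }

  if (!identical(sort(names(spec$arms)), c("comparator", "reference"))) {
    fail_spec("arms must be a list with elements 'reference' and 'comparator'")
  }
  for (role in c("reference", "comparator")) {
    arm <- spec$arms[[role]]
    if (!identical(arm$role, role)) {
      fail_spec("arm '", arm$name, "' has role '", arm$role, "' but is listed as ", role)
    }
    validate_arm(arm)
  }
  invisible(spec)
}

validate_arm <- function(arm) {
  sch <- arm$schedule
  for (f in c("course_length_days", "first_course_admin_days",
              "subsequent_course_admin_days", "doses_per_day")) {
    v <- sch[[f]]
    if (!is.numeric(v) || v <= 0 || v %% 1 != 0) {
      fail_spec("arm '", arm$name, "': schedule field ", f, " must be a positive integer, got ", v)
    }
  }
  if (sch$first_course_admin_days < sch$subsequent_course_admin_days) {
    fail_spec("arm '", arm$name, "': first_course_admin_days < subsequent_course_admin_days")
  }
  if (sch$courses_per_cycle <= 0 || sch$courses_per_year_for_amortization <= 0) {
    fail_spec("arm '", arm$name, "': courses_per_cycle and amortization divisor must be > 0")
  }
  if (arm$utility_route_factor <= 0) {
    fail_spec("arm '", arm$name, "': utility_route_factor must be > 0")
  }

  cm <- arm$costs
  for (f in c("unit_drug_price", "device_insertion_cost", "device_insertions_per_year",
              "device_maintenance_cost", "maintenance_events_per_course",
              "transport_cost_per_visit")) {
    if (cm[[f]] < 0) {
      fail_spec("arm '", arm$name, "': cost field ", f, " is negative (", cm[[f]], ")")
    }
  }
  ev <- cm$ae_profile$events
  if (nrow(ev)) {
    if (any(ev$probability < 0 | ev$probability > 1)) {
      fail_spec("arm '", arm$name, "': adverse-event probabilities must lie in [0, 1]")
    }
    if (any(ev$cost < 0)) fail_spec("arm '", arm$name, "': adverse-event costs must be >= 0")
  }
  ind <- cm$indirect
  if (ind$employment_rate < 0 || ind$employment_rate > 1) {
    fail_spec("arm '", arm$name, "': employment_rate must lie in [0, 1]")
  }
  if (ind$hours_lost_per_visit < 0 || ind$hourly_wage < 0) {
    fail_spec("arm '", arm$name, "': indirect-cost components must be >= 0")
  }
  vp <- cm$visit_policy
  if (vp$productivity_visits_per_course < 0 || vp$transport_visits_per_course < 0) {
    fail_spec("arm '", arm$name, "': visit counts must be >= 0")
  }
  invisible(arm)
}

living_states <- function(spec) spec$states[-length(spec$states)]

#' @export
print.cea_model_spec <- function(x, ...) {
  cat("<cea_model_spec> ", x$name, "\n", sep = "")
  cat("  states: ", paste(x$states, collapse = ", "),
      " (absorbing: ", x$absorbing_state, ")\n", sep = "")
  cat(sprintf("  horizon: %d cycles x %.2f y; discount %.1f%%/y (%s)\n",
              x$n_cycles, x$cycle_length_years, 100 * x$discount_rate_annual,
              x$discount_from))
  cat("  arms: reference = ", x$arms$reference$name,
      " (", x$arms$reference$administration_setting, "), comparator = ",
      x$arms$comparator$name, " (", x$arms$comparator$administration_setting,
      ")\n", sep = "")
  cat(sprintf("  comparator utility coefficient: %.4g\n",
              x$utilities$comparator_adjustment_coefficient))
  invisible(x)
}

#' Round a pair of route utility factors into an adjustment coefficient
#'
#' The comparator's utility advantage is encoded as the ratio of the
#' route-of-administration factors (e.g. 0.99 for oral over 0.97 for
#' intravenous), rounded to the precision at which such coefficients are
#' conventionally reported.
#'
#' @param comparator_factor,reference_factor Strictly positive route factors.
#' @param digits Decimal places for the reported coefficient.
#' @return The rounded ratio, e.g. `0.99 / 0.97` -> 1.021.
#' @export
utility_adjustment_coefficient <- function(comparator_factor = 0.99,
                                           reference_factor = 0.97,
                                           digits = 3) {
  stopifnot(comparator_factor > 0, reference_factor > 0)
  round(comparator_factor / reference_factor, digits)
}
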