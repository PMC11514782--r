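# Random valid decision problems plus an individual-level microsimulation
# oracle. Together they let every pipeline stage be exercised without any
# external data: the generator covers the input space (absorbing-chain
# kernels, monotone stage utilities, positive course-based costs) and the
# microsimulation provides an estimate of trace and valuation quantities
# that deliberately bypasses the cohort propagation code.

#' Configuration for the random model generator
#'
#' @param n_states Number of states including the terminal absorbing state
#'   (>= 2).
#' @param progression_only If `TRUE`, the living block is upper-triangular:
#'   no mass flows from a later to an earlier stage (the structure of an
#'   irreversible staging system).
#' @param cost_scale Typical magnitude of generated unit costs.
#' @param utility_range Range the strictly decreasing stage utilities are
#'   drawn from.
#' @param coefficient_range Range of the comparator utility adjustment
#'   coefficient.
#' @param n_cycles,cycle_length_years,discount_rate_annual Timing and
#'   discounting of generated models.
#' @param seed Optional integer; when given, generation is deterministic.
#' @export
generator_config <- function(n_states = 5,
                             progression_only = TRUE,
                             cost_scale = 1000,
                             utility_range = c(0.2, 0.9),
                             coefficient_range = c(0.95, 1.15),
                             n_cycles = 40,
                             cycle_length_years = 0.25,
                             discount_rate_annual = 0.05,
                             seed = NULL) {
  stopifnot(n_states >= 2, cost_scale > 0,
            utility_range[1] > 0, utility_range[2] <= 1,
            utility_range[1] < utility_range[2])
  structure(
    list(
      n_states = n_states, progression_only = progression_only,
      cost_scale = cost_scale, utility_range = utility_range,
      coefficient_range = coefficient_range,
      n_cycles = n_cycles, cycle_length_years = cycle_length_years,
      discount_rate_annual = discount_rate_annual, seed = seed
    ),
    class = "cea_generator_config"
  )
}

random_arm <- function(role, cfg) {
  has_device <- runif(1) < 0.5
  n_ae <- sample(0:3, 1)
  ae <- adverse_event_profile(data.frame(
    name = if (n_ae) paste0("ae", seq_len(n_ae)) else character(),
    probability = runif(n_ae, 0, 0.05),
    cost = runif(n_ae, 0.1, 2) * cfg$cost_scale
  ))
  arm_spec(
    name = paste0(role, "_arm"), role = role,
    schedule = treatment_schedule(
      course_length_days = 28,
      first_course_admin_days = sample(10:14, 1),
      subsequent_course_admin_days = sample(5:10, 1),
      doses_per_day = sample(1:3, 1),
      courses_per_cycle = runif(1, 1, 4),
      courses_per_year_for_amortization = 13
    ),
    costs = cost_model(
      unit_drug_price = runif(1, 0.05, 0.5) * cfg$cost_scale,
      device_insertion_cost = if (has_device) runif(1, 1, 3) * cfg$cost_scale else 0,
      device_insertions_per_year = 1,
      device_maintenance_cost = if (has_device) runif(1, 0.05, 0.2) * cfg$cost_scale else 0,
      maintenance_events_per_course = if (has_device) sample(1:3, 1) else 0,
      ae_profile = ae,
      indirect = indirect_cost_params(
        employment_rate = runif(1, 0.05, 0.6),
        hours_lost_per_visit = runif(1, 1, 8),
        hourly_wage = runif(1, 0.005, 0.05) * cfg$cost_scale
      ),
      transport_cost_per_visit = runif(1, 0, 0.2) * cfg$cost_scale,
      visit_policy = visit_policy(
        productivity_visits_per_course = sample(0:12, 1),
        transport_visits_per_course = sample(0:12, 1)
      )
    ),
    utility_route_factor = runif(1, 0.9, 1),
    administration_setting = sample(c("home", "hospital"), 1)
  )
}

#' Generate a random valid decision model
#'
#' Transition rows of the living states are drawn from a flat simplex
#' sampler (independent exponentials, normalized per row), masked to the
#' upper triangle when `progression_only`; every row keeps strictly
#' positive mass into the absorbing state so the chain is eventually
#' absorbed. Stage utilities are strictly decreasing draws from
#' `utility_range`; both arms get positive course-based cost structures at
#' `cost_scale`. Generation is deterministic under `seed`, and every
#' generated spec passes full validation.
#'
#' @param config A [generator_config()].
#' @return A validated `cea_model_spec`.
#' @examples
#' spec <- generate_model(generator_config(seed = 42))
#' run_cua(spec)
#' @export
generate_model <- function(config = generator_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n_s <- config$n_states
  states <- c(paste0("stage", seq_len(n_s - 1)), "death")

  P <- matrix(0, n_s, n_s, dimnames = list(from = states, to = states))
  for (i in seq_len(n_s - 1)) {
    allowed <- if (config$progression_only) i:n_s else seq_len(n_s)
    w <- rexp(length(allowed))
    # keep the chain lazy enough to be interesting and guarantee positive
    # absorption mass from every living state
    w[allowed == i] <- w[allowed == i] + length(allowed)
    w[allowed == n_s] <- pmax(w[allowed == n_s], 0.05)
    P[i, allowed] <- w / sum(w)
  }
  P[n_s, n_s] <- 1

  u <- sort(runif(n_s - 1, config$utility_range[1], config$utility_range[2]),
            decreasing = TRUE)
  names(u) <- states[-n_s]

  model_spec(
    states = states,
    transition = orient_transition_table(P, "rows-are-from", states),
    utilities = utility_model(
      stage_utilities = u,
      comparator_adjustment_coefficient = runif(1, config$coefficient_range[1],
                                                config$coefficient_range[2])
    ),
    arms = list(
      reference = random_arm("reference", config),
      comparator = random_arm("comparator", config)
    ),
    n_cycles = config$n_cycles,
    cycle_length_years = config$cycle_length_years,
    discount_rate_annual = config$discount_rate_annual,
    name = "generated cohort model"
  )
}

#' Individual-level microsimulation of an arm
#'
#' Simulates `n_patients` state paths directly from the transition kernel
#' (one categorical draw per patient per cycle), tabulates empirical
#' per-cycle state frequencies, and values them with exactly the same
#' half-cycle-corrected, discounted costing and QALY rules as the cohort
#' engine ([value_arm()] on the empirical occupancy). The state
#' propagation deliberately does not share code with [run_trace()]'s
#' matrix recursion, so the microsimulation serves as an independent
#' oracle: cohort occupancy must match the empirical frequencies to Monte
#' Carlo accuracy, and valuations likewise.
#'
#' @param spec A validated `cea_model_spec`.
#' @param arm One of `spec$arms`.
#' @param n_patients Number of simulated patients (>= 1).
#' @param seed Integer seed.
#' @return A `cea_microsim`: `valuation` (a `cea_arm_valuation` of the
#'   empirical trace), `trace` (the empirical `cea_trace`), and
#'   `n_patients`.
#' @examples
#' spec <- als_edaravone_spec()
#' ms <- microsimulate(spec, spec$arms$reference, n_patients = 2000, seed = 7)
#' ms$valuation
#' @export
microsimulate <- function(spec, arm, n_patients = 10000, seed = 1L) {
  stopifnot(n_patients >= 1)
  set.seed(seed)
  n_s <- length(spec$states)
  n <- spec$n_cycles
  P <- unclass(spec$transition)

  state <- sample.int(n_s, n_patients, replace = TRUE,
                      prob = spec$start_distribution)
  occ <- matrix(0, n + 1L, n_s, dimnames = list(NULL, spec$states))
  occ[1L, ] <- tabulate(state, n_s) / n_patients
  for (k in seq_len(n)) {
    # transition from a snapshot so nobody moves twice in one cycle
    cur <- state
    for (s in seq_len(n_s - 1L)) {
      idx <- which(cur == s)
      if (length(idx)) {
        state[idx] <- sample.int(n_s, length(idx), replace = TRUE, prob = P[s, ])
      }
    }
    occ[k + 1L, ] <- tabulate(state, n_s) / n_patients
  }

  trace <- new_trace(occ, spec)
  structure(
    list(valuation = value_arm(trace, arm, spec),
         trace = trace, n_patients = n_patients),
    class = "cea_microsim"
  )
}

#' @export
print.cea_microsim <- function(x, ...) {
  cat("<cea_microsim> ", x$n_patients, " patients\n", sep = "")
  print(x$valuation)
  invisible(x)
}
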