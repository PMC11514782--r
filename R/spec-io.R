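# YAML (or JSON) serialization of model specifications. The file schema
# mirrors the constructor surface one to one; unknown keys are rejected by
# name so typos never silently fall back to defaults.

check_keys <- function(x, required, optional = character(), where = "top level") {
  nm <- names(x)
  missing <- setdiff(required, nm)
  if (length(missing)) {
    stop("model file: missing required field(s) [", paste(missing, collapse = ", "),
         "] at ", where, call. = FALSE)
  }
  unknown <- setdiff(nm, c(required, optional))
  if (length(unknown)) {
    stop("model file: unknown key(s) [", paste(unknown, collapse = ", "),
         "] at ", where, call. = FALSE)
  }
  invisible(x)
}

parse_arm <- function(x, role, where) {
  check_keys(x, required = c("name", "schedule", "costs"),
             optional = c("administration_setting", "utility_route_factor"),
             where = where)
  check_keys(x$schedule, required = character(),
             optional = c("course_length_days", "first_course_admin_days",
                          "subsequent_course_admin_days", "doses_per_day",
                          "courses_per_cycle", "courses_per_year_for_amortization"),
             where = paste0(where, ".schedule"))
  check_keys(x$costs, required = "unit_drug_price",
             optional = c("device_insertion_cost", "device_insertions_per_year",
                          "device_maintenance_cost", "maintenance_events_per_course",
                          "transport_cost_per_visit", "adverse_events", "indirect",
                          "visit_policy"),
             where = paste0(where, ".costs"))

  sch <- do.call(treatment_schedule, x$schedule)
  ae <- adverse_event_profile(
    if (is.null(x$costs$adverse_events)) {
      data.frame(name = character(), probability = numeric(), cost = numeric())
    } else {
      do.call(rbind, lapply(x$costs$adverse_events, function(e) {
        check_keys(e, required = c("name", "probability", "cost"),
                   where = paste0(where, ".costs.adverse_events"))
        data.frame(name = e$name, probability = e$probability, cost = e$cost)
      }))
    }
  )
  ind <- do.call(indirect_cost_params, x$costs$indirect %||% list())
  vp <- do.call(visit_policy, x$costs$visit_policy %||% list())
  cm <- cost_model(
    unit_drug_price = x$costs$unit_drug_price,
    device_insertion_cost = x$costs$device_insertion_cost %||% 0,
    device_insertions_per_year = x$costs$device_insertions_per_year %||% 1,
    device_maintenance_cost = x$costs$device_maintenance_cost %||% 0,
    maintenance_events_per_course = x$costs$maintenance_events_per_course %||% 0,
    ae_profile = ae, indirect = ind,
    transport_cost_per_visit = x$costs$transport_cost_per_visit %||% 0,
    visit_policy = vp
  )
  arm_spec(
    name = x$name, role = role, schedule = sch, costs = cm,
    utility_route_factor = x$utility_route_factor %||% 1,
    administration_setting = x$administration_setting %||% "home"
  )
}

#' Read and validate a model-specification file
#'
#' Parses a YAML (or JSON, an equivalent dialect for this schema) decision
#' model description, builds the typed specification and runs full
#' validation. Any unknown key anywhere in the file is an error naming the
#' key; so is any violated invariant (non-stochastic transition row,
#' negative cost, ...).
#'
#' @param path Path to a model file; see the bundled
#'   `system.file("extdata", "als_edaravone.yaml", package = "cohortcea")`
#'   for the schema.
#' @return A validated `cea_model_spec`.
#' @seealso [write_model_spec()], [als_edaravone_spec()]
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  check_keys(
    x,
    required = c("states", "transition", "utilities", "arms"),
    optional = c("name", "currency", "absorbing_state", "start_distribution",
                 "cycle_length_years", "n_cycles", "discount_rate_annual",
                 "discount_from", "start_age_years")
  )
  check_keys(x$transition, required = "probabilities", optional = "orientation",
             where = "transition")
  check_keys(x$utilities, required = "stage_utilities",
             optional = "comparator_adjustment_coefficient", where = "utilities")
  check_keys(x$arms, required = c("reference", "comparator"), where = "arms")

  states <- unlist(x$states)
  raw <- do.call(rbind, x$transition$probabilities)
  trans <- orient_transition_table(
    raw,
    orientation = x$transition$orientation %||% "rows-are-from",
    state_names = states
  )
  su <- unlist(x$utilities$stage_utilities)
  model_spec(
    states = states,
    transition = trans,
    utilities = utility_model(
      stage_utilities = su,
      comparator_adjustment_coefficient =
        x$utilities$comparator_adjustment_coefficient %||% 1
    ),
    arms = list(
      reference = parse_arm(x$arms$reference, "reference", "arms.reference"),
      comparator = parse_arm(x$arms$comparator, "comparator", "arms.comparator")
    ),
    absorbing_state = x$absorbing_state %||% states[length(states)],
    start_distribution = unlist(x$start_distribution) %||%
      c(1, rep(0, length(states) - 1)),
    cycle_length_years = x$cycle_length_years %||% 0.25,
    n_cycles = x$n_cycles %||% 80,
    discount_rate_annual = x$discount_rate_annual %||% 0.05,
    discount_from = x$discount_from %||% "first_cycle",
    start_age_years = x$start_age_years %||% NA_real_,
    name = x$name %||% basename(path),
    currency = x$currency %||% "CNY"
  )
}

arm_to_config <- function(arm) {
  ev <- arm$costs$ae_profile$events
  list(
    name = arm$name,
    administration_setting = arm$administration_setting,
    utility_route_factor = arm$utility_route_factor,
    schedule = unclass(arm$schedule),
    costs = list(
      unit_drug_price = arm$costs$unit_drug_price,
      device_insertion_cost = arm$costs$device_insertion_cost,
      device_insertions_per_year = arm$costs$device_insertions_per_year,
      device_maintenance_cost = arm$costs$device_maintenance_cost,
      maintenance_events_per_course = arm$costs$maintenance_events_per_course,
      transport_cost_per_visit = arm$costs$transport_cost_per_visit,
      adverse_events = lapply(seq_len(nrow(ev)), function(i) {
        list(name = ev$name[i], probability = ev$probability[i], cost = ev$cost[i])
      }),
      indirect = unclass(arm$costs$indirect),
      visit_policy = unclass(arm$costs$visit_policy)
    )
  )
}

#' Write a model specification to a YAML file
#'
#' Serializes in the canonical row-stochastic (`rows-are-from`) orientation.
#' Round-trips: `read_model_spec(write_model_spec(spec, f))` reproduces every
#' numeric field to within 1e-12.
#'
#' @param spec A validated `cea_model_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  P <- unclass(spec$transition)
  cfg <- list(
    name = spec$name,
    currency = spec$currency,
    states = as.list(spec$states),
    absorbing_state = spec$absorbing_state,
    start_distribution = as.list(unname(spec$start_distribution)),
    cycle_length_years = spec$cycle_length_years,
    n_cycles = spec$n_cycles,
    discount_rate_annual = spec$discount_rate_annual,
    discount_from = spec$discount_from,
    start_age_years = spec$start_age_years,
    transition = list(
      orientation = "rows-are-from",
      probabilities = lapply(seq_len(nrow(P)), function(i) as.list(unname(P[i, ])))
    ),
    utilities = list(
      stage_utilities = as.list(spec$utilities$stage_utilities),
      comparator_adjustment_coefficient =
        spec$utilities$comparator_adjustment_coefficient
    ),
    arms = list(
      reference = arm_to_config(spec$arms$reference),
      comparator = arm_to_config(spec$arms$comparator)
    )
  )
  if (is.na(cfg$start_age_years)) cfg$start_age_years <- NULL
  writeLines(yaml::as.yaml(cfg, precision = 15), path)
  invisible(path)
}

#' The bundled ALS edaravone decision model
#'
#' A fully parameterized cost-utility model comparing sublingual (SL,
#' comparator) and intravenous (IV, reference) edaravone for amyotrophic
#' lateral sclerosis in the Chinese setting: King's stages 1-4 plus death,
#' quarterly cycles over a 20-year horizon, 5% annual discounting, published
#' stage utilities with an SL utility adjustment coefficient of 1.021, and
#' course-based drug, device, adverse-event, and productivity-loss costs.
#' The `"hospital"` variant administers IV in hospital: transport and
#' productivity losses on administration visits and a setting utility
#' coefficient of 1.147 replacing the route coefficient.
#'
#' @param variant `"base"` (both arms at home) or `"hospital"`.
#' @return A validated `cea_model_spec`.
#' @examples
#' spec <- als_edaravone_spec()
#' spec
#' @export
als_edaravone_spec <- function(variant = c("base", "hospital")) {
  variant <- match.arg(variant)
  read_model_spec(als_edaravone_path(variant))
}

#' @rdname als_edaravone_spec
#' @export
als_edaravone_path <- function(variant = c("base", "hospital")) {
  variant <- match.arg(variant)
  fn <- switch(variant,
    base = "als_edaravone.yaml",
    hospital = "als_edaravone_hospital.yaml"
  )
  system.file("extdata", fn, package = "cohortcea", mustWork = TRUE)
}
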