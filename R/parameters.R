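# Dotted-path addressing of the numeric leaves of a model spec, shared by
# the one-way and probabilistic sensitivity machinery.
#
# Grammar:
#   discount_rate_annual
#   transition.<from>.<to>                  (off-diagonal; diagonal absorbs)
#   utilities.stage_utilities.<state>
#   utilities.comparator_adjustment_coefficient
#   arms.<role>.utility_route_factor
#   arms.<role>.costs.<scalar field>
#   arms.<role>.costs.ae_profile.<event>.probability|cost
#   arms.<role>.costs.indirect.<field>

spec_get_param <- function(spec, id) {
  p <- strsplit(id, ".", fixed = TRUE)[[1]]
  switch(p[1],
    discount_rate_annual = spec$discount_rate_annual,
    transition = unclass(spec$transition)[p[2], p[3]],
    utilities = if (p[2] == "stage_utilities") {
      spec$utilities$stage_utilities[[p[3]]]
    } else {
      spec$utilities[[p[2]]]
    },
    arms = {
      arm <- spec$arms[[p[2]]]
      if (p[3] == "utility_route_factor") {
        arm$utility_route_factor
      } else if (p[4] == "ae_profile") {
        ev <- arm$costs$ae_profile$events
        ev[[p[6]]][ev$name == p[5]]
      } else if (p[4] == "indirect") {
        arm$costs$indirect[[p[5]]]
      } else {
        arm$costs[[p[4]]]
      }
    },
    stop("cannot resolve parameter id '", id, "'")
  )
}

# Set a parameter. For transition entries the same-state (diagonal) element
# absorbs the change so the row still sums to 1; a negative diagonal is
# reported as infeasible rather than silently renormalized.
# Returns list(spec = , feasible = logical).
spec_set_param <- function(spec, id, value) {
  p <- strsplit(id, ".", fixed = TRUE)[[1]]
  feasible <- TRUE
  switch(p[1],
    discount_rate_annual = {
      spec$discount_rate_annual <- value
    },
    transition = {
      from <- p[2]; to <- p[3]
      if (from == to) stop("perturb off-diagonal transition entries only ('", id, "')")
      P <- unclass(spec$transition)
      new_diag <- P[from, from] + (P[from, to] - value)
      if (new_diag < -1e-12) {
        feasible <- FALSE
      } else {
        P[from, to] <- value
        P[from, from] <- max(new_diag, 0)
        class(P) <- class(spec$transition)
        spec$transition <- P
      }
    },
    utilities = {
      if (p[2] == "stage_utilities") {
        spec$utilities$stage_utilities[[p[3]]] <- value
      } else {
        spec$utilities[[p[2]]] <- value
      }
    },
    arms = {
      role <- p[2]
      if (p[3] == "utility_route_factor") {
        spec$arms[[role]]$utility_route_factor <- value
      } else if (p[4] == "ae_profile") {
        ev <- spec$arms[[role]]$costs$ae_profile$events
        ev[[p[6]]][ev$name == p[5]] <- value
        spec$arms[[role]]$costs$ae_profile$events <- ev
      } else if (p[4] == "indirect") {
        spec$arms[[role]]$costs$indirect[[p[5]]] <- value
      } else {
        spec$arms[[role]]$costs[[p[4]]] <- value
      }
    },
    stop("cannot resolve parameter id '", id, "'")
  )
  list(spec = spec, feasible = feasible)
}

#' Enumerate the sensitivity-parameter universe of a model
#'
#' Every nonzero numeric leaf that the sensitivity analyses vary: unit drug
#' prices, device insertion/maintenance costs, transport cost, adverse-event
#' rates and costs (for events with nonzero incidence), productivity-loss
#' components (for arms that incur visits), each nonzero off-diagonal
#' transition probability of the living states, each stage utility, the
#' comparator utility adjustment coefficient, and the discount rate.
#'
#' @param spec A validated `cea_model_spec`.
#' @return A tibble with columns `parameter_id`, `kind` (`"cost"`,
#'   `"effect"`, or `"discount"`), `base_value`, and `clamp_unit` (whether
#'   the parameter is constrained to \[0, 1\]).
#' @export
spec_parameters <- function(spec) {
  rows <- list()
  add <- function(id, kind, base, clamp = FALSE) {
    rows[[length(rows) + 1L]] <<- tibble(
      parameter_id = id, kind = kind, base_value = base, clamp_unit = clamp
    )
  }

  add("discount_rate_annual", "discount", spec$discount_rate_annual, FALSE)

  P <- unclass(spec$transition)
  living <- living_states(spec)
  for (from in living) {
    for (to in spec$states) {
      if (from != to && P[from, to] > 0) {
        add(paste("transition", from, to, sep = "."), "effect", P[from, to], TRUE)
      }
    }
  }

  for (s in names(spec$utilities$stage_utilities)) {
    add(paste("utilities.stage_utilities", s, sep = "."), "effect",
        spec$utilities$stage_utilities[[s]], TRUE)
  }
  add("utilities.comparator_adjustment_coefficient", "effect",
      spec$utilities$comparator_adjustment_coefficient, FALSE)

  for (role in c("reference", "comparator")) {
    arm <- spec$arms[[role]]
    cm <- arm$costs
    pre <- function(f) paste("arms", role, "costs", f, sep = ".")
    add(pre("unit_drug_price"), "cost", cm$unit_drug_price)
    if (cm$device_insertion_cost > 0) {
      add(pre("device_insertion_cost"), "cost", cm$device_insertion_cost)
    }
    if (cm$device_maintenance_cost > 0 && cm$maintenance_events_per_course > 0) {
      add(pre("device_maintenance_cost"), "cost", cm$device_maintenance_cost)
    }
    if (cm$transport_cost_per_visit > 0 &&
        cm$visit_policy$transport_visits_per_course > 0) {
      add(pre("transport_cost_per_visit"), "cost", cm$transport_cost_per_visit)
    }
    ev <- cm$ae_profile$events
    for (i in seq_len(nrow(ev))) {
      if (ev$probability[i] > 0) {
        add(pre(paste("ae_profile", ev$name[i], "probability", sep = ".")),
            "effect", ev$probability[i], TRUE)
        if (ev$cost[i] > 0) {
          add(pre(paste("ae_profile", ev$name[i], "cost", sep = ".")),
              "cost", ev$cost[i])
        }
      }
    }
    if (cm$visit_policy$productivity_visits_per_course > 0) {
      ind <- cm$indirect
      if (ind$employment_rate > 0) {
        add(pre("indirect.employment_rate"), "cost", ind$employment_rate, TRUE)
      }
      if (ind$hours_lost_per_visit > 0) {
        add(pre("indirect.hours_lost_per_visit"), "cost", ind$hours_lost_per_visit)
      }
      if (ind$hourly_wage > 0) {
        add(pre("indirect.hourly_wage"), "cost", ind$hourly_wage)
      }
    }
  }
  dplyr::bind_rows(rows)
}
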