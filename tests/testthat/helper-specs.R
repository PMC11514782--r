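# Small model builders used across the suite. All fixtures are built in
# code; the only file-based fixture is the bundled ALS model.

toy_arm <- function(role, price = 10,
                    vp = visit_policy(),
                    ae = adverse_event_profile(),
                    courses_per_cycle = 1,
                    indirect = indirect_cost_params()) {
  arm_spec(
    name = paste0(role, "_arm"), role = role,
    schedule = treatment_schedule(courses_per_cycle = courses_per_cycle),
    costs = cost_model(
      unit_drug_price = price, ae_profile = ae, indirect = indirect,
      visit_policy = vp
    ),
    utility_route_factor = 0.95
  )
}

# Two-state chain: one living state with per-cycle death probability p.
two_state_spec <- function(p_death = 0.5, n_cycles = 20, utility = 0.8,
                           coef = 1, rate = 0.05, price = 10) {
  model_spec(
    states = c("s1", "death"),
    transition = rbind(c(1 - p_death, p_death), c(0, 1)),
    utilities = utility_model(c(s1 = utility), coef),
    arms = list(
      reference = toy_arm("reference", price = price),
      comparator = toy_arm("comparator", price = price * 1.5)
    ),
    n_cycles = n_cycles,
    discount_rate_annual = rate,
    name = "two-state toy"
  )
}

# Identity kernel: nobody ever moves (or dies).
frozen_spec <- function(n_cycles = 10) {
  model_spec(
    states = c("s1", "s2", "death"),
    transition = diag(3),
    utilities = utility_model(c(s1 = 0.9, s2 = 0.5), 1.1),
    arms = list(
      reference = toy_arm("reference"),
      comparator = toy_arm("comparator")
    ),
    start_distribution = c(0.6, 0.4, 0),
    n_cycles = n_cycles,
    name = "frozen toy"
  )
}

# Deterministic conveyor s1 -> s2 -> death, for exact microsim agreement.
conveyor_spec <- function(n_cycles = 6) {
  model_spec(
    states = c("s1", "s2", "death"),
    transition = rbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 1)),
    utilities = utility_model(c(s1 = 0.9, s2 = 0.5), 1.2),
    arms = list(
      reference = toy_arm("reference"),
      comparator = toy_arm("comparator")
    ),
    n_cycles = n_cycles,
    name = "conveyor toy"
  )
}

# Re-read the bundled base model once per test file.
als_base <- function() als_edaravone_spec("base")
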