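test_that("perturbation ranges follow the cost/effect rules with clamping", {
  expect_equal(perturbation_range(2600, "cost"), c(2080, 3120))
  expect_equal(perturbation_range(0.740, "effect"), c(0.666, 0.814))
  expect_equal(perturbation_range(0.95, "effect", clamp_unit = TRUE),
               c(0.855, 1)) # high end clamped to 1
  expect_equal(perturbation_range(0.05, "discount"), c(0, 0.08))
  expect_equal(perturbation_range(0.05, "discount", effect_fraction = 0),
               c(0.05, 0.05))
  expect_error(perturbation_range(1, "nonsense"), "arg")
})

test_that("the parameter universe covers the documented leaves", {
  pars <- spec_parameters(als_base())
  ids <- pars$parameter_id
  expect_true("discount_rate_annual" %in% ids)
  expect_true("transition.stage1.stage2" %in% ids)
  expect_true("utilities.stage_utilities.stage4" %in% ids)
  expect_true("utilities.comparator_adjustment_coefficient" %in% ids)
  expect_true("arms.comparator.costs.unit_drug_price" %in% ids)
  expect_true("arms.reference.costs.ae_profile.liver_damage.probability" %in% ids)
  # diagonals never perturbed directly (they absorb)
  expect_false(any(grepl("transition.stage1.stage1", ids, fixed = TRUE)))
  # zero-incidence events are not varied
  expect_false(any(grepl("kidney_damage", ids[grepl("reference", ids)])))
  # every id resolves to its base value
  for (i in seq_len(nrow(pars))) {
    expect_equal(spec_get_param(als_base(), pars$parameter_id[i]),
                 pars$base_value[i])
  }
})

test_that("transition perturbations are absorbed by the diagonal", {
  spec <- als_base()
  set <- spec_set_param(spec, "transition.stage1.stage2", 0.25)
  expect_true(set$feasible)
  P <- unclass(set$spec$transition)
  expect_equal(P["stage1", "stage2"], 0.25)
  expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-12)
  expect_equal(P["stage1", "stage1"], 0.677 - (0.25 - 0.217))

  # infeasible absorption is flagged, not renormalized
  tight <- two_state_spec(p_death = 0.97)
  bad <- spec_set_param(tight, "transition.s1.death", 0.999 + 0.05)
  expect_false(bad$feasible)
})

test_that("cost perturbations leave the QALY difference untouched", {
  spec <- als_base()
  base <- run_cua(spec)
  pars <- dplyr::filter(spec_parameters(spec), kind == "cost")
  ow <- run_owsa(spec, parameters = pars)
  expect_true(all(ow$feasible))
  expect_equal(ow$delta_qaly_low, rep(base$delta_qaly, nrow(ow)))
  expect_equal(ow$delta_qaly_high, rep(base$delta_qaly, nrow(ow)))
})

test_that("coefficient perturbation moves the QALY difference proportionally", {
  spec <- als_base()
  iv_qaly <- run_cua(spec)$reference$total_qaly
  pars <- dplyr::filter(spec_parameters(spec),
                        parameter_id == "utilities.comparator_adjustment_coefficient")
  ow <- run_owsa(spec, parameters = pars)
  expect_equal(ow$delta_qaly_low, iv_qaly * (ow$low_value - 1), tolerance = 1e-9)
  expect_equal(ow$delta_qaly_high, iv_qaly * (ow$high_value - 1), tolerance = 1e-9)
})

test_that("zero perturbation fractions reproduce the base case everywhere", {
  spec <- als_base()
  base <- run_cua(spec)
  ow <- run_owsa(spec, cost_fraction = 0, effect_fraction = 0)
  expect_true(all(ow$feasible))
  expect_equal(ow$span, rep(0, nrow(ow)), tolerance = 1e-6)
  expect_equal(ow$icer_low, rep(base$icer, nrow(ow)), tolerance = 1e-9)
  expect_equal(ow$icer_high, rep(base$icer, nrow(ow)), tolerance = 1e-9)
})

test_that("tornado ordering surfaces drug costs and the utility coefficient", {
  ow <- run_owsa(als_base())
  expect_true(all(ow$feasible))
  expect_true(all(diff(ow$span) <= 1e-9)) # sorted descending
  top3 <- ow$parameter_id[1:3]
  expect_true("utilities.comparator_adjustment_coefficient" %in% top3)
  expect_true(any(grepl("unit_drug_price", top3)))

  # adverse-event inputs are insensitive relative to drug prices
  ae_span <- max(ow$span[grepl("ae_profile", ow$parameter_id)])
  drug_span <- max(ow$span[grepl("unit_drug_price", ow$parameter_id)])
  expect_lt(ae_span, 0.05 * drug_span)

  expect_s3_class(autoplot(ow), "ggplot")
})

test_that("perturbed models that break an invariant are flagged infeasible", {
  # utilities 10% apart: +10% on the lower stage breaks monotonicity
  spec <- two_state_spec()
  spec3 <- model_spec(
    states = c("s1", "s2", "death"),
    transition = rbind(c(0.8, 0.1, 0.1), c(0, 0.8, 0.2), c(0, 0, 1)),
    utilities = utility_model(c(s1 = 0.62, s2 = 0.60), 1.05),
    arms = spec$arms, n_cycles = 10
  )
  pars <- dplyr::filter(spec_parameters(spec3),
                        parameter_id == "utilities.stage_utilities.s2")
  ow <- run_owsa(spec3, parameters = pars)
  expect_false(ow$feasible[1])
  expect_true(is.na(ow$icer_high))
})
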