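test_that("course costs reproduce the published per-course arithmetic", {
  spec <- als_base()
  sl <- spec$arms$comparator
  iv <- spec$arms$reference

  expect_equal(course_cost(sl$schedule, sl$costs), 2600.00)
  expect_equal(course_cost(sl$schedule, sl$costs, first = TRUE), 3640.00)
  # 14 x 2 x 86.83 + 2 x 103.17 + 1847.96 / 13
  expect_equal(round(course_cost(iv$schedule, iv$costs, first = TRUE), 2), 2779.73)
  expect_equal(round(course_cost(iv$schedule, iv$costs), 2), 2085.09)
})

test_that("expected adverse-event cost is the probability-weighted sum", {
  spec <- als_base()
  expect_equal(round(expected_ae_cost(spec$arms$comparator$costs$ae_profile), 2),
               6.49)
  expect_equal(round(expected_ae_cost(spec$arms$reference$costs$ae_profile), 2),
               55.93)
  zero <- adverse_event_profile(data.frame(
    name = c("a", "b"), probability = c(0, 0), cost = c(100, 200)
  ))
  expect_equal(expected_ae_cost(zero), 0)
  expect_equal(expected_ae_cost(adverse_event_profile()), 0)
})

test_that("productivity loss per visit multiplies its three components", {
  spec <- als_base()
  expect_equal(round(indirect_cost_per_visit(spec$arms$reference$costs$indirect), 2),
               17.23)
  expect_equal(indirect_cost_per_visit(indirect_cost_params(0, 6.23, 18.44)), 0)
  expect_equal(indirect_cost_per_visit(indirect_cost_params(1, 1, 1)), 1)
})

test_that("per-cycle cost composes courses, AEs, visits and the premium", {
  spec <- als_base()
  sl <- spec$arms$comparator
  iv <- spec$arms$reference
  cpc <- sl$schedule$courses_per_cycle

  ae_sl <- expected_ae_cost(sl$costs$ae_profile)
  expect_equal(cycle_cost(sl, 2), cpc * (2600 + ae_sl))
  expect_equal(cycle_cost(sl, 1), cpc * (2600 + ae_sl) + (3640 - 2600))
  expect_equal(cycle_cost(sl, 2:5), rep(cycle_cost(sl, 2), 4))

  # IV at home: productivity visits, no transport
  ae_iv <- expected_ae_cost(iv$costs$ae_profile)
  expect_equal(
    cycle_cost(iv, 2),
    cpc * (course_cost(iv$schedule, iv$costs) + ae_iv +
             7 * indirect_cost_per_visit(iv$costs$indirect))
  )

  # hospital variant adds transport + productivity on each of 9 visits
  hosp_iv <- als_edaravone_spec("hospital")$arms$reference
  extra <- cycle_cost(hosp_iv, 2) -
    cpc * (course_cost(iv$schedule, iv$costs) + ae_iv)
  expect_equal(extra,
               cpc * 9 * (116.67 + indirect_cost_per_visit(iv$costs$indirect)))

  free <- toy_arm("reference", price = 0)
  expect_equal(cycle_cost(free, 1:10), rep(0, 10))
})

test_that("state utilities apply the comparator coefficient and zero at death", {
  spec <- als_base()
  u <- spec$utilities
  expect_equal(arm_utility("stage1", spec$arms$reference, u), 0.740)
  expect_equal(arm_utility("stage1", spec$arms$comparator, u), 0.740 * 1.021)
  expect_equal(arm_utility("death", spec$arms$reference, u), 0)
  expect_equal(arm_utility("death", spec$arms$comparator, u), 0)
  expect_error(arm_utility("stage9", spec$arms$reference, u), "stage9")
})

test_that("valuations scale linearly in prices and utilities", {
  spec <- als_base()
  tr <- run_trace(spec)
  base <- value_arm(tr, spec$arms$reference, spec)

  doubled <- spec
  cm <- doubled$arms$reference$costs
  cm$unit_drug_price <- 2 * cm$unit_drug_price
  cm$device_insertion_cost <- 2 * cm$device_insertion_cost
  cm$device_maintenance_cost <- 2 * cm$device_maintenance_cost
  cm$transport_cost_per_visit <- 2 * cm$transport_cost_per_visit
  cm$ae_profile$events$cost <- 2 * cm$ae_profile$events$cost
  cm$indirect$hourly_wage <- 2 * cm$indirect$hourly_wage
  doubled$arms$reference$costs <- cm
  expect_equal(value_arm(tr, doubled$arms$reference, doubled)$total_cost,
               2 * base$total_cost, tolerance = 1e-12)

  shrunk <- spec
  shrunk$utilities$stage_utilities <- 0.5 * shrunk$utilities$stage_utilities
  expect_equal(value_arm(tr, shrunk$arms$reference, shrunk)$total_qaly,
               0.5 * base$total_qaly, tolerance = 1e-12)
})

test_that("comparator/reference QALY ratio equals the coefficient exactly", {
  spec <- als_base()
  tr <- run_trace(spec)
  sl <- value_arm(tr, spec$arms$comparator, spec)
  iv <- value_arm(tr, spec$arms$reference, spec)
  expect_equal(sl$total_qaly / iv$total_qaly, 1.021, tolerance = 1e-12)

  g <- generate_model(generator_config(seed = 21))
  trg <- run_trace(g)
  ratio <- value_arm(trg, g$arms$comparator, g)$total_qaly /
    value_arm(trg, g$arms$reference, g)$total_qaly
  expect_equal(ratio, g$utilities$comparator_adjustment_coefficient,
               tolerance = 1e-12)
})

test_that("totals equal their per-cycle breakdown and respect bounds", {
  spec <- als_base()
  tr <- run_trace(spec)
  for (role in c("reference", "comparator")) {
    val <- value_arm(tr, spec$arms[[role]], spec)
    expect_equal(val$total_cost, sum(val$per_cycle$cost), tolerance = 1e-9)
    expect_equal(val$total_qaly, sum(val$per_cycle$qaly), tolerance = 1e-9)
    expect_true(all(val$per_cycle$cost >= 0))
  }

  # undiscounted life-years x max utility x coefficient bounds the QALYs
  undisc <- spec
  undisc$discount_rate_annual <- 0
  tru <- run_trace(undisc)
  ly <- sum(rowSums(tru$corrected_occupancy[, 1:4])) * 0.25
  val <- value_arm(tr, spec$arms$comparator, spec)
  expect_lte(val$total_qaly, ly * 0.740 * 1.021)
})

test_that("discounting more steeply strictly shrinks both totals", {
  spec <- als_base()
  rates <- c(0, 0.03, 0.05, 0.08)
  vals <- lapply(rates, function(r) {
    s <- spec
    s$discount_rate_annual <- r
    value_arm(run_trace(s), s$arms$reference, s)
  })
  costs <- vapply(vals, `[[`, numeric(1), "total_cost")
  qalys <- vapply(vals, `[[`, numeric(1), "total_qaly")
  expect_true(all(diff(costs) < 0))
  expect_true(all(diff(qalys) < 0))
})
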