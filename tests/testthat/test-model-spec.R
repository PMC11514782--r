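test_that("bundled ALS model loads with the documented structure", {
  spec <- als_base()
  expect_s3_class(spec, "cea_model_spec")
  expect_equal(spec$states, c("stage1", "stage2", "stage3", "stage4", "death"))
  expect_equal(spec$n_cycles, 80)
  expect_equal(spec$cycle_length_years, 0.25)
  expect_equal(spec$discount_rate_annual, 0.05)
  expect_equal(spec$start_age_years, 54)
  expect_equal(unname(spec$start_distribution), c(1, 0, 0, 0, 0))
})

test_that("bundled ALS model reproduces every published input exactly", {
  spec <- als_base()
  P <- unclass(spec$transition)
  expect_equal(unname(P["stage1", ]), c(0.677, 0.217, 0.064, 0.038, 0.004))
  expect_equal(unname(P["stage2", ]), c(0, 0.706, 0.213, 0.063, 0.018))
  expect_equal(unname(P["stage3", ]), c(0, 0, 0.830, 0.118, 0.052))
  expect_equal(unname(P["stage4", ]), c(0, 0, 0, 0.820, 0.180))
  expect_equal(unname(P["death", ]), c(0, 0, 0, 0, 1))

  u <- spec$utilities$stage_utilities
  expect_equal(unname(u), c(0.740, 0.630, 0.510, 0.370))
  expect_equal(spec$utilities$comparator_adjustment_coefficient, 1.021)

  sl <- spec$arms$comparator
  iv <- spec$arms$reference
  expect_equal(sl$costs$unit_drug_price, 130.00)
  expect_equal(iv$costs$unit_drug_price, 86.83)
  expect_equal(iv$costs$device_insertion_cost, 1847.96)
  expect_equal(iv$costs$device_maintenance_cost, 103.17)
  expect_equal(iv$costs$maintenance_events_per_course, 2)

  expect_equal(sl$costs$ae_profile$events$probability, c(0.0005, 0.0024, 0.0028))
  expect_equal(iv$costs$ae_profile$events$probability, c(0.0070, 0.0281, 0.0000))
  expect_equal(sl$costs$ae_profile$events$cost, c(20.00, 1985.50, 613.00))

  ind <- iv$costs$indirect
  expect_equal(ind$employment_rate, 0.15)
  expect_equal(ind$hours_lost_per_visit, 6.23)
  expect_equal(ind$hourly_wage, 18.44)

  expect_equal(sl$utility_route_factor, 0.99)
  expect_equal(iv$utility_route_factor, 0.97)
})

test_that("orientation handling transposes column-stochastic tables", {
  # as printed: columns index the from-state and sum to 1
  printed <- rbind(
    c(0.677, 0.000, 0.000, 0.000, 0.000),
    c(0.217, 0.706, 0.000, 0.000, 0.000),
    c(0.064, 0.213, 0.830, 0.000, 0.000),
    c(0.038, 0.063, 0.118, 0.820, 0.000),
    c(0.004, 0.018, 0.052, 0.180, 1.000)
  )
  P <- orient_transition_table(printed, "columns-are-from")
  expect_equal(unname(rowSums(P)), rep(1, 5))
  expect_equal(unname(unclass(P)[1, ]), c(0.677, 0.217, 0.064, 0.038, 0.004))

  # identity is its own transpose
  expect_equal(unclass(orient_transition_table(diag(3), "rows-are-from")),
               unclass(orient_transition_table(diag(3), "columns-are-from")))

  # already row-stochastic input passes through unchanged
  rs <- rbind(c(0.7, 0.3), c(0, 1))
  expect_equal(unname(unclass(orient_transition_table(rs, "rows-are-from"))), rs,
               ignore_attr = TRUE)

  # a non-stochastic table reports both sum vectors
  bad <- rbind(c(0.5, 0.3), c(0.2, 0.4))
  expect_error(orient_transition_table(bad, "rows-are-from"),
               "row sums.*column sums")
})

test_that("validation errors identify field and value", {
  spec <- als_base()

  broken <- spec
  P <- unclass(broken$transition)
  P["stage2", "stage3"] <- 0.5 # row no longer sums to 1
  class(P) <- class(broken$transition)
  broken$transition <- P
  expect_error(validate_model_spec(broken), "stage2")

  broken <- spec
  broken$arms$reference$costs$unit_drug_price <- -1
  expect_error(validate_model_spec(broken), "unit_drug_price.*-1")

  broken <- spec
  broken$start_distribution[1] <- 0.9
  expect_error(validate_model_spec(broken), "start_distribution")

  broken <- spec
  broken$utilities$stage_utilities[2] <- 0.75 # breaks monotonicity
  expect_error(validate_model_spec(broken), "decreasing")
})

test_that("unknown configuration keys are rejected by name", {
  cfg <- yaml::read_yaml(als_edaravone_path("base"))
  cfg$typo_key <- 1
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, f)
  expect_error(read_model_spec(f), "typo_key")

  cfg$typo_key <- NULL
  cfg$arms$reference$costs$unit_price <- 5
  yaml::write_yaml(cfg, f)
  expect_error(read_model_spec(f), "unit_price")
})

test_that("missing required fields are reported", {
  cfg <- yaml::read_yaml(als_edaravone_path("base"))
  cfg$transition <- NULL
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, f)
  expect_error(read_model_spec(f), "transition")
})

test_that("write/read round trip preserves every numeric field", {
  spec <- als_base()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(spec, f)
  spec2 <- read_model_spec(f)

  expect_equal(unclass(spec2$transition), unclass(spec$transition),
               tolerance = 1e-12)
  expect_equal(spec2$utilities, spec$utilities, tolerance = 1e-12)
  expect_equal(spec2$start_distribution, spec$start_distribution,
               tolerance = 1e-12)
  for (role in c("reference", "comparator")) {
    expect_equal(spec2$arms[[role]]$costs, spec$arms[[role]]$costs,
                 tolerance = 1e-12)
    expect_equal(spec2$arms[[role]]$schedule, spec$arms[[role]]$schedule,
                 tolerance = 1e-12)
  }

  # a generated model (non-round decimals) round-trips too
  g <- generate_model(generator_config(seed = 11))
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(g, f2)
  g2 <- read_model_spec(f2)
  expect_equal(unclass(g2$transition), unclass(g$transition), tolerance = 1e-12)
  expect_equal(g2$arms$reference$costs$unit_drug_price,
               g$arms$reference$costs$unit_drug_price, tolerance = 1e-12)
})

test_that("zero discount rate loads and yields undiscounted totals", {
  spec <- als_base()
  spec$discount_rate_annual <- 0
  tr <- run_trace(spec)
  val <- value_arm(tr, spec$arms$reference, spec)
  u <- c(spec$utilities$stage_utilities, death = 0)
  manual <- sum((tr$corrected_occupancy %*% u) * spec$cycle_length_years)
  expect_equal(val$total_qaly, manual, tolerance = 1e-12)
})

test_that("route factors 0.99/0.97 round to the reported coefficient", {
  expect_equal(utility_adjustment_coefficient(0.99, 0.97, digits = 3), 1.021)
})
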