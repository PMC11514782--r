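test_that("method-of-moments conversions match their closed forms", {
  g <- gamma_from_mean_se(100, 20)
  expect_equal(g$shape, 25)
  expect_equal(g$scale, 4)
  g2 <- gamma_from_mean_se(2600, 260)
  expect_equal(g2$shape, 100)
  expect_equal(g2$scale, 26)
  # round trip: implied moments equal the request exactly
  expect_equal(g$shape * g$scale, 100)
  expect_equal(g$shape * g$scale^2, 400)

  b <- beta_from_mean_se(0.5, 0.1)
  expect_equal(b$alpha, 12)
  expect_equal(b$beta, 12)
  b2 <- beta_from_mean_se(0.74, 0.074)
  nu <- 0.74 * 0.26 / 0.074^2 - 1
  expect_equal(b2$alpha, 0.74 * nu)
  expect_equal(b2$alpha / (b2$alpha + b2$beta), 0.74)

  # symmetric identity at mean 1/2
  b3 <- beta_from_mean_se(0.5, 0.23)
  expect_equal(b3$alpha, b3$beta)

  expect_error(gamma_from_mean_se(-1, 1), "mean > 0")
  expect_error(beta_from_mean_se(0.5, 0.6), "se\\^2 < mean\\(1-mean\\)")
})

test_that("samplers recover the requested moments", {
  set.seed(99)
  n <- 20000
  for (case in list(list("gamma", 2600, 260), list("beta", 0.74, 0.074),
                    list("gamma", 17.23, 1.723), list("beta", 0.217, 0.0217))) {
    x <- cohortcea:::draw_param(case[[1]], case[[2]], case[[3]], n = n)
    expect_equal(mean(x), case[[2]], tolerance = 0.02)
    expect_equal(stats::sd(x), case[[3]], tolerance = 0.03)
  }
})

test_that("the default distribution set pairs families with parameter types", {
  spec <- als_base()
  dists <- psa_distributions(spec)
  expect_true(all(dists$family[grepl("transition|utilities|probability|route",
                                     dists$parameter_id)] == "beta"))
  expect_true(all(dists$family[grepl("price|insertion|wage", dists$parameter_id)]
                  == "gamma"))
  # discount rate and the derived coefficient are never drawn directly
  expect_false("discount_rate_annual" %in% dists$parameter_id)
  expect_false("utilities.comparator_adjustment_coefficient" %in% dists$parameter_id)
  # beta dispersion stays inside the admissible bound
  beta_rows <- dists[dists$family == "beta", ]
  expect_true(all(beta_rows$se^2 < beta_rows$mean * (1 - beta_rows$mean)))
})

test_that("degenerate distributions reproduce the spec unchanged", {
  spec <- als_base()
  dists <- psa_distributions(spec, se_fraction = 0)
  set.seed(1)
  s <- sample_spec(spec, dists)
  expect_equal(unclass(s$spec$transition), unclass(spec$transition))
  expect_equal(s$spec$utilities, spec$utilities)
  expect_equal(s$spec$arms$reference$costs, spec$arms$reference$costs)

  psa <- run_psa(spec, dists = dists, n_draws = 1, seed = 5)
  base <- run_cua(spec)
  expect_equal(psa$draws$delta_cost, base$delta_cost, tolerance = 1e-12)
  expect_equal(psa$draws$delta_qaly, base$delta_qaly, tolerance = 1e-12)
})

test_that("sampling is deterministic under a fixed seed", {
  spec <- als_base()
  dists <- psa_distributions(spec)
  set.seed(42)
  a <- sample_spec(spec, dists)
  set.seed(42)
  b <- sample_spec(spec, dists)
  expect_identical(a$params, b$params)

  # sampled values respect their supports
  expect_true(all(unclass(a$spec$transition) >= 0 &
                  unclass(a$spec$transition) <= 1))
  expect_equal(unname(rowSums(unclass(a$spec$transition))), rep(1, 5),
               tolerance = 1e-12)
  expect_true(all(a$spec$utilities$stage_utilities > 0 &
                  a$spec$utilities$stage_utilities <= 1))
  expect_true(a$spec$arms$reference$costs$unit_drug_price > 0)
})

test_that("draw i does not depend on the total number of draws", {
  spec <- als_base()
  p5 <- run_psa(spec, n_draws = 5, seed = 3)
  p3 <- run_psa(spec, n_draws = 3, seed = 3)
  expect_equal(p5$draws[1:3, c("delta_cost", "delta_qaly")],
               p3$draws[, c("delta_cost", "delta_qaly")])
  # and reruns are bit-identical
  p3b <- run_psa(spec, n_draws = 3, seed = 3)
  expect_identical(p3$draws, p3b$draws)
  expect_identical(p3$summary, p3b$summary)
})

test_that("the CE-plane cloud behaves like the base case in the small", {
  spec <- als_base()
  psa <- run_psa(spec, n_draws = 200, seed = 1)
  s <- psa$summary
  expect_equal(s$prop_q1 + s$prop_q2 + s$prop_q3 + s$prop_q4, 1)
  expect_gt(s$prop_q1, 0.5) # mostly costlier and more effective
  coef_draws <- psa$param_draws[, "utilities.comparator_adjustment_coefficient"]
  expect_gt(mean(coef_draws < 1), 0) # the comparator can lose utility
  expect_s3_class(autoplot(psa, "plane"), "ggplot")
  expect_s3_class(autoplot(psa, "ceac"), "ggplot")
})

test_that("the acceptability curve equals the brute-force NMB fraction", {
  spec <- als_base()
  psa <- run_psa(spec, n_draws = 100, seed = 8)
  grid <- c(0, 1e5, 268074, 5e5)
  curve <- ceac(psa, grid)
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  for (j in seq_along(grid)) {
    hits <- 0
    for (i in seq_len(nrow(psa$draws))) {
      nmb_i <- grid[j] * psa$draws$delta_qaly[i] - psa$draws$delta_cost[i]
      if (nmb_i > 0) hits <- hits + 1
    }
    expect_equal(curve$probability[j], hits / nrow(psa$draws))
  }
  expect_equal(curve$probability[1], mean(psa$draws$delta_cost < 0))
  expect_error(ceac(psa, c(-1, 10)), ">= 0")
})
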