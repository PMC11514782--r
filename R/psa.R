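#' Method-of-moments gamma and beta parameterizations
#'
#' Converts a (mean, standard error) pair into the natural parameters of
#' the distribution conventionally assumed for that quantity in
#' probabilistic sensitivity analysis: gamma for costs (support > 0), beta
#' for probabilities and utilities (support \[0, 1\]).
#'
#' For the gamma, `shape = (mean/se)^2`, `scale = se^2/mean`, so the
#' resulting distribution has exactly the requested mean and variance. For
#' the beta, `nu = mean(1-mean)/se^2 - 1`, `alpha = mean * nu`,
#' `beta = (1-mean) * nu`; the se must satisfy `se^2 < mean(1-mean)` for
#' the moments to be attainable.
#'
#' @param mean Target mean (> 0; in (0,1) for the beta).
#' @param se Target standard error (> 0).
#' @return A named list: `shape`/`scale` for the gamma, `alpha`/`beta` for
#'   the beta.
#' @examples
#' gamma_from_mean_se(100, 20) # shape 25, scale 4
#' beta_from_mean_se(0.5, 0.1) # alpha 12, beta 12
#' @export
gamma_from_mean_se <- function(mean, se) {
  if (mean <= 0) stop("gamma requires mean > 0, got ", mean)
  if (se <= 0) stop("gamma requires se > 0, got ", se)
  list(shape = (mean / se)^2, scale = se^2 / mean)
}

#' @rdname gamma_from_mean_se
#' @export
beta_from_mean_se <- function(mean, se) {
  if (mean <= 0 || mean >= 1) stop("beta requires mean in (0, 1), got ", mean)
  if (se <= 0) stop("beta requires se > 0, got ", se)
  bound <- mean * (1 - mean)
  if (se^2 >= bound) {
    stop("se too large for a beta with mean ", mean,
         ": need se^2 < mean(1-mean) = ", format(bound, digits = 6),
         ", got se^2 = ", format(se^2, digits = 6))
  }
  nu <- bound / se^2 - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

# One draw (or n) from the PSA distribution of a parameter; se = 0 is the
# degenerate point mass at the mean.
draw_param <- function(family, mean, se, n = 1) {
  if (se == 0) return(rep(mean, n))
  switch(family,
    gamma = {
      g <- gamma_from_mean_se(mean, se)
      rgamma(n, shape = g$shape, scale = g$scale)
    },
    beta = {
      b <- beta_from_mean_se(mean, se)
      rbeta(n, b$alpha, b$beta)
    },
    stop("unknown distribution family '", family, "'")
  )
}

#' Default PSA distribution set for a model
#'
#' Assigns each sensitivity parameter ([spec_parameters()]) its
#' conventional distribution family: gamma for monetary quantities, beta
#' for probabilities and utilities. The comparator utility adjustment
#' coefficient is not drawn directly (its mean exceeds 1): instead the two
#' route factors are drawn from betas and the coefficient is scaled by
#' their ratio, so sampled coefficients below 1 arise naturally. The
#' discount rate is held fixed (its uncertainty is a policy choice explored
#' deterministically, not a sampling quantity).
#'
#' Dispersion defaults to `se_fraction` (10%) of the mean for every
#' parameter, overridable per row. For beta parameters the se is
#' additionally capped at `beta_se_cap` (30%) of the admissible bound
#' `sqrt(mean (1 - mean))`: a 10%-of-mean se on a parameter with mean 0.99
#' would sit at 99.5% of that bound, which parameterizes a two-point
#' distribution piling on 0 and 1 and produces numerically degenerate
#' draws. The cap only bites for means near 1 (in the bundled model, the
#' route factors); transition probabilities and stage utilities keep their
#' 10% se.
#'
#' @param spec A validated `cea_model_spec`.
#' @param se_fraction Standard error as a fraction of the mean.
#' @param beta_se_cap Cap on beta standard errors, as a fraction of
#'   `sqrt(mean (1 - mean))`.
#' @return A tibble with columns `parameter_id`, `family` (`"gamma"` or
#'   `"beta"`), `mean`, `se`.
#' @export
psa_distributions <- function(spec, se_fraction = 0.1, beta_se_cap = 0.3) {
  pars <- spec_parameters(spec)
  pars <- dplyr::filter(
    pars,
    .data$kind != "discount",
    .data$parameter_id != "utilities.comparator_adjustment_coefficient"
  )
  dists <- dplyr::transmute(
    pars,
    parameter_id = .data$parameter_id,
    family = ifelse(.data$clamp_unit, "beta", "gamma"),
    mean = .data$base_value,
    se = se_fraction * .data$base_value
  )
  route <- purrr::map_dfr(c("reference", "comparator"), function(role) {
    f <- spec$arms[[role]]$utility_route_factor
    tibble(
      parameter_id = paste("arms", role, "utility_route_factor", sep = "."),
      family = "beta", mean = f, se = se_fraction * f
    )
  })
  dists <- dplyr::bind_rows(dists, route)
  dplyr::mutate(
    dists,
    se = ifelse(
      .data$family == "beta",
      pmin(.data$se, beta_se_cap * sqrt(pmax(.data$mean * (1 - .data$mean), 0))),
      .data$se
    )
  )
}

#' Draw one perturbed model from a PSA distribution set
#'
#' Samples every parameter independently from its distribution, then
#' rebuilds the spec. Transition rows are reconstructed by drawing the
#' off-diagonal entries and setting the same-state (diagonal) entry to the
#' remainder; a row whose drawn entries exceed 1 is redrawn, up to
#' `max_attempts` times. If both arms' route factors are in the
#' distribution set, the comparator utility adjustment coefficient is
#' multiplied by the ratio of the factor draws to their means, so the
#' coefficient's sampling distribution is a ratio of betas centred on its
#' base value (and can fall below 1).
#'
#' Uses the current RNG state; seed management belongs to the caller
#' ([run_psa()] derives one substream per draw).
#'
#' @param spec A validated `cea_model_spec`.
#' @param dists A distribution set from [psa_distributions()].
#' @param max_attempts Redraw cap per transition row.
#' @return A list: `spec` (the perturbed model) and `params` (named vector
#'   of the sampled parameter values, including the derived coefficient).
#' @export
sample_spec <- function(spec, dists, max_attempts = 100) {
  drawn <- numeric(0)

  is_trans <- startsWith(dists$parameter_id, "transition.")
  plain <- dists[!is_trans, ]
  route_ids <- paste("arms", c("reference", "comparator"),
                     "utility_route_factor", sep = ".")

  out <- spec
  for (i in seq_len(nrow(plain))) {
    id <- plain$parameter_id[i]
    v <- draw_param(plain$family[i], plain$mean[i], plain$se[i])
    drawn[[id]] <- v
    if (!(id %in% route_ids)) {
      out <- spec_set_param(out, id, v)$spec
    }
  }

  if (all(route_ids %in% plain$parameter_id)) {
    means <- setNames(plain$mean, plain$parameter_id)
    ratio <- (drawn[[route_ids[2]]] / means[[route_ids[2]]]) /
             (drawn[[route_ids[1]]] / means[[route_ids[1]]])
    coef <- spec$utilities$comparator_adjustment_coefficient * ratio
    out$utilities$comparator_adjustment_coefficient <- coef
    out$arms$reference$utility_route_factor <- drawn[[route_ids[1]]]
    out$arms$comparator$utility_route_factor <- drawn[[route_ids[2]]]
    drawn[["utilities.comparator_adjustment_coefficient"]] <- coef
  }

  tr <- dists[is_trans, ]
  if (nrow(tr)) {
    parts <- strsplit(tr$parameter_id, ".", fixed = TRUE)
    tr$from <- vapply(parts, `[[`, character(1), 2)
    tr$to <- vapply(parts, `[[`, character(1), 3)
    P <- unclass(out$transition)
    for (from in unique(tr$from)) {
      rows <- tr[tr$from == from, ]
      for (attempt in seq_len(max_attempts)) {
        vals <- vapply(seq_len(nrow(rows)), function(j) {
          draw_param(rows$family[j], rows$mean[j], rows$se[j])
        }, numeric(1))
        rem <- P[from, from] + sum(rows$mean) - sum(vals)
        if (rem >= 0) break
        vals <- NULL
      }
      if (is.null(vals)) {
        stop("transition row '", from, "' infeasible after ", max_attempts,
             " redraw attempts (drawn off-diagonal mass exceeds 1)")
      }
      P[from, rows$to] <- vals
      P[from, from] <- rem
      drawn[paste("transition", from, rows$to, sep = ".")] <- vals
    }
    class(P) <- class(out$transition)
    out$transition <- P
  }

  list(spec = out, params = drawn)
}

quadrant_of <- function(dq, dc) {
  # CE plane: x = incremental effect, y = incremental cost. Boundary points
  # (a zero difference) are counted with the non-positive side so the four
  # proportions always partition the draws.
  dplyr::case_when(
    dq > 0 & dc > 0 ~ "I",
    dq <= 0 & dc > 0 ~ "II",
    dq <= 0 & dc <= 0 ~ "III",
    TRUE ~ "IV"
  )
}

psa_draw_seed <- function(seed, i) {
  (seed %% 16384) * 131072 + (i %% 131072)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo re-evaluation of the model: each draw samples every
#' parameter from its PSA distribution ([sample_spec()]), reruns the
#' trace-valuation-incremental pipeline, and records the incremental cost
#' and QALY pair. Summaries are computed from the resulting
#' cost-effectiveness plane cloud: quadrant proportions, means, percentile
#' 95% intervals, and the acceptability curve. Ratio statistics over draws
#' are deliberately avoided (the mean of ICERs is unstable whenever the
#' QALY difference crosses zero); the cloud and the CEAC carry the
#' uncertainty statement.
#'
#' Each draw uses its own RNG substream derived from `seed` and the draw
#' counter, so draw i is identical regardless of `n_draws` and reruns are
#' bit-identical.
#'
#' @param spec A validated `cea_model_spec`.
#' @param dists Distribution set, default [psa_distributions()].
#' @param n_draws Number of Monte Carlo draws (>= 1).
#' @param seed Integer seed governing all draws.
#' @param wtp Willingness-to-pay threshold for the headline probability of
#'   cost-effectiveness.
#' @param wtp_grid Thresholds for the acceptability curve; default an
#'   81-point grid from 0 to twice `wtp`.
#' @return A `cea_psa`: `draws` tibble (draw, delta_cost, delta_qaly,
#'   quadrant), `param_draws` matrix, `ceac` tibble, and a `summary`
#'   one-row tibble.
#' @examples
#' \donttest{
#' psa <- run_psa(als_edaravone_spec(), n_draws = 200, seed = 1)
#' glance(psa)
#' }
#' @export
run_psa <- function(spec, dists = psa_distributions(spec),
                    n_draws = 5000, seed = 1L,
                    wtp = .default_wtp, wtp_grid = NULL) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  wtp_grid <- wtp_grid %||% seq(0, 2 * wtp, length.out = 81)

  draws <- vector("list", n_draws)
  params <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    set.seed(psa_draw_seed(seed, i))
    s <- sample_spec(spec, dists)
    r <- run_cua(s$spec, wtp = wtp)
    draws[[i]] <- c(delta_cost = r$delta_cost, delta_qaly = r$delta_qaly)
    params[[i]] <- s$params
  }
  cloud <- as_tibble(do.call(rbind, draws))
  cloud <- dplyr::mutate(
    cloud,
    draw = seq_len(n_draws), .before = 1
  )
  cloud$quadrant <- quadrant_of(cloud$delta_qaly, cloud$delta_cost)
  param_draws <- do.call(rbind, params)

  ceac_tbl <- ceac(cloud, wtp_grid)
  qprop <- prop.table(table(factor(cloud$quadrant, levels = c("I", "II", "III", "IV"))))
  ci <- function(x) quantile(x, c(0.025, 0.975), names = FALSE)
  ci_dc <- ci(cloud$delta_cost); ci_dq <- ci(cloud$delta_qaly)
  summary <- tibble(
    n_draws = n_draws, seed = seed, wtp = wtp,
    mean_delta_cost = mean(cloud$delta_cost),
    mean_delta_qaly = mean(cloud$delta_qaly),
    delta_cost_lo = ci_dc[1], delta_cost_hi = ci_dc[2],
    delta_qaly_lo = ci_dq[1], delta_qaly_hi = ci_dq[2],
    prop_q1 = qprop[["I"]], prop_q2 = qprop[["II"]],
    prop_q3 = qprop[["III"]], prop_q4 = qprop[["IV"]],
    prob_ce_at_wtp = mean(wtp * cloud$delta_qaly - cloud$delta_cost > 0)
  )
  structure(
    list(draws = cloud, param_draws = param_draws, ceac = ceac_tbl,
         summary = summary, wtp = wtp, seed = seed, n_draws = n_draws),
    class = "cea_psa"
  )
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the fraction of draws whose net
#' monetary benefit `wtp * delta_qaly - delta_cost` is positive, i.e. the
#' probability that the comparator is cost-effective at that threshold.
#'
#' @param x A `cea_psa` or a data frame with `delta_cost` and `delta_qaly`
#'   columns.
#' @param wtp_grid Non-negative thresholds.
#' @return A tibble (wtp, probability).
#' @export
ceac <- function(x, wtp_grid) {
  if (inherits(x, "cea_psa")) x <- x$draws
  if (any(wtp_grid < 0)) stop("wtp_grid must be >= 0")
  if (!nrow(x)) stop("no draws supplied")
  prob <- vapply(wtp_grid, function(w) {
    mean(w * x$delta_qaly - x$delta_cost > 0)
  }, numeric(1))
  tibble(wtp = wtp_grid, probability = prob)
}

#' @export
print.cea_psa <- function(x, ...) {
  s <- x$summary
  cat("<cea_psa> ", x$n_draws, " draws (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  mean incremental: cost %.2f, QALYs %.4f\n",
              s$mean_delta_cost, s$mean_delta_qaly))
  cat(sprintf("  95%% CI cost [%.2f, %.2f]; QALYs [%.4f, %.4f]\n",
              s$delta_cost_lo, s$delta_cost_hi, s$delta_qaly_lo, s$delta_qaly_hi))
  cat(sprintf("  quadrants I/II/III/IV: %.1f%% / %.1f%% / %.1f%% / %.1f%%\n",
              100 * s$prop_q1, 100 * s$prop_q2, 100 * s$prop_q3, 100 * s$prop_q4))
  cat(sprintf("  P(cost-effective at WTP %.0f) = %.2f%%\n",
              s$wtp, 100 * s$prob_ce_at_wtp))
  invisible(x)
}

#' @method tidy cea_psa
#' @export
tidy.cea_psa <- function(x, ...) x$draws

#' @method glance cea_psa
#' @export
glance.cea_psa <- function(x, ...) x$summary

#' Plot a probabilistic sensitivity analysis
#'
#' `type = "plane"` draws the cost-effectiveness plane (one point per draw,
#' dashed line at the WTP threshold); `type = "ceac"` the acceptability
#' curve.
#'
#' @param object A `cea_psa`.
#' @param type `"plane"` or `"ceac"`.
#' @param ... Unused.
#' @method autoplot cea_psa
#' @export
autoplot.cea_psa <- function(object, type = c("plane", "ceac"), ...) {
  type <- match.arg(type)
  if (type == "plane") {
    ggplot2::ggplot(object$draws,
                    ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
      ggplot2::geom_point(alpha = 0.3, size = 0.8) +
      ggplot2::geom_hline(yintercept = 0) +
      ggplot2::geom_vline(xintercept = 0) +
      ggplot2::geom_abline(slope = object$wtp, intercept = 0, linetype = 2) +
      ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$ceac,
                    ggplot2::aes(x = .data$wtp, y = .data$probability)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = object$wtp, linetype = 2) +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(x = "Willingness to pay per QALY",
                    y = "P(comparator cost-effective)") +
      ggplot2::theme_minimal()
  }
}

#' Export PSA artifacts to CSV
#'
#' Writes the cost-effectiveness plane cloud (`ce_plane.csv`: draw,
#' delta_qaly, delta_cost) and the acceptability curve (`ceac.csv`: wtp,
#' probability) into a directory.
#'
#' @param psa A `cea_psa`.
#' @param dir Output directory (created if needed).
#' @return The two file paths, invisibly.
#' @export
export_psa <- function(psa, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  plane <- file.path(dir, "ce_plane.csv")
  curve <- file.path(dir, "ceac.csv")
  readr::write_csv(psa$draws[, c("draw", "delta_qaly", "delta_cost")], plane)
  readr::write_csv(psa$ceac, curve)
  invisible(c(plane, curve))
}
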