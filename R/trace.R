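#' Per-cycle discount weight
#'
#' Converts an annual discount rate into the weight applied to value accrued
#' in a given cycle. Under the default `"first_cycle"` convention cycle 1 is
#' undiscounted and a full year's discount has accrued after
#' `1 / cycle_length_years` cycles:
#' \deqn{w_k = (1 + r)^{-L (k - 1)}}
#' with annual rate \eqn{r} and cycle length \eqn{L} years. Under `"zero"`
#' the exponent is \eqn{-Lk}.
#'
#' @param cycle_index Cycle number(s), 1-based; vectorized.
#' @param annual_rate Annual discount rate (>= 0).
#' @param cycle_length_years Cycle length as a fraction of a year.
#' @param from Discount-timing convention, `"first_cycle"` or `"zero"`.
#' @return Numeric vector of weights in (0, 1].
#' @examples
#' discount_factor(1, 0.05, 0.25) # 1: first cycle undiscounted
#' discount_factor(5, 0.05, 0.25) # one elapsed year, 1/1.05
#' @export
discount_factor <- function(cycle_index, annual_rate, cycle_length_years,
                            from = c("first_cycle", "zero")) {
  from <- match.arg(from)
  if (any(cycle_index < 1)) stop("cycle_index must be >= 1")
  if (annual_rate < 0) stop("annual_rate must be >= 0, got ", annual_rate)
  elapsed <- if (from == "first_cycle") cycle_index - 1 else cycle_index
  (1 + annual_rate)^(-cycle_length_years * elapsed)
}

new_trace <- function(occupancy, spec) {
  n <- nrow(occupancy) - 1L
  ab <- length(spec$states)
  corrected <- (occupancy[seq_len(n), , drop = FALSE] +
                occupancy[seq_len(n) + 1L, , drop = FALSE]) / 2
  rownames(occupancy) <- 0:n
  rownames(corrected) <- seq_len(n)
  structure(
    list(
      occupancy = occupancy,
      corrected_occupancy = corrected,
      death_cdf = unname(occupancy[seq_len(n) + 1L, ab]),
      state_names = spec$states,
      absorbing_state = spec$absorbing_state,
      cycle_length_years = spec$cycle_length_years,
      n_cycles = n
    ),
    class = "cea_trace"
  )
}

#' Run the cohort trace
#'
#' Propagates a unit cohort through the transition kernel:
#' `occupancy[k] = occupancy[k - 1] %*% P` for cycles 1..n, starting from
#' the spec's start distribution at cycle 0. Person-time per cycle is
#' half-cycle corrected in the life-table (trapezoid) sense: the corrected
#' occupancy of cycle k is the mean of its beginning- and end-of-cycle
#' occupancy. The death CDF is the absorbing-state column.
#'
#' @param spec A validated `cea_model_spec`.
#' @return A `cea_trace` with elements `occupancy` (cycles 0..n by state),
#'   `corrected_occupancy` (cycles 1..n), and `death_cdf`.
#' @examples
#' tr <- run_trace(als_edaravone_spec())
#' tr$occupancy["1", ] # one-cycle-ahead distribution from stage 1
#' @export
run_trace <- function(spec) {
  P <- unclass(spec$transition)
  n <- spec$n_cycles
  occ <- matrix(0, n + 1L, length(spec$states),
                dimnames = list(NULL, spec$states))
  occ[1L, ] <- spec$start_distribution
  for (k in seq_len(n)) {
    occ[k + 1L, ] <- occ[k, ] %*% P
  }
  new_trace(occ, spec)
}

#' @export
print.cea_trace <- function(x, ...) {
  cat("<cea_trace> ", x$n_cycles, " cycles x ", length(x$state_names),
      " states (", x$cycle_length_years, " y/cycle)\n", sep = "")
  cat(sprintf("  death CDF at horizon: %.6f\n", x$death_cdf[x$n_cycles]))
  invisible(x)
}

#' @method as_tibble cea_trace
#' @export
as_tibble.cea_trace <- function(x, ...) {
  occ <- as_tibble(x$occupancy)
  dplyr::mutate(occ,
    cycle = 0:x$n_cycles,
    death_cdf = c(x$occupancy[1, length(x$state_names)], x$death_cdf),
    .before = 1
  )
}

#' @method tidy cea_trace
#' @export
tidy.cea_trace <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(dplyr::all_of(x$state_names),
                        names_to = "state", values_to = "occupancy") |>
    dplyr::mutate(state = factor(.data$state, levels = x$state_names))
}

#' @method autoplot cea_trace
#' @export
autoplot.cea_trace <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$cycle * object$cycle_length_years,
      y = .data$occupancy, fill = .data$state
    )) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Years", y = "Cohort fraction", fill = "State") +
    ggplot2::theme_minimal()
}

# linear interpolation of the death CDF at arbitrary times (years);
# cdf(0) = starting absorbing mass (normally 0)
interp_cdf <- function(trace, years) {
  times <- c(0, seq_len(trace$n_cycles)) * trace$cycle_length_years
  cdf <- c(trace$occupancy[1, length(trace$state_names)], trace$death_cdf)
  stats::approx(times, cdf, xout = years, rule = 2)$y
}

#' Survival summaries of a cohort trace
#'
#' Deterministic functionals of the death CDF: survival quantiles (by linear
#' interpolation between cycle boundaries) and the fraction of the cohort
#' dying within given time windows, computed as
#' `cdf(b) - cdf(a)` for a window `[a, b)` in years.
#'
#' @param trace A `cea_trace`.
#' @param probs Quantile levels; default the median.
#' @param windows List of `c(from, to)` windows in years; must lie inside
#'   the model horizon.
#' @return A list with tibbles `quantiles` (prob, years; `NA` when the CDF
#'   never reaches the level) and `windows` (from_years, to_years, fraction).
#' @examples
#' survival_quantiles(run_trace(als_edaravone_spec()), windows = list(c(3, 5)))
#' @export
survival_quantiles <- function(trace, probs = 0.5, windows = list()) {
  horizon <- trace$n_cycles * trace$cycle_length_years
  times <- c(0, seq_len(trace$n_cycles)) * trace$cycle_length_years
  cdf <- c(trace$occupancy[1, length(trace$state_names)], trace$death_cdf)
  q <- vapply(probs, function(p) {
    k <- which(cdf >= p)[1]
    if (is.na(k)) return(NA_real_)
    if (k == 1L) return(times[1])
    # invert between the bracketing cycle boundaries
    t0 <- times[k - 1]; t1 <- times[k]; c0 <- cdf[k - 1]; c1 <- cdf[k]
    if (c1 == c0) t1 else t0 + (p - c0) / (c1 - c0) * (t1 - t0)
  }, numeric(1))
  win <- purrr::map_dfr(windows, function(w) {
    if (w[2] < w[1]) stop("window must have from <= to")
    if (w[2] > horizon + 1e-12) {
      stop("window [", w[1], ", ", w[2], "] y exceeds the ", horizon, " y horizon")
    }
    tibble(
      from_years = w[1], to_years = w[2],
      fraction = interp_cdf(trace, w[2]) - interp_cdf(trace, w[1])
    )
  })
  list(quantiles = tibble(prob = probs, years = q), windows = win)
}

#' Export a cohort trace to CSV
#'
#' Columns: cycle, occupancy per state, death CDF, and half-cycle-corrected
#' person-time per state (`pt_<state>`, defined for cycles 1..n).
#'
#' @param trace A `cea_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_trace <- function(trace, path) {
  wide <- as_tibble(trace)
  pt <- as_tibble(rbind(NA, trace$corrected_occupancy))
  names(pt) <- paste0("pt_", trace$state_names)
  readr::write_csv(dplyr::bind_cols(wide, pt), path)
  invisible(path)
}
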