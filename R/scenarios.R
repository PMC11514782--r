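#' Define a named scenario transformation
#'
#' A scenario is a small set of optional overrides applied to a base model:
#' a replacement comparator utility adjustment coefficient, per-arm
#' administration settings, a transport cost, and per-arm visit-policy
#' counts. Applying an empty scenario is the identity.
#'
#' @param name Scenario label.
#' @param utility_coefficient_override Replacement (not multiplier) for the
#'   comparator utility adjustment coefficient.
#' @param setting_overrides Named list, arm role -> `"home"`/`"hospital"`.
#' @param transport_cost_override Per-visit transport cost applied to arms
#'   whose setting is overridden to `"hospital"`.
#' @param visit_policy_overrides Named list, arm role -> list of
#'   [visit_policy()] fields.
#' @return A `cea_scenario`.
#' @seealso [apply_scenario()], [hospital_iv_scenario()]
#' @export
scenario_def <- function(name,
                         utility_coefficient_override = NULL,
                         setting_overrides = NULL,
                         transport_cost_override = NULL,
                         visit_policy_overrides = NULL) {
  structure(
    list(
      name = name,
      utility_coefficient_override = utility_coefficient_override,
      setting_overrides = setting_overrides,
      transport_cost_override = transport_cost_override,
      visit_policy_overrides = visit_policy_overrides
    ),
    class = "cea_scenario"
  )
}

#' The bundled hospital-administration scenario
#'
#' Sublingual therapy stays at home; the intravenous (reference) arm moves
#' to hospital administration. The setting utility coefficient 1.147
#' replaces the base-case route coefficient (the difference between home
#' and hospital care dominates the route-of-administration difference, so
#' the coefficients do not stack), and each course incurs hospital visits
#' that carry a 116.67 CNY round-trip transport cost plus the per-visit
#' productivity loss.
#'
#' @param visits_per_course Hospital visits per treatment course for the
#'   reference arm (both transport and productivity loss apply to each).
#' @return A `cea_scenario`.
#' @export
hospital_iv_scenario <- function(visits_per_course = 9) {
  scenario_def(
    name = "hospital_iv",
    utility_coefficient_override = 1.147,
    setting_overrides = list(reference = "hospital"),
    transport_cost_override = 116.67,
    visit_policy_overrides = list(
      reference = list(
        productivity_visits_per_course = visits_per_course,
        transport_visits_per_course = visits_per_course
      )
    )
  )
}

#' Apply a scenario to a model specification
#'
#' Pure transformation: returns a new validated spec, leaves the input
#' untouched, and is idempotent for a given scenario.
#'
#' @param spec A validated `cea_model_spec`.
#' @param scenario A `cea_scenario`.
#' @return The transformed, revalidated `cea_model_spec`.
#' @examples
#' hosp <- apply_scenario(als_edaravone_spec(), hospital_iv_scenario())
#' run_cua(hosp)
#' @export
apply_scenario <- function(spec, scenario) {
  stopifnot(inherits(scenario, "cea_scenario"))
  out <- spec
  if (!is.null(scenario$utility_coefficient_override)) {
    out$utilities$comparator_adjustment_coefficient <-
      scenario$utility_coefficient_override
  }
  for (role in names(scenario$setting_overrides)) {
    setting <- match.arg(scenario$setting_overrides[[role]], c("home", "hospital"))
    out$arms[[role]]$administration_setting <- setting
    if (setting == "hospital" && !is.null(scenario$transport_cost_override)) {
      out$arms[[role]]$costs$transport_cost_per_visit <-
        scenario$transport_cost_override
    }
  }
  for (role in names(scenario$visit_policy_overrides)) {
    ov <- scenario$visit_policy_overrides[[role]]
    vp <- out$arms[[role]]$costs$visit_policy
    for (f in names(ov)) {
      if (!f %in% names(vp)) {
        stop("unknown visit_policy field '", f, "' in scenario '",
             scenario$name, "'")
      }
      vp[[f]] <- ov[[f]]
    }
    out$arms[[role]]$costs$visit_policy <- vp
  }
  out$name <- paste0(spec$name, " [", scenario$name, "]")
  validate_model_spec(out)
}
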