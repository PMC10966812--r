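# Parameter data model: scenario settings, per-arm cost bundles, utility
# series and next-line treatment mixtures, loaded from YAML/JSON scenario
# files. Monetary amounts are euros (or the scenario's currency) at full
# precision; rounding happens only in the reporting layer.

EQ5D_UTILITY_MIN <- -0.59  # lower bound of the EQ-5D index value set

#' Scenario settings
#'
#' Country-level settings of a cost-utility scenario: discount rates,
#' willingness-to-pay threshold, cohort baseline age and cycle length.
#' `friction_period_days` is provenance metadata for the productivity-loss
#' inputs; productivity costs enter the model as euro amounts and are never
#' recomputed from the friction period.
#'
#' @param country_label,currency_label Text labels.
#' @param discount_rate_costs,discount_rate_effects Annual rates in `[0, 1)`.
#' @param wtp_threshold Willingness to pay, currency per QALY, `>= 0`.
#' @param baseline_age_years Cohort age at model start (the model stops at
#'   age 100).
#' @param cycle_length_years Cycle length in years (default 0.25 = 3 months).
#' @param friction_period_days Metadata, days.
#' @return A list of class `cua_scenario`.
#' @export
scenario_settings <- function(country_label, discount_rate_costs,
                              discount_rate_effects, wtp_threshold,
                              baseline_age_years,
                              cycle_length_years = 0.25,
                              friction_period_days = NA_real_,
                              currency_label = "EUR") {
  for (r in c(discount_rate_costs, discount_rate_effects)) {
    if (!is.numeric(r) || r < 0 || r >= 1)
      stop("discount rates must lie in [0, 1), got ", r)
  }
  if (wtp_threshold < 0) stop("wtp_threshold must be >= 0")
  if (cycle_length_years <= 0) stop("cycle_length_years must be > 0")
  if (!is.numeric(baseline_age_years) || baseline_age_years <= 0 ||
      baseline_age_years >= 100)
    stop("baseline_age_years must lie in (0, 100)")
  structure(list(
    country_label = country_label,
    discount_rate_costs = discount_rate_costs,
    discount_rate_effects = discount_rate_effects,
    wtp_threshold = wtp_threshold,
    baseline_age_years = baseline_age_years,
    cycle_length_years = cycle_length_years,
    friction_period_days = friction_period_days,
    currency_label = currency_label
  ), class = "cua_scenario")
}

#' Cost bundle
#'
#' One arm's schedule of costs of a given perspective (treatment/healthcare
#' or societal): one-time items applied at model start, a first-cycle
#' amount, a recurring per-cycle amount (which may stop after
#' `follow_up_stop_years`, e.g. follow-up visits assumed to cease at 5
#' years), an annual amount (e.g. copay) charged pro rata per cycle, and a
#' terminal-care cost attached to each incident death.
#'
#' @param one_time_items Named numeric vector (or named list) of amounts
#'   applied once at model start.
#' @param first_cycle_amount Amount in the first cycle only.
#' @param per_cycle_amount Amount per 3-month cycle while alive, from the
#'   second cycle on.
#' @param annual_amount Amount per year while alive.
#' @param death_cost Amount per incident death.
#' @param follow_up_stop_years Years after which the per-cycle amount
#'   ceases; `Inf` (default) never stops.
#' @return A list of class `cost_bundle`.
#' @export
cost_bundle <- function(one_time_items = numeric(), first_cycle_amount = 0,
                        per_cycle_amount = 0, annual_amount = 0,
                        death_cost = 0, follow_up_stop_years = Inf) {
  one_time_items <- unlist(one_time_items)
  if (is.null(one_time_items)) one_time_items <- numeric()
  amounts <- c(one_time_items, first_cycle_amount, per_cycle_amount,
               annual_amount, death_cost)
  if (any(amounts < 0)) stop("cost amounts must be >= 0")
  if (follow_up_stop_years <= 0) stop("follow_up_stop_years must be > 0")
  structure(list(
    one_time_items = one_time_items,
    first_cycle_amount = first_cycle_amount,
    per_cycle_amount = per_cycle_amount,
    annual_amount = annual_amount,
    death_cost = death_cost,
    follow_up_stop_years = follow_up_stop_years
  ), class = "cost_bundle")
}

#' Next-line treatment option
#'
#' One component of the mixture of treatments patients switch to on
#' progression: a per-patient course cost, a per-cycle health-state
#' utility, and the proportion of progressing patients receiving it.
#'
#' @param label Text label.
#' @param course_cost Cost per patient of the full course, `>= 0`.
#' @param utility Per-cycle utility in `[-0.59, 1]`, or `NA` if unknown
#'   (rejected by [next_line_expected_utility()]).
#' @param proportion Fraction of progressing patients, in `[0, 1]`.
#' @return A list of class `next_line_option`.
#' @export
next_line_option <- function(label, course_cost, utility, proportion) {
  if (course_cost < 0) stop("course_cost must be >= 0 for option ", label)
  if (proportion < 0 || proportion > 1)
    stop("proportion must lie in [0, 1] for option ", label,
         ", got ", proportion)
  if (!is.na(utility) && (utility < EQ5D_UTILITY_MIN || utility > 1))
    stop("utility must lie in [", EQ5D_UTILITY_MIN, ", 1] for option ",
         label, ", got ", utility)
  structure(list(label = label, course_cost = course_cost,
                 utility = utility, proportion = proportion),
            class = "next_line_option")
}

validate_mixture <- function(mix) {
  if (length(mix) == 0L) stop("next-line mixture is empty")
  stopifnot(all(vapply(mix, inherits, logical(1), "next_line_option")))
  total <- sum(vapply(mix, `[[`, numeric(1), "proportion"))
  if (abs(total - 1) > 1e-9)
    stop("next-line mixture proportions must sum to 1, got ",
         format(total, digits = 10))
  invisible(mix)
}

#' Expected per-patient cost of a next-line mixture
#'
#' Proportion-weighted mean of the component course costs.
#'
#' @param mix List of [next_line_option()]s whose proportions sum to 1.
#' @return Expected cost, currency units.
#' @export
next_line_expected_cost <- function(mix) {
  validate_mixture(mix)
  sum(vapply(mix, function(o) o$proportion * o$course_cost, numeric(1)))
}

#' Expected per-cycle utility of a next-line mixture
#'
#' Proportion-weighted mean of the component utilities. Every component
#' must carry a utility; a missing one is reported by label rather than
#' silently dropped.
#'
#' @inheritParams next_line_expected_cost
#' @return Expected utility.
#' @export
next_line_expected_utility <- function(mix) {
  validate_mixture(mix)
  miss <- vapply(mix, function(o) is.na(o$utility), logical(1))
  if (any(miss))
    stop("next-line option(s) without a utility: ",
         paste(vapply(mix[miss], `[[`, character(1), "label"),
               collapse = ", "))
  sum(vapply(mix, function(o) o$proportion * o$utility, numeric(1)))
}

#' Progression-free utility series
#'
#' EQ-5D utilities observed at scheduled visits while progression-free,
#' used as a step function over the model grid. `pre_death_utility` is the
#' utility applied to the cycle in which death occurs (the trial applied a
#' terminal-decline utility to the 3 months prior to death).
#'
#' @param timepoints Visit months, strictly increasing.
#' @param values Utilities in `[-0.59, 1]`, one per timepoint.
#' @param carry_forward If `TRUE` (default) the last value extends beyond
#'   the last timepoint; if `FALSE`, evaluation beyond it is an error.
#' @param pre_death_utility Utility of the cycle containing death.
#' @return A list of class `utility_series`.
#' @export
utility_series <- function(timepoints, values, carry_forward = TRUE,
                           pre_death_utility = 0.665) {
  stopifnot(length(timepoints) == length(values), length(values) >= 1L)
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("utility timepoints must be strictly increasing")
  if (any(values < EQ5D_UTILITY_MIN | values > 1))
    stop("utility values must lie in [", EQ5D_UTILITY_MIN, ", 1]")
  if (pre_death_utility < EQ5D_UTILITY_MIN || pre_death_utility > 1)
    stop("pre_death_utility must lie in [", EQ5D_UTILITY_MIN, ", 1]")
  structure(list(timepoints = timepoints, values = values,
                 carry_forward = carry_forward,
                 pre_death_utility = pre_death_utility),
            class = "utility_series")
}

#' Utility at a given month
#'
#' Step-function lookup: the value at the latest timepoint at or before
#' `month`; before the first timepoint the first value applies.
#'
#' @param series A [utility_series()].
#' @param month Months, vectorised.
#' @return Utilities.
#' @export
utility_at <- function(series, month) {
  tp <- series$timepoints
  if (!series$carry_forward && any(month > tp[length(tp)]))
    stop("utility requested at month ", max(month),
         " beyond the series end and carry_forward is FALSE")
  idx <- pmax(findInterval(month, tp), 1L)
  series$values[idx]
}

#' Treatment-arm model
#'
#' Bundles everything one arm needs: PFS and OS survival laws, treatment
#' and societal cost schedules, the progression-free utility series and the
#' next-line treatment mixture applied on progression.
#'
#' @param name Arm label.
#' @param pfs_curve,os_curve [parametric_survival()] objects.
#' @param treatment_costs,societal_costs [cost_bundle()]s.
#' @param pfs_utilities A [utility_series()].
#' @param next_line_mix List of [next_line_option()]s summing to 1.
#' @return A list of class `arm_model`.
#' @export
arm_model <- function(name, pfs_curve, os_curve, treatment_costs,
                      societal_costs, pfs_utilities, next_line_mix) {
  stopifnot(inherits(pfs_curve, "parsurv"), inherits(os_curve, "parsurv"),
            inherits(treatment_costs, "cost_bundle"),
            inherits(societal_costs, "cost_bundle"),
            inherits(pfs_utilities, "utility_series"))
  validate_mixture(next_line_mix)
  structure(list(name = name, pfs_curve = pfs_curve, os_curve = os_curve,
                 treatment_costs = treatment_costs,
                 societal_costs = societal_costs,
                 pfs_utilities = pfs_utilities,
                 next_line_mix = next_line_mix),
            class = "arm_model")
}

.require_fields <- function(x, fields, where) {
  miss <- setdiff(fields, names(x))
  if (length(miss))
    stop("scenario file: missing required field(s) in ", where, ": ",
         paste(miss, collapse = ", "))
  invisible(x)
}

.parse_curve <- function(spec, dir, where) {
  .require_fields(spec, "family", where)
  if (!is.null(spec$alpha)) {
    parametric_survival(spec$family, spec$alpha,
                        if (is.null(spec$beta)) NA_real_ else spec$beta,
                        fitted_from = "specified")
  } else if (!is.null(spec$points_csv)) {
    path <- spec$points_csv
    if (!file.exists(path)) path <- file.path(dir, spec$points_csv)
    if (!file.exists(path))
      stop("survival points CSV not found: ", spec$points_csv)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!is.null(spec$arm) && "arm" %in% names(df))
      df <- df[df$arm == spec$arm, , drop = FALSE]
    if (!is.null(spec$endpoint) && "endpoint" %in% names(df))
      df <- df[df$endpoint == spec$endpoint, , drop = FALSE]
    if (!nrow(df)) stop("no survival points left after filtering for ", where)
    pts <- survival_points(df$time_months, df$survival_probability)
    fit_points(pts, spec$family)
  } else {
    stop("curve ", where, " needs either alpha/beta or points_csv")
  }
}

.parse_bundle <- function(b, where) {
  if (is.null(b)) b <- list()
  cost_bundle(
    one_time_items = if (is.null(b$one_time_items)) numeric()
                     else unlist(b$one_time_items),
    first_cycle_amount = b$first_cycle_amount %||% 0,
    per_cycle_amount = b$per_cycle_amount %||% 0,
    annual_amount = b$annual_amount %||% 0,
    death_cost = b$death_cost %||% 0,
    follow_up_stop_years = b$follow_up_stop_years %||% Inf
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a scenario file
#'
#' Reads a YAML (or JSON) scenario document containing one `scenario` block
#' and an `arms` list, validates all invariants, fits any survival curves
#' given as points CSV references (paths resolved relative to the scenario
#' file), and returns the assembled model.
#'
#' @param path Scenario file path.
#' @return A list of class `cua_model` with elements `scenario`
#'   (a `cua_scenario`) and `arms` (named list of `arm_model`s).
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  dir <- dirname(path)
  .require_fields(doc, c("scenario", "arms"), "top level")
  s <- doc$scenario
  .require_fields(s, c("country_label", "discount_rate_costs",
                       "discount_rate_effects", "wtp_threshold",
                       "baseline_age_years"), "scenario")
  scen <- scenario_settings(
    country_label = s$country_label,
    discount_rate_costs = s$discount_rate_costs,
    discount_rate_effects = s$discount_rate_effects,
    wtp_threshold = s$wtp_threshold,
    baseline_age_years = s$baseline_age_years,
    cycle_length_years = s$cycle_length_years %||% 0.25,
    friction_period_days = s$friction_period_days %||% NA_real_,
    currency_label = s$currency_label %||% "EUR"
  )
  arms <- lapply(doc$arms, function(a) {
    .require_fields(a, c("name", "pfs_curve", "os_curve", "pfs_utilities",
                         "next_line_mix"), "arm")
    u <- a$pfs_utilities
    .require_fields(u, c("timepoints", "values"), paste0("arm ", a$name,
                                                         " utilities"))
    mix <- lapply(a$next_line_mix, function(o) {
      .require_fields(o, c("label", "course_cost", "proportion"),
                      paste0("arm ", a$name, " next_line_mix"))
      next_line_option(o$label, o$course_cost,
                       o$utility %||% NA_real_, o$proportion)
    })
    arm_model(
      name = a$name,
      pfs_curve = .parse_curve(a$pfs_curve, dir, paste0(a$name, " pfs")),
      os_curve = .parse_curve(a$os_curve, dir, paste0(a$name, " os")),
      treatment_costs = .parse_bundle(a$treatment_costs, "treatment"),
      societal_costs = .parse_bundle(a$societal_costs, "societal"),
      pfs_utilities = utility_series(
        timepoints = unlist(u$timepoints),
        values = unlist(u$values),
        carry_forward = u$carry_forward %||% TRUE,
        pre_death_utility = u$pre_death_utility %||% 0.665),
      next_line_mix = mix
    )
  })
  names(arms) <- vapply(arms, `[[`, character(1), "name")
  structure(list(scenario = scen, arms = arms), class = "cua_model")
}

#' Write a model back to a scenario file
#'
#' Serialises a `cua_model` to YAML; survival curves are written as
#' resolved `(family, alpha, beta)` parameters so that re-loading
#' reproduces identical parameter values regardless of how the curves were
#' originally obtained.
#'
#' @param model A `cua_model`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(model, path) {
  stopifnot(inherits(model, "cua_model"))
  s <- unclass(model$scenario)
  if (is.na(s$friction_period_days)) s$friction_period_days <- NULL
  arms <- lapply(unname(model$arms), function(a) {
    curve_doc <- function(cv) {
      out <- list(family = cv$family, alpha = cv$alpha)
      if (!is.na(cv$beta)) out$beta <- cv$beta
      out
    }
    bundle_doc <- function(b) {
      out <- list(
        one_time_items = as.list(b$one_time_items),
        first_cycle_amount = b$first_cycle_amount,
        per_cycle_amount = b$per_cycle_amount,
        annual_amount = b$annual_amount,
        death_cost = b$death_cost)
      if (is.finite(b$follow_up_stop_years))
        out$follow_up_stop_years <- b$follow_up_stop_years
      out
    }
    list(
      name = a$name,
      pfs_curve = curve_doc(a$pfs_curve),
      os_curve = curve_doc(a$os_curve),
      treatment_costs = bundle_doc(a$treatment_costs),
      societal_costs = bundle_doc(a$societal_costs),
      pfs_utilities = list(
        timepoints = a$pfs_utilities$timepoints,
        values = a$pfs_utilities$values,
        carry_forward = a$pfs_utilities$carry_forward,
        pre_death_utility = a$pfs_utilities$pre_death_utility),
      next_line_mix = lapply(a$next_line_mix, function(o)
        list(label = o$label, course_cost = o$course_cost,
             utility = if (is.na(o$utility)) NULL else o$utility,
             proportion = o$proportion))
    )
  })
  yaml::write_yaml(list(scenario = s, arms = arms), path, precision = 15)
  invisible(path)
}

#' Path to a shipped scenario or data file
#'
#' Convenience wrapper around `system.file()` for the configuration files
#' installed with the package (`nl_base_case.yaml`, `dk_scenario.yaml`,
#' `table1_survival_points.csv`).
#'
#' @param file File name under `extdata`.
#' @return Absolute path.
#' @export
cua_example <- function(file = "nl_base_case.yaml") {
  p <- system.file("extdata", file, package = "tilcea")
  if (p == "") stop("no shipped file named ", file)
  p
}
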