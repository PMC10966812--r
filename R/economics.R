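# Incremental cost-effectiveness reporting: ICER, dominance classification,
# net monetary benefit and the per-horizon summary table. All internal math
# is at full precision; rounding ((QA)LYs to 2 decimals, currency to whole
# units, half-up) happens only at render time, after differencing.

#' Net monetary benefit
#'
#' `wtp * delta_qaly - delta_cost`: positive exactly when the incremental
#' pair lies below the willingness-to-pay line on the cost-effectiveness
#' plane, which makes it a dominance-safe ordering metric.
#'
#' @param delta_cost Incremental cost (intervention minus comparator).
#' @param delta_qaly Incremental QALYs.
#' @param wtp Willingness to pay per QALY, `>= 0`.
#' @return Net monetary benefit in currency units.
#' @export
nmb <- function(delta_cost, delta_qaly, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * delta_qaly - delta_cost
}

#' Incremental cost-effectiveness of intervention versus comparator
#'
#' Computes incremental cost and QALYs, classifies the quadrant of the
#' cost-effectiveness plane (`dominant`: cheaper and more effective;
#' `dominated`: costlier and less effective; `icer_ne_quadrant` /
#' `icer_sw_quadrant`: a ratio is meaningful) and reports the ICER where
#' defined plus the net monetary benefit at the given threshold. With zero
#' incremental QALYs no ratio is reported and classification follows the
#' cost sign alone.
#'
#' @param intervention,comparator `ce_result`s from [evaluate_arm()], with
#'   matching horizon and discounting.
#' @param wtp Willingness to pay per QALY.
#' @return A list of class `icer_result` with `delta_cost`, `delta_qaly`,
#'   `delta_ly`, `classification`, `icer_value` (`NA` where no ratio is
#'   reported) and `nmb_at_wtp`.
#' @export
icer <- function(intervention, comparator, wtp) {
  stopifnot(inherits(intervention, "ce_result"),
            inherits(comparator, "ce_result"))
  if (!identical(intervention$horizon_years, comparator$horizon_years))
    stop("horizon mismatch: ", intervention$horizon_years, " vs ",
         comparator$horizon_years)
  if (!identical(intervention$discounted, comparator$discounted))
    stop("discounting mismatch between arms")
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$qalys - comparator$qalys
  dl <- intervention$life_years - comparator$life_years
  classification <-
    if (dq > 0 && dc < 0) "dominant"
    else if (dq < 0 && dc > 0) "dominated"
    else if (dq == 0) {
      # boundary: no ratio, cost sign decides
      if (dc < 0) "dominant" else if (dc > 0) "dominated"
      else "icer_ne_quadrant"
    }
    else if (dq > 0) "icer_ne_quadrant"
    else "icer_sw_quadrant"
  icer_value <- if (classification %in% c("icer_ne_quadrant",
                                          "icer_sw_quadrant") && dq != 0)
    dc / dq else NA_real_
  structure(list(
    intervention = intervention$arm, comparator = comparator$arm,
    horizon_years = intervention$horizon_years,
    discounted = intervention$discounted,
    delta_cost = dc, delta_qaly = dq, delta_ly = dl,
    classification = classification, icer_value = icer_value,
    nmb_at_wtp = nmb(dc, dq, wtp), wtp = wtp
  ), class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("%s vs %s (%s, %s): dCost %s, dQALY %.2f -> %s",
              x$intervention, x$comparator,
              if (is.finite(x$horizon_years))
                paste0(x$horizon_years, "y") else "lifetime",
              if (x$discounted) "discounted" else "undiscounted",
              format_currency(x$delta_cost), round(x$delta_qaly, 2),
              x$classification))
  if (!is.na(x$icer_value))
    cat(sprintf(", ICER %s/QALY", format_currency(x$icer_value)))
  cat(sprintf(", NMB@%s = %s\n", format_currency(x$wtp),
              format_currency(x$nmb_at_wtp)))
  invisible(x)
}

#' Round half-up
#'
#' Commercial rounding used when rendering currency: exact halves round away
#' from zero (R's `round()` rounds half to even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

format_currency <- function(x) {
  formatC(round_half_up(x), format = "d", big.mark = ",")
}

#' Per-horizon summary of both arms with incremental columns
#'
#' Evaluates every arm at each horizon, undiscounted and discounted, and
#' derives the incremental column (first arm = intervention, second =
#' comparator) with its dominance/ICER line. Horizons are half-open on
#' cycle-start times: a 5-year horizon counts cycles starting before year 5.
#'
#' @param model A `cua_model` from [load_scenario()], or a list with
#'   `scenario` and `arms`.
#' @param horizons Numeric horizons in years; `Inf` means lifetime.
#' @return A list of class `cua_summary`: `per_arm` (one row per horizon x
#'   discounting x arm) and `incremental` (one row per horizon x
#'   discounting with deltas, classification, ICER and NMB at the scenario
#'   threshold).
#' @export
summary_table <- function(model, horizons = c(5, 10, Inf)) {
  scenario <- model$scenario
  arms <- model$arms
  stopifnot(length(arms) == 2L)
  traces <- lapply(arms, build_trace, scenario = scenario)
  per_arm <- list()
  incr <- list()
  for (h in horizons) {
    for (disc in c(FALSE, TRUE)) {
      res <- mapply(function(a, tr) evaluate_arm(a, scenario, h, disc, tr),
                    arms, traces, SIMPLIFY = FALSE)
      for (r in res) {
        per_arm[[length(per_arm) + 1L]] <- data.frame(
          horizon_years = h, discounted = disc, arm = r$arm,
          life_years = r$life_years, qalys = r$qalys,
          total_cost = r$total_cost)
      }
      ic <- icer(res[[1]], res[[2]], scenario$wtp_threshold)
      incr[[length(incr) + 1L]] <- data.frame(
        horizon_years = h, discounted = disc,
        delta_ly = ic$delta_ly, delta_qaly = ic$delta_qaly,
        delta_cost = ic$delta_cost, classification = ic$classification,
        icer_value = ic$icer_value, nmb_at_wtp = ic$nmb_at_wtp)
    }
  }
  structure(list(scenario = scenario,
                 per_arm = do.call(rbind, per_arm),
                 incremental = do.call(rbind, incr)),
            class = "cua_summary")
}

#' @export
print.cua_summary <- function(x, ...) {
  cat("Cost-utility summary —", x$scenario$country_label, "\n")
  pa <- x$per_arm
  pa$life_years <- round_half_up(pa$life_years, 2)
  pa$qalys <- round_half_up(pa$qalys, 2)
  pa$total_cost <- round_half_up(pa$total_cost)
  print(pa, row.names = FALSE)
  cat("\nIncremental (", unique(pa$arm)[1], " vs ", unique(pa$arm)[2],
      "):\n", sep = "")
  ic <- x$incremental
  ic$delta_ly <- round_half_up(ic$delta_ly, 2)
  ic$delta_qaly <- round_half_up(ic$delta_qaly, 2)
  ic$delta_cost <- round_half_up(ic$delta_cost)
  ic$icer_value <- round_half_up(ic$icer_value)
  ic$nmb_at_wtp <- round_half_up(ic$nmb_at_wtp)
  print(ic, row.names = FALSE)
  invisible(x)
}

#' Write a summary to CSV and JSON
#'
#' @param summary A [summary_table()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_summary <- function(summary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(summary$per_arm, file.path(dir, "per_arm.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$incremental, file.path(dir, "incremental.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(scenario = summary$scenario$country_label,
         per_arm = summary$per_arm, incremental = summary$incremental),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
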