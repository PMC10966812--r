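# Cohort engine: runs the three-state trace over the lifetime horizon on a
# 3-month grid and accumulates (discounted) life years, QALYs and itemised
# costs. The heavy lifting is done on plain numeric vectors so that the
# probabilistic sensitivity analysis can re-evaluate the model thousands of
# times cheaply; `build_trace()` is the public, data-frame-shaped surface.

DEAD_OCCUPANCY_CUTOFF <- 0.999  # model stops once 99.9% of the cohort died
MAX_HORIZON_YEARS <- 200

# internal: raw trace vectors for one arm
.trace_vectors <- function(arm, scenario, pd_cost_mode = "one_time") {
  cyc_y <- scenario$cycle_length_years
  cyc_m <- cyc_y * 12
  k_age <- ceiling((100 - scenario$baseline_age_years) / cyc_y)
  if (k_age * cyc_y > MAX_HORIZON_YEARS)
    stop("no model cutoff reachable within ", MAX_HORIZON_YEARS, " years")
  tm <- (0:k_age) * cyc_m
  occ <- occupancy_from_curves(arm$pfs_curve, arm$os_curve, tm)
  k_dead <- which(occ$dead >= DEAD_OCCUPANCY_CUTOFF)
  k <- if (length(k_dead)) min(k_dead[1] - 1L, k_age) else k_age
  idx <- seq_len(k + 1L)
  pfs <- occ$pfs[idx]; pd <- occ$pd[idx]; dead <- occ$dead[idx]
  n <- k + 1L
  incident_deaths <- c(0, diff(dead))
  # deaths allocated to states proportionally to occupancy at cycle start;
  # only the PD-entry timing (next-line cost) depends on this allocation
  alive_prev <- c(1, pfs[-n] + pd[-n])
  pfs_prev <- c(1, pfs[-n])
  share_pfs <- ifelse(alive_prev > 0, pfs_prev / alive_prev, 0)
  incident_pd <- pmax(0, c(0, -diff(pfs)) - incident_deaths * share_pfs)
  list(cycle_index = 0:k, time_years = (0:k) * cyc_y,
       pfs = pfs, pd = pd, dead = dead,
       incident_deaths = incident_deaths, incident_pd = incident_pd,
       cycle_length_years = cyc_y, clamped = attr(occ, "clamped"))
}

#' Build the cohort trace for one arm
#'
#' Runs the partitioned-survival occupancy on the cycle grid from time 0
#' until the earlier of the cohort reaching age 100 or 99.9% of the cohort
#' dead (the cutoff cycle is included). Incident deaths per cycle are the
#' increments of the dead state; incident progressive-disease entries are
#' the decline in progression-free occupancy net of deaths allocated to the
#' progression-free state (proportionally to state occupancy at cycle
#' start).
#'
#' @param arm An [arm_model()].
#' @param scenario A [scenario_settings()].
#' @return A data frame of class `cohort_trace` with columns `cycle_index`,
#'   `time_years`, `pfs`, `pd`, `dead`, `incident_deaths`, `incident_pd`;
#'   the cycle length is kept in the `cycle_length_years` attribute.
#' @export
build_trace <- function(arm, scenario) {
  v <- .trace_vectors(arm, scenario)
  out <- data.frame(cycle_index = v$cycle_index, time_years = v$time_years,
                    pfs = v$pfs, pd = v$pd, dead = v$dead,
                    incident_deaths = v$incident_deaths,
                    incident_pd = v$incident_pd)
  attr(out, "cycle_length_years") <- v$cycle_length_years
  attr(out, "clamped") <- v$clamped
  class(out) <- c("cohort_trace", "data.frame")
  out
}

.trace_cycle_length <- function(trace) {
  cl <- attr(trace, "cycle_length_years")
  if (is.null(cl)) cl <- if (nrow(trace) > 1) diff(trace$time_years[1:2]) else 0.25
  cl
}

.discount <- function(rate, time_years) (1 + rate)^(-time_years)

#' Accumulate (discounted) life years
#'
#' Sum over cycles of the alive occupancy at cycle start, times the cycle
#' length, discounted at cycle-start times: rate 0 gives the undiscounted
#' total.
#'
#' @param trace A [build_trace()] result (possibly horizon-truncated).
#' @param rate Annual discount rate, `>= 0`.
#' @param horizon_years Only cycles with start time strictly below this are
#'   counted (default `Inf` = lifetime).
#' @return Life years.
#' @export
accumulate_life_years <- function(trace, rate = 0, horizon_years = Inf) {
  stopifnot(rate >= 0)
  keep <- trace$time_years < horizon_years
  cyc <- .trace_cycle_length(trace)
  sum((trace$pfs[keep] + trace$pd[keep]) * cyc *
        .discount(rate, trace$time_years[keep]))
}

# per-cycle utility-weighted person-time (undiscounted, years): each cycle's
# alive mass splits into those still progression-free at the next grid point
# (progression-free utility at cycle start), those in progressive disease at
# the next grid point (next-line mixture utility), and those dying during
# the cycle (pre-death utility).
.utility_time <- function(trace, arm, next_line_utility) {
  n <- nrow(trace)
  cyc <- .trace_cycle_length(trace)
  month <- trace$time_years * 12
  u_pfs <- utility_at(arm$pfs_utilities, month)
  cont_pfs <- c(trace$pfs[-1], trace$pfs[n])
  cont_pd <- c(trace$pd[-1], trace$pd[n])
  dying <- c(trace$incident_deaths[-1], 0)
  (cont_pfs * u_pfs + cont_pd * next_line_utility +
     dying * arm$pfs_utilities$pre_death_utility) * cyc
}

#' Accumulate (discounted) QALYs
#'
#' Each cycle's alive person-time is utility-weighted: mass still
#' progression-free through the cycle at the progression-free utility (step
#' series, last value carried forward), mass in progressive disease at the
#' expected next-line utility, and mass dying during the cycle at the
#' pre-death utility. Discounting at cycle-start times.
#'
#' @inheritParams accumulate_life_years
#' @param arm The [arm_model()] the trace came from.
#' @param next_line_utility Expected per-cycle utility in progressive
#'   disease; default the proportion-weighted mixture utility.
#' @return QALYs.
#' @export
accumulate_qalys <- function(trace, arm, rate = 0,
                             next_line_utility =
                               next_line_expected_utility(arm$next_line_mix),
                             horizon_years = Inf) {
  stopifnot(rate >= 0)
  ut <- .utility_time(trace, arm, next_line_utility)
  keep <- trace$time_years < horizon_years
  sum(ut[keep] * .discount(rate, trace$time_years[keep]))
}

# per-cycle undiscounted cost items for one bundle
.bundle_cycle_costs <- function(bundle, trace, cyc) {
  n <- nrow(trace)
  alive <- trace$pfs + trace$pd
  one_time <- c(sum(bundle$one_time_items), rep(0, n - 1L))
  first_cycle <- c(bundle$first_cycle_amount * alive[1], rep(0, n - 1L))
  recurring <- bundle$per_cycle_amount * alive *
    (trace$cycle_index >= 1L) *
    (trace$time_years < bundle$follow_up_stop_years)
  annual <- bundle$annual_amount * cyc * alive
  death <- bundle$death_cost * trace$incident_deaths
  list(one_time = one_time, first_cycle = first_cycle,
       recurring = recurring, annual = annual, death = death)
}

#' Accumulate (discounted) costs with an itemised cycle ledger
#'
#' Applies the arm's treatment and societal cost bundles to the trace:
#' one-time items and the first-cycle amount in the first cycle, recurring
#' per-cycle amounts from the second cycle while alive (treatment follow-up
#' items cease at the bundle's `follow_up_stop_years`), annual amounts pro
#' rata per cycle while alive, the expected next-line course cost at each
#' progressive-disease entry, and the terminal-care cost at each incident
#' death. Every item is discounted at its cycle-start time.
#'
#' @inheritParams accumulate_qalys
#' @param scenario The [scenario_settings()]; supplies the default discount
#'   rate for costs if `rate` is missing.
#' @param rate Annual discount rate for costs.
#' @return A list with `total` (currency units) and `ledger`, a data frame
#'   with one row per cycle and one column per item group (all discounted);
#'   ledger column sums reproduce `total` exactly.
#' @export
accumulate_costs <- function(trace, arm, scenario,
                             rate = scenario$discount_rate_costs,
                             horizon_years = Inf) {
  stopifnot(rate >= 0)
  cyc <- .trace_cycle_length(trace)
  tx <- .bundle_cycle_costs(arm$treatment_costs, trace, cyc)
  so <- .bundle_cycle_costs(arm$societal_costs, trace, cyc)
  next_line <- next_line_expected_cost(arm$next_line_mix) * trace$incident_pd
  disc <- .discount(rate, trace$time_years)
  keep <- as.numeric(trace$time_years < horizon_years)
  w <- disc * keep
  ledger <- data.frame(
    cycle_index = trace$cycle_index,
    time_years = trace$time_years,
    treatment = (tx$one_time + tx$first_cycle) * w,
    follow_up = (tx$recurring + tx$annual) * w,
    next_line = next_line * w,
    death = (tx$death + so$death) * w,
    societal = (so$one_time + so$first_cycle + so$recurring + so$annual) * w
  )
  ledger$total <- ledger$treatment + ledger$follow_up + ledger$next_line +
    ledger$death + ledger$societal
  list(total = sum(ledger$total), ledger = ledger)
}

#' Evaluate one arm
#'
#' Convenience wrapper: builds the trace and returns the arm's life years,
#' QALYs and total cost at a given horizon, discounted at the scenario's
#' rates or undiscounted.
#'
#' @param arm An [arm_model()].
#' @param scenario A [scenario_settings()].
#' @param horizon_years Horizon in years (`Inf` = lifetime); cycles with
#'   start time strictly below the horizon count.
#' @param discounted Apply the scenario's discount rates?
#' @param trace Optional pre-built trace (avoids re-computation).
#' @return A list of class `ce_result` with fields `arm`, `horizon_years`,
#'   `discounted`, `life_years`, `qalys`, `total_cost`.
#' @export
evaluate_arm <- function(arm, scenario, horizon_years = Inf,
                         discounted = TRUE, trace = NULL) {
  if (is.null(trace)) trace <- build_trace(arm, scenario)
  r_eff <- if (discounted) scenario$discount_rate_effects else 0
  r_cost <- if (discounted) scenario$discount_rate_costs else 0
  structure(list(
    arm = arm$name,
    horizon_years = horizon_years,
    discounted = discounted,
    life_years = accumulate_life_years(trace, r_eff, horizon_years),
    qalys = accumulate_qalys(trace, arm, r_eff, horizon_years = horizon_years),
    total_cost = accumulate_costs(trace, arm, scenario, r_cost,
                                  horizon_years)$total
  ), class = "ce_result")
}

#' Export a cohort trace (and optional ledger) to CSV
#'
#' @param trace A [build_trace()] result.
#' @param path Output CSV path.
#' @param ledger Optional ledger from [accumulate_costs()], merged by cycle.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, ledger = NULL) {
  out <- as.data.frame(trace)
  if (!is.null(ledger))
    out <- cbind(out, ledger[, setdiff(names(ledger),
                                       c("cycle_index", "time_years"))])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
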