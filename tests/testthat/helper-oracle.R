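# Independent brute-force re-implementations of the engine accumulators,
# written as naive per-cycle scalar loops. They share nothing with the
# package internals beyond the documented accounting rules, and serve as
# the oracle for randomized equivalence tests.

oracle_life_years <- function(trace, rate, cyc) {
  total <- 0
  for (i in seq_len(nrow(trace))) {
    alive <- trace$pfs[i] + trace$pd[i]
    total <- total + alive * cyc / (1 + rate)^trace$time_years[i]
  }
  total
}

oracle_qalys <- function(trace, arm, next_line_utility, rate, cyc) {
  n <- nrow(trace)
  total <- 0
  for (i in seq_len(n)) {
    month <- trace$time_years[i] * 12
    tp <- arm$pfs_utilities$timepoints
    u_pfs <- arm$pfs_utilities$values[max(1, sum(tp <= month))]
    if (i < n) {
      cont_pfs <- trace$pfs[i + 1]
      cont_pd <- trace$pd[i + 1]
      dying <- trace$incident_deaths[i + 1]
    } else {
      cont_pfs <- trace$pfs[i]
      cont_pd <- trace$pd[i]
      dying <- 0
    }
    q <- cont_pfs * u_pfs + cont_pd * next_line_utility +
      dying * arm$pfs_utilities$pre_death_utility
    total <- total + q * cyc / (1 + rate)^trace$time_years[i]
  }
  total
}

oracle_costs <- function(trace, arm, scenario, rate, cyc) {
  nl_cost <- 0
  for (o in arm$next_line_mix) nl_cost <- nl_cost + o$proportion * o$course_cost
  total <- 0
  for (i in seq_len(nrow(trace))) {
    t <- trace$time_years[i]
    alive <- trace$pfs[i] + trace$pd[i]
    amt <- 0
    for (b in list(arm$treatment_costs, arm$societal_costs)) {
      if (i == 1) amt <- amt + sum(b$one_time_items) + b$first_cycle_amount * alive
      if (i > 1 && t < b$follow_up_stop_years)
        amt <- amt + b$per_cycle_amount * alive
      amt <- amt + b$annual_amount * cyc * alive
      amt <- amt + b$death_cost * trace$incident_deaths[i]
    }
    amt <- amt + nl_cost * trace$incident_pd[i]
    total <- total + amt / (1 + rate)^t
  }
  total
}

# a small random but valid model, deterministic in `seed`; a high baseline
# age keeps the trace short so brute-force loops stay cheap
random_small_model <- function(seed) {
  set.seed(seed)
  scen <- scenario_settings(
    country_label = "synthetic",
    discount_rate_costs = runif(1, 0, 0.06),
    discount_rate_effects = runif(1, 0, 0.04),
    wtp_threshold = 80000,
    baseline_age_years = runif(1, 93, 98),
    cycle_length_years = 0.25
  )
  random_arm <- function(name) {
    a_pfs <- runif(1, 3, 15)
    a_os <- a_pfs + runif(1, 2, 20)
    beta <- runif(1, 0.9, 2.5)
    props <- as.vector(stats::rgamma(3, 1)) ; props <- props / sum(props)
    mix <- mapply(function(i, p) next_line_option(
      paste0("opt", i), runif(1, 0, 90000), runif(1, 0.5, 0.9), p),
      seq_along(props), props, SIMPLIFY = FALSE)
    arm_model(
      name = name,
      pfs_curve = parametric_survival("loglogistic", a_pfs, beta),
      os_curve = parametric_survival("loglogistic", a_os, beta * runif(1, 0.9, 1.1)),
      treatment_costs = cost_bundle(
        one_time_items = c(item_a = runif(1, 0, 90000)),
        first_cycle_amount = runif(1, 0, 4000),
        per_cycle_amount = runif(1, 0, 400),
        annual_amount = runif(1, 0, 500),
        death_cost = runif(1, 0, 2500),
        follow_up_stop_years = sample(c(2, 5, Inf), 1)),
      societal_costs = cost_bundle(
        first_cycle_amount = runif(1, 0, 5000),
        per_cycle_amount = runif(1, 0, 300),
        annual_amount = runif(1, 0, 400)),
      pfs_utilities = utility_series(
        timepoints = c(0, 3, 6, 9, 12),
        values = runif(5, 0.7, 0.95),
        pre_death_utility = runif(1, 0.4, 0.8)),
      next_line_mix = mix
    )
  }
  structure(list(scenario = scen,
                 arms = list(A = random_arm("A"), B = random_arm("B"))),
            class = "cua_model")
}

nl_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_scenario(cua_example("nl_base_case.yaml"))
    cache
  }
})

# Table 1 modeled survival points
TIL_PFS_POINTS <- data.frame(time_months = c(3, 6, 9, 12),
                             survival = c(0.792, 0.612, 0.485, 0.395))
TIL_OS_POINTS <- data.frame(time_months = c(3, 6, 9, 12),
                            survival = c(0.942, 0.871, 0.801, 0.735))
IPI_PFS_POINTS <- data.frame(time_months = c(3, 6, 9, 12),
                             survival = c(0.635, 0.269, 0.129, 0.072))
IPI_OS_POINTS <- data.frame(time_months = c(3, 6, 9, 12),
                            survival = c(0.936, 0.847, 0.759, 0.679))

# build a cohort_trace by hand for degenerate engine cases
manual_trace <- function(pfs, pd, dead, cyc = 0.25) {
  n <- length(pfs)
  tr <- data.frame(cycle_index = 0:(n - 1),
                   time_years = (0:(n - 1)) * cyc,
                   pfs = pfs, pd = pd, dead = dead,
                   incident_deaths = c(0, diff(dead)),
                   incident_pd = pmax(0, c(0, -diff(pfs)) - c(0, diff(dead))))
  attr(tr, "cycle_length_years") <- cyc
  class(tr) <- c("cohort_trace", "data.frame")
  tr
}
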