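nl_scenario <- function() nl_model()$scenario

test_that("the trace stops at age 100 when nobody reaches 99.9% mortality", {
  scen <- nl_scenario()
  arm <- nl_model()$arms$TIL
  arm$os_curve <- parametric_survival("exponential", 1e9)  # ~immortal
  arm$pfs_curve <- parametric_survival("exponential", 1e9)
  tr <- build_trace(arm, scen)
  expect_equal(nrow(tr), (100 - scen$baseline_age_years) / 0.25 + 1)
  expect_true(all(tr$dead < 1e-6))
})

test_that("the trace stops one row after mortality crosses 99.9%", {
  scen <- nl_scenario()
  arm <- nl_model()$arms$TIL
  arm$pfs_curve <- parametric_survival("exponential", 2)
  arm$os_curve <- parametric_survival("exponential", 2)
  tr <- build_trace(arm, scen)
  k <- nrow(tr) - 1  # cutoff cycle index
  expect_gte(tr$dead[k + 1], 0.999)
  expect_lt(tr$dead[k], 0.999)
  expect_equal(tr$cycle_index, 0:k)
  # cumulative incident deaths reproduce the dead state
  expect_equal(cumsum(tr$incident_deaths), tr$dead, tolerance = 1e-12)
})

test_that("the TIL trace matches the published month-12 occupancy", {
  tr <- build_trace(nl_model()$arms$TIL, nl_scenario())
  r <- tr[tr$cycle_index == 4, ]
  expect_equal(r$pfs, 0.395, tolerance = 0.005)
  expect_equal(r$pd, 0.340, tolerance = 0.01)
  expect_equal(r$dead, 0.265, tolerance = 0.005)
  expect_true(all(abs(tr$pfs + tr$pd + tr$dead - 1) < 1e-12))
  expect_true(all(tr$incident_pd >= 0))
  expect_true(all(tr$incident_deaths >= 0))
})

test_that("life years accumulate occupancy with cycle-start discounting", {
  one <- manual_trace(pfs = 1, pd = 0, dead = 0)
  expect_equal(accumulate_life_years(one, 0), 0.25)
  four <- manual_trace(pfs = rep(1, 4), pd = rep(0, 4), dead = rep(0, 4))
  expect_equal(accumulate_life_years(four, 0.04), 0.9854591,
               tolerance = 1e-7)
  expect_equal(accumulate_life_years(four, 0), 1)
})

test_that("QALY accounting splits person-time by continuing state and death", {
  arm <- nl_model()$arms$TIL
  one <- manual_trace(pfs = 1, pd = 0, dead = 0)
  expect_equal(accumulate_qalys(one, arm, 0, next_line_utility = 0.8),
               0.874 * 0.25)
  # all utilities 1, nobody dies: QALYs equal life years
  arm1 <- arm
  arm1$pfs_utilities <- utility_series(0, 1, pre_death_utility = 1)
  tr <- manual_trace(pfs = c(1, 0.6, 0.4), pd = c(0, 0.4, 0.6),
                     dead = c(0, 0, 0))
  expect_equal(accumulate_qalys(tr, arm1, 0, next_line_utility = 1),
               accumulate_life_years(tr, 0))
  # a dying mass contributes at the pre-death utility
  tr2 <- manual_trace(pfs = c(1, 0.9), pd = c(0, 0), dead = c(0, 0.1))
  q <- accumulate_qalys(tr2, arm, 0, next_line_utility = 0)
  # cycle 0: 0.9 continuing at 0.874 + 0.1 dying at 0.665; cycle 1: 0.9 at 0.879
  expect_equal(q, (0.9 * 0.874 + 0.1 * 0.665) * 0.25 + 0.9 * 0.879 * 0.25)
})

test_that("cost accumulation applies the published bundles at model start", {
  m <- nl_model()
  scen <- m$scenario
  arm <- m$arms$TIL
  # strip everything but the one-time treatment items
  arm$treatment_costs <- cost_bundle(
    one_time_items = arm$treatment_costs$one_time_items)
  arm$societal_costs <- cost_bundle()
  arm$next_line_mix <- list(next_line_option("none", 0, 0.8, 1))
  tr <- build_trace(arm, scen)
  res <- accumulate_costs(tr, arm, scen, rate = 0)
  expect_equal(res$total, 117940)
  expect_equal(sum(res$ledger$treatment), 117940)
  expect_equal(res$ledger$treatment[1], 117940)

  # empty bundles cost nothing
  arm0 <- arm
  arm0$treatment_costs <- cost_bundle()
  expect_equal(accumulate_costs(tr, arm0, scen, rate = 0)$total, 0)

  # a terminal-care cost of 1516 against a fully dying cohort
  armd <- arm0
  armd$pfs_curve <- parametric_survival("exponential", 2)
  armd$os_curve <- parametric_survival("exponential", 2)
  armd$treatment_costs <- cost_bundle(death_cost = 1516)
  trd <- build_trace(armd, scen)
  resd <- accumulate_costs(trd, armd, scen, rate = 0)
  expect_equal(resd$total, 1516 * sum(trd$incident_deaths))
  expect_equal(resd$total, 1516, tolerance = 0.002)
})

test_that("ledger columns are conserved and follow-up costs stop on time", {
  m <- nl_model()
  arm <- m$arms$Ipilimumab
  arm$treatment_costs$per_cycle_amount <- 100
  tr <- build_trace(arm, m$scenario)
  res <- accumulate_costs(tr, arm, m$scenario, rate = 0)
  lg <- res$ledger
  expect_equal(lg$treatment + lg$follow_up + lg$next_line + lg$death +
                 lg$societal, lg$total)
  expect_equal(sum(lg$total), res$total)
  # follow-up items cease at 5 years; the societal annual copay continues
  follow_rows <- tr$time_years >= arm$treatment_costs$follow_up_stop_years
  per_cycle_part <- 100 * (tr$pfs + tr$pd) * (tr$cycle_index >= 1) *
    (tr$time_years < 5)
  expect_equal(lg$follow_up, per_cycle_part)
  expect_true(all(lg$societal[follow_rows] > 0))
})

test_that("vectorised accumulators agree with the brute-force oracle", {
  for (seed in 1:6) {
    m <- random_small_model(seed)
    for (arm in m$arms) {
      tr <- build_trace(arm, m$scenario)
      cyc <- 0.25
      r_e <- m$scenario$discount_rate_effects
      r_c <- m$scenario$discount_rate_costs
      expect_equal(accumulate_life_years(tr, r_e),
                   oracle_life_years(tr, r_e, cyc), tolerance = 1e-9)
      nlu <- next_line_expected_utility(arm$next_line_mix)
      expect_equal(accumulate_qalys(tr, arm, r_e),
                   oracle_qalys(tr, arm, nlu, r_e, cyc), tolerance = 1e-9)
      expect_equal(accumulate_costs(tr, arm, m$scenario, r_c)$total,
                   oracle_costs(tr, arm, m$scenario, r_c, cyc),
                   tolerance = 1e-9)
    }
  }
})

test_that("QALYs never exceed life years and discounting is monotone", {
  for (seed in 1:4) {
    m <- random_small_model(seed)
    arm <- m$arms$A
    tr <- build_trace(arm, m$scenario)
    expect_lte(accumulate_qalys(tr, arm, 0), accumulate_life_years(tr, 0))
    rates <- c(0, 0.015, 0.04, 0.1)
    ly <- vapply(rates, function(r) accumulate_life_years(tr, r), numeric(1))
    qa <- vapply(rates, function(r) accumulate_qalys(tr, arm, r), numeric(1))
    co <- vapply(rates, function(r)
      accumulate_costs(tr, arm, m$scenario, r)$total, numeric(1))
    expect_true(all(diff(ly) < 0))
    expect_true(all(diff(qa) < 0))
    expect_true(all(diff(co) < 0))
    # rate 0 reproduces the undiscounted total by definition of the oracle
    expect_equal(ly[1], oracle_life_years(tr, 0, 0.25))
  }
})

test_that("horizon truncation is half-open on cycle-start times", {
  m <- nl_model()
  arm <- m$arms$TIL
  tr <- build_trace(arm, m$scenario)
  expect_equal(accumulate_life_years(tr, 0, horizon_years = 0), 0)
  expect_equal(accumulate_costs(tr, arm, m$scenario, 0, horizon_years = 0)$total, 0)
  ly5 <- accumulate_life_years(tr, 0, horizon_years = 5)
  keep <- tr$time_years < 5
  expect_equal(ly5, sum((tr$pfs[keep] + tr$pd[keep]) * 0.25))
  expect_lt(ly5, accumulate_life_years(tr, 0))
})
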