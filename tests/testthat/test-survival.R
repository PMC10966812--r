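FAMILIES <- c("exponential", "weibull", "gompertz", "lognormal", "loglogistic")

test_that("every family gives a proper survival function", {
  for (fam in FAMILIES) {
    m <- parametric_survival(fam, alpha = 8, beta = 1.4)
    expect_equal(survival_at(m, 0), 1, info = fam)
    t <- seq(0, 400, by = 0.5)
    s <- survival_at(m, t)
    expect_true(all(diff(s) <= 1e-12), info = fam)
    expect_true(all(s >= 0 & s <= 1), info = fam)
    expect_lt(survival_at(m, 1e5), 0.01)
  }
  expect_error(survival_at(parametric_survival("weibull", 8, 1), -1), ">= 0")
})

test_that("the log-logistic median and scale coincide", {
  m <- parametric_survival("loglogistic", alpha = 7.3, beta = 2.2)
  expect_equal(survival_at(m, 7.3), 0.5)
})

test_that("point fits recover exact log-logistic data to machine precision", {
  truth <- parametric_survival("loglogistic", 6, 2)
  pts <- survival_points(c(3, 6, 9, 12), survival_at(truth, c(3, 6, 9, 12)))
  fit <- fit_points(pts, "loglogistic")
  expect_equal(fit$alpha, 6, tolerance = 1e-9)
  expect_equal(fit$beta, 2, tolerance = 1e-9)
  expect_lt(fit$diagnostics$sse, 1e-18)
})

test_that("exact-model recovery holds for every linearised family", {
  for (fam in c("exponential", "weibull", "lognormal", "loglogistic")) {
    truth <- parametric_survival(fam, 9, 1.7)
    tt <- c(2, 5, 8, 14)
    fit <- fit_points(survival_points(tt, survival_at(truth, tt)), fam)
    expect_equal(fit$alpha, 9, tolerance = 1e-6, info = fam)
    if (fam != "exponential")
      expect_equal(fit$beta, 1.7, tolerance = 1e-6, info = fam)
  }
  # gompertz goes through the numeric path
  truth <- parametric_survival("gompertz", 12, 0.8)
  tt <- c(3, 6, 9, 12, 18)
  fit <- fit_points(survival_points(tt, survival_at(truth, tt)), "gompertz")
  expect_equal(fit$alpha, 12, tolerance = 1e-3)
  expect_equal(fit$beta, 0.8, tolerance = 1e-3)
})

test_that("month 3-9 fits extrapolate to the published month-12 values", {
  fit_ipi <- fit_points(survival_points(c(3, 6, 9), c(0.635, 0.269, 0.129)),
                        "loglogistic")
  expect_equal(round(survival_at(fit_ipi, 12), 3), 0.072)
  fit_til <- fit_points(survival_points(c(3, 6, 9), c(0.792, 0.612, 0.485)),
                        "loglogistic")
  expect_equal(round(survival_at(fit_til, 12), 3), 0.395)
  # TIL PFS scale/shape used throughout as reference values
  expect_equal(fit_til$alpha, 8.585, tolerance = 1e-3)
  expect_equal(fit_til$beta, 1.2716, tolerance = 1e-3)
  expect_equal(survival_at(fit_til, 3), 0.792, tolerance = 0.001)
})

test_that("four-point fits reproduce every published probability within 0.005", {
  for (pts in list(TIL_PFS_POINTS, TIL_OS_POINTS, IPI_PFS_POINTS,
                   IPI_OS_POINTS)) {
    fit <- fit_points(survival_points(pts$time_months, pts$survival),
                      "loglogistic")
    expect_true(all(abs(survival_at(fit, pts$time_months) - pts$survival)
                    <= 0.005))
  }
})

test_that("degenerate point inputs are rejected", {
  expect_error(survival_points(c(3, 6), c(1.0, 0.5)), "inside")
  expect_error(survival_points(c(3, 6), c(0.5, 0)), "inside")
  expect_error(fit_points(survival_points(3, 0.7), "loglogistic"),
               "at least 2")
})

test_that("maximum-likelihood fits match closed forms and recover truth", {
  # exponential MLE is events / person-time
  d <- data.frame(time_months = rep(10, 10), event = 1)
  fit <- fit_ipd(d, "exponential")
  expect_equal(fit$alpha, 10, tolerance = 1e-6)
  expect_error(fit_ipd(data.frame(time_months = c(5, 8), event = 0),
                       "exponential"), "censored")

  truth <- parametric_survival("loglogistic", 8.585, 1.2716)
  ipd <- simulate_ipd(2000, truth,
                      parametric_survival("loglogistic", 30, 1.2716),
                      censor_months = Inf, seed = 42)
  fit <- fit_ipd(data.frame(time_months = ipd$pfs_time,
                            event = ipd$pfs_event), "loglogistic")
  expect_lt(abs(fit$alpha - 8.585) / 8.585, 0.05)
  expect_lt(abs(fit$beta - 1.2716) / 1.2716, 0.05)
  expect_true(all(c("log_likelihood", "aic", "bic", "parameter_covariance")
                  %in% names(fit$diagnostics)))
  expect_equal(fit$diagnostics$aic,
               -2 * fit$diagnostics$log_likelihood + 4)
  expect_equal(fit$diagnostics$bic,
               -2 * fit$diagnostics$log_likelihood + 2 * log(2000))
})

test_that("information criteria select the generating family at large n", {
  truth <- parametric_survival("loglogistic", 8.585, 1.2716)
  ipd <- simulate_ipd(2000, truth,
                      parametric_survival("loglogistic", 30, 1.2716),
                      censor_months = Inf, seed = 7)
  d <- data.frame(time_months = ipd$pfs_time, event = ipd$pfs_event)
  fits <- lapply(FAMILIES, function(f) suppressWarnings(fit_ipd(d, f)))
  ranked <- compare_fits(fits, eval_times = c(3, 6, 9, 12))
  expect_equal(ranked[[1]]$family, "loglogistic")
  expect_s3_class(attr(ranked, "comparison"), "data.frame")
  expect_true("loglogistic" %in% names(attr(ranked, "comparison")))
})

test_that("ranking is stable on ties and ascending in AIC", {
  a <- parametric_survival("weibull", 5, 1, fitted_from = "ipd")
  a$diagnostics <- list(aic = 100, bic = 100)
  b <- parametric_survival("loglogistic", 5, 1, fitted_from = "ipd")
  b$diagnostics <- list(aic = 90, bic = 90)
  expect_equal(compare_fits(list(a, b))[[1]]$family, "loglogistic")
  a2 <- a
  expect_equal(vapply(compare_fits(list(a, a2)), `[[`, character(1),
                      "family"),
               c("weibull", "weibull"))
  mixed <- parametric_survival("weibull", 5, 1, fitted_from = "points")
  mixed$diagnostics <- list(sse = 1)
  expect_error(compare_fits(list(a, mixed)), "provenance")
})

test_that("occupancy partitions the cohort and clamps curve crossings", {
  pfs <- fit_points(survival_points(TIL_PFS_POINTS$time_months,
                                    TIL_PFS_POINTS$survival))
  os <- fit_points(survival_points(TIL_OS_POINTS$time_months,
                                   TIL_OS_POINTS$survival))
  grid <- seq(0, 60, by = 3)
  occ <- occupancy_from_curves(pfs, os, grid)
  expect_equal(unlist(occ[1, c("pfs", "pd", "dead")], use.names = FALSE),
               c(1, 0, 0))
  expect_true(all(abs(occ$pfs + occ$pd + occ$dead - 1) < 1e-12))
  expect_true(all(diff(occ$dead) >= -1e-12))
  # month 6 close to the printed probabilities (pd = 0.871 - 0.612)
  i6 <- which(grid == 6)
  expect_equal(occ$pfs[i6], 0.612, tolerance = 0.005)
  expect_equal(occ$pd[i6], 0.259, tolerance = 0.01)
  expect_equal(occ$dead[i6], 0.129, tolerance = 0.005)

  # identical curves: no progressive-disease mass
  same <- parametric_survival("weibull", 10, 1.3)
  occ2 <- occupancy_from_curves(same, same, grid)
  expect_true(all(occ2$pd == 0))

  # crossing curves get clamped in favour of OS
  slow_pfs <- parametric_survival("exponential", 100)
  fast_os <- parametric_survival("exponential", 10)
  occ3 <- occupancy_from_curves(slow_pfs, fast_os, grid)
  expect_true(all(abs(occ3$pfs + occ3$pd + occ3$dead - 1) < 1e-12))
  expect_true(all(occ3$pd == 0))
  expect_gt(attr(occ3, "clamped"), 0)
  expect_error(occupancy_from_curves(slow_pfs, fast_os, c(3, 6)), "start at 0")
})
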