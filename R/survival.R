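#' Parametric survival laws
#'
#' Constructor for a two-parameter (one for the exponential) parametric
#' survival law used to model and extrapolate progression-free and overall
#' survival. All families are parameterised with a scale `alpha` in months
#' and a dimensionless shape `beta`:
#'
#' * `loglogistic`: \eqn{S(t) = 1 / (1 + (t/\alpha)^\beta)}; `alpha` is the
#'   median survival time and `logit S(t)` is linear in `log t`.
#' * `weibull`: \eqn{S(t) = \exp(-(t/\alpha)^\beta)}.
#' * `exponential`: \eqn{S(t) = \exp(-t/\alpha)}; `alpha` is the mean, the
#'   shape is unused.
#' * `lognormal`: \eqn{S(t) = \Phi(-\beta \log(t/\alpha))}, i.e.
#'   `meanlog = log(alpha)`, `sdlog = 1/beta`.
#' * `gompertz`: \eqn{S(t) = \exp(-(e^{\beta t/\alpha} - 1)/\beta)}, hazard
#'   \eqn{h(t) = (1/\alpha) e^{\beta t / \alpha}}; `beta <= 0` gives an
#'   improper law (a plateau) and is only tolerated, with a warning, so that
#'   maximum-likelihood fits on decreasing-hazard data can still be ranked
#'   by information criteria.
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"lognormal"`, `"loglogistic"`.
#' @param alpha Scale parameter, months, `> 0`.
#' @param beta Shape parameter, dimensionless, `> 0` (ignored for the
#'   exponential).
#' @param fitted_from Provenance: `"points"`, `"ipd"` or `"specified"`.
#' @param diagnostics Optional fit diagnostics list (see [fit_points()],
#'   [fit_ipd()]).
#' @return An object of class `parsurv`.
#' @export
parametric_survival <- function(family, alpha, beta = NA_real_,
                                fitted_from = "specified",
                                diagnostics = NULL) {
  family <- match.arg(family, c("exponential", "weibull", "gompertz",
                                "lognormal", "loglogistic"))
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (alpha <= 0) stop("scale `alpha` must be > 0, got ", alpha)
  if (family != "exponential") {
    if (!is.finite(beta)) stop("shape `beta` is required for family ", family)
    if (beta <= 0) {
      if (family == "gompertz") {
        warning("Gompertz shape beta <= 0: survival plateaus above 0 ",
                "(improper law); kept for model comparison only.")
      } else {
        stop("shape `beta` must be > 0, got ", beta)
      }
    }
  }
  fitted_from <- match.arg(fitted_from, c("points", "ipd", "specified"))
  structure(
    list(family = family, alpha = alpha, beta = beta,
         fitted_from = fitted_from, diagnostics = diagnostics),
    class = "parsurv"
  )
}

#' @export
print.parsurv <- function(x, ...) {
  cat(sprintf("<parsurv> %s(alpha = %.4g months%s), fitted from %s\n",
              x$family, x$alpha,
              if (x$family == "exponential") "" else
                sprintf(", beta = %.4g", x$beta),
              x$fitted_from))
  if (!is.null(x$diagnostics)) {
    d <- x$diagnostics
    if (!is.null(d$aic))
      cat(sprintf("  loglik = %.3f, AIC = %.3f, BIC = %.3f\n",
                  d$log_likelihood, d$aic, d$bic))
    if (!is.null(d$sse)) cat(sprintf("  SSE = %.3g\n", d$sse))
  }
  invisible(x)
}

#' Survival probability at time t
#'
#' Evaluates the survival function of a fitted or specified parametric law.
#'
#' @param model A [parametric_survival()] object.
#' @param t Time in months, vectorised, `>= 0`.
#' @return Survival probabilities in `[0, 1]`.
#' @export
survival_at <- function(model, t) {
  stopifnot(inherits(model, "parsurv"), is.numeric(t))
  if (any(t < 0)) stop("time `t` must be >= 0")
  a <- model$alpha
  b <- model$beta
  # (t/a)^b at t = 0 with b > 0 is 0 in R; only lognormal needs a 0 guard
  s <- switch(model$family,
    exponential = exp(-t / a),
    weibull     = exp(-(t / a)^b),
    gompertz    = exp(-(exp(b * t / a) - 1) / b),
    lognormal   = ifelse(t == 0, 1, stats::pnorm(-b * log(t / a))),
    loglogistic = 1 / (1 + (t / a)^b)
  )
  pmin(pmax(s, 0), 1)
}

#' Summary survival points
#'
#' Validates a table of modeled survival probabilities at given times, as
#' printed in trial reports (e.g. PFS at months 3, 6, 9, 12).
#'
#' @param time_months Strictly increasing times `> 0`.
#' @param survival Survival probabilities in `(0, 1)`, non-increasing.
#' @return A `data.frame` of class `survival_points`.
#' @export
survival_points <- function(time_months, survival) {
  stopifnot(length(time_months) == length(survival), length(survival) >= 1L)
  if (any(time_months <= 0)) stop("times must be > 0")
  if (is.unsorted(time_months, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(survival <= 0 | survival >= 1))
    stop("survival points must lie strictly inside (0, 1)")
  if (is.unsorted(rev(survival))) stop("survival must be non-increasing")
  structure(data.frame(time_months = time_months, survival = survival),
            class = c("survival_points", "data.frame"))
}

#' Read survival points from CSV
#'
#' Expects a header with columns `time_months,survival_probability`.
#'
#' @param path CSV file path.
#' @return A [survival_points()] table.
#' @export
read_survival_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_months", "survival_probability")
  if (!all(need %in% names(df)))
    stop("survival points CSV must have columns ", paste(need, collapse = ", "))
  survival_points(df$time_months, df$survival_probability)
}

# linearisation used by fit_points: y = transform(S) is linear in log(t),
# y = -beta * (log t - log alpha)
.point_transform <- function(family) {
  switch(family,
    loglogistic = stats::qlogis,                 # logit(S)
    weibull     = function(s) -log(-log(s)),     # -cloglog
    lognormal   = function(s) stats::qnorm(s),   # probit(S) = -probit(1-S)
    NULL
  )
}

#' Fit a parametric survival law to summary points
#'
#' Fits by least squares on the family's linearising transform where one
#' exists: for the log-logistic, `logit S(t)` regressed on `log t` (exactly
#' linear, closed form); Weibull via `log(-log S)` on `log t`; lognormal via
#' the probit of `S` on `log t`; exponential via `-log S` proportional to
#' `t` (through the origin). The Gompertz has no linearisation and is fitted
#' by numeric least squares on the survival scale, started at
#' `alpha` = median-crossing time, `beta = 1`.
#'
#' @param points A [survival_points()] table (or data.frame with the same
#'   columns); at least 2 rows for two-parameter families.
#' @param family Survival family name.
#' @return A `parsurv` with `diagnostics$sse` populated (sum of squared
#'   deviations between fitted and observed survival).
#' @export
fit_points <- function(points, family = "loglogistic") {
  family <- match.arg(family, c("exponential", "weibull", "gompertz",
                                "lognormal", "loglogistic"))
  if (!inherits(points, "survival_points"))
    points <- survival_points(points$time_months, points$survival)
  t <- points$time_months
  s <- points$survival
  kmin <- if (family == "exponential") 1L else 2L
  if (nrow(points) < kmin)
    stop("need at least ", kmin, " points to fit a ", family, " law")

  if (family == "exponential") {
    # -log S = t / alpha; LS through the origin
    alpha <- sum(t^2) / sum(t * (-log(s)))
    fit <- parametric_survival("exponential", alpha, fitted_from = "points")
  } else if (family == "gompertz") {
    med <- stats::approx(s, t, xout = 0.5, rule = 2)$y
    obj <- function(p) {
      m <- parametric_survival("gompertz", exp(p[1]), exp(p[2]))
      sum((survival_at(m, t) - s)^2)
    }
    opt <- suppressWarnings(
      stats::optim(c(log(med), 0), obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)))
    fit <- parametric_survival("gompertz", exp(opt$par[1]), exp(opt$par[2]),
                               fitted_from = "points")
  } else {
    tr <- .point_transform(family)
    y <- tr(s)
    co <- stats::coef(stats::lm(y ~ log(t)))
    beta <- -co[[2]]
    if (beta <= 0)
      stop("points imply a non-positive shape for family ", family)
    alpha <- exp(co[[1]] / beta)
    fit <- parametric_survival(family, alpha, beta, fitted_from = "points")
  }
  fit$diagnostics <- list(sse = sum((survival_at(fit, t) - s)^2))
  fit
}

# flexsurv distribution names and parameter mapping to (alpha, beta)
.flexsurv_map <- list(
  exponential = list(dist = "exp",
                     to_ab = function(p) c(1 / p[["rate"]], NA_real_)),
  weibull     = list(dist = "weibull",
                     to_ab = function(p) c(p[["scale"]], p[["shape"]])),
  gompertz    = list(dist = "gompertz",
                     to_ab = function(p) c(1 / p[["rate"]],
                                           p[["shape"]] / p[["rate"]])),
  lognormal   = list(dist = "lnorm",
                     to_ab = function(p) c(exp(p[["meanlog"]]),
                                           1 / p[["sdlog"]])),
  loglogistic = list(dist = "llogis",
                     to_ab = function(p) c(p[["scale"]], p[["shape"]]))
)

#' Maximum-likelihood fit to right-censored individual-patient data
#'
#' Fits a parametric survival law by maximum likelihood with right
#' censoring (via `flexsurv::flexsurvreg`) and records the log-likelihood,
#' AIC (`-2 loglik + 2k`), BIC (`-2 loglik + k log n`) and the covariance of
#' the estimated parameters (on the estimation scale, i.e. log scale for
#' positive parameters) in `diagnostics`.
#'
#' @param data Data frame with columns `time_months` (> 0) and `event`
#'   (1 = event observed, 0 = right censored); at least one event.
#' @param family Survival family name.
#' @return A `parsurv` with full `diagnostics`.
#' @export
fit_ipd <- function(data, family = "loglogistic") {
  family <- match.arg(family, c("exponential", "weibull", "gompertz",
                                "lognormal", "loglogistic"))
  stopifnot(all(c("time_months", "event") %in% names(data)))
  if (any(data$time_months <= 0)) stop("event/censor times must be > 0")
  if (!any(data$event == 1)) stop("all observations censored: cannot fit")
  map <- .flexsurv_map[[family]]
  fs <- flexsurv::flexsurvreg(
    survival::Surv(time_months, event) ~ 1, data = data, dist = map$dist)
  p <- stats::setNames(fs$res[, "est"], rownames(fs$res))
  ab <- map$to_ab(p)
  k <- length(p)
  n <- nrow(data)
  ll <- as.numeric(fs$loglik)
  fit <- suppressWarnings(parametric_survival(
    family, ab[1], ab[2], fitted_from = "ipd"))
  fit$diagnostics <- list(
    log_likelihood = ll,
    aic = -2 * ll + 2 * k,
    bic = -2 * ll + k * log(n),
    n = n,
    parameter_covariance = stats::vcov(fs),
    flexsurv_pars = p
  )
  fit
}

#' Rank fitted survival models by information criteria
#'
#' Sorts models by ascending AIC with BIC as the tie-break, preserving
#' input order on exact ties, and attaches a comparison table of fitted
#' survival probabilities for visual inspection.
#'
#' @param models List of `parsurv` objects fitted on identical data (same
#'   `fitted_from` provenance) with populated diagnostics.
#' @param eval_times Optional times (months) at which the comparison table
#'   tabulates each fitted `S(t)`.
#' @param observed Optional observed survival at `eval_times` to include in
#'   the table.
#' @return The sorted list, with attributes `ranking` (a data.frame of
#'   family/AIC/BIC) and `comparison` (the inspection table).
#' @export
compare_fits <- function(models, eval_times = NULL, observed = NULL) {
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "parsurv")))
  prov <- vapply(models, `[[`, character(1), "fitted_from")
  if (length(unique(prov)) != 1L)
    stop("models have mixed provenance: ", paste(unique(prov), collapse = ", "))
  crit <- function(m, what) {
    v <- m$diagnostics[[what]]
    if (is.null(v)) NA_real_ else v
  }
  aic <- vapply(models, crit, numeric(1), "aic")
  bic <- vapply(models, crit, numeric(1), "bic")
  if (all(is.na(aic))) { # point fits: rank by SSE
    aic <- vapply(models, crit, numeric(1), "sse")
    bic <- aic
  }
  if (anyNA(aic)) stop("every model needs populated fit diagnostics")
  ord <- order(aic, bic)  # order() is stable: ties keep input order
  out <- models[ord]
  rank_df <- data.frame(
    family = vapply(out, `[[`, character(1), "family"),
    aic = aic[ord], bic = bic[ord])
  attr(out, "ranking") <- rank_df
  if (!is.null(eval_times)) {
    comp <- data.frame(time_months = eval_times)
    if (!is.null(observed)) comp$observed <- observed
    for (m in out) comp[[m$family]] <- survival_at(m, eval_times)
    attr(out, "comparison") <- comp
  }
  out
}

#' Three-state occupancy from paired PFS/OS curves
#'
#' Partitioned-survival construction: at each grid time the
#' progression-free occupancy is `S_pfs(t)`, the dead occupancy
#' `1 - S_os(t)`, and progressive disease the difference
#' `S_os(t) - S_pfs(t)` floored at zero. Where the fitted curves cross
#' (`S_pfs > S_os`) the conflict is resolved in favour of OS: the PFS
#' occupancy is clamped down to `S_os(t)` so rows sum to 1 exactly; the
#' number of clamped grid points is recorded in the `clamped` attribute.
#'
#' @param pfs,os `parsurv` curves for progression-free and overall survival.
#' @param grid Cycle-start times in months, starting at 0 with a constant
#'   step.
#' @return Data frame with columns `time_months`, `pfs`, `pd`, `dead`.
#' @export
occupancy_from_curves <- function(pfs, os, grid) {
  stopifnot(inherits(pfs, "parsurv"), inherits(os, "parsurv"))
  if (length(grid) < 1L || grid[1] != 0)
    stop("grid must start at 0")
  if (length(grid) > 2L) {
    steps <- diff(grid)
    if (max(abs(steps - steps[1])) > 1e-9)
      stop("grid must have a constant step")
  }
  s_pfs <- survival_at(pfs, grid)
  s_os <- survival_at(os, grid)
  clamped <- sum(s_pfs > s_os)
  occ_pfs <- pmin(s_pfs, s_os)
  out <- data.frame(
    time_months = grid,
    pfs = occ_pfs,
    pd = s_os - occ_pfs,
    dead = 1 - s_os
  )
  attr(out, "clamped") <- clamped
  out
}
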