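# Deterministic (tornado) and probabilistic sensitivity analyses over the
# loaded model. Parameters are addressed by slash-separated paths into the
# model structure ("arms/TIL/pfs_curve/alpha",
# "arms/Ipilimumab/next_line_mix/Pembrolizumab/utility", ...); list entries
# can be picked by name, by a `label`/`name` field, or by 1-based index.

.path_steps <- function(path) strsplit(path, "/", fixed = TRUE)[[1]]

.step_index <- function(x, step) {
  if (!is.null(names(x)) && step %in% names(x)) return(match(step, names(x)))
  if (is.list(x)) {
    labs <- vapply(x, function(el) {
      if (is.list(el) && !is.null(el$label)) el$label
      else if (is.list(el) && !is.null(el$name)) el$name
      else NA_character_
    }, character(1))
    if (step %in% labs) return(match(step, labs))
  }
  i <- suppressWarnings(as.integer(step))
  if (!is.na(i) && i >= 1 && i <= length(x)) return(i)
  NA_integer_
}

.resolve_chain <- function(model, path) {
  x <- model
  chain <- integer()
  for (step in .path_steps(path)) {
    i <- .step_index(x, step)
    if (is.na(i)) stop("unresolvable parameter path: ", path,
                       " (at '", step, "')")
    chain <- c(chain, i)
    x <- x[[i]]
  }
  chain
}

#' Get a model parameter by path
#'
#' @param model A `cua_model` (or any nested list).
#' @param path Slash-separated path, e.g. `"arms/TIL/pfs_curve/alpha"`.
#' @return The parameter value.
#' @export
get_param <- function(model, path) {
  x <- model
  for (step in .path_steps(path)) {
    i <- .step_index(x, step)
    if (is.na(i)) stop("unresolvable parameter path: ", path,
                       " (at '", step, "')")
    x <- x[[i]]
  }
  x
}

#' Set a model parameter by path
#'
#' @inheritParams get_param
#' @param value Replacement value.
#' @return The modified model.
#' @export
set_param <- function(model, path, value) {
  steps <- .path_steps(path)
  rec <- function(x, depth) {
    i <- .step_index(x, steps[depth])
    if (is.na(i)) stop("unresolvable parameter path: ", path,
                       " (at '", steps[depth], "')")
    if (depth == length(steps)) x[[i]] <- value
    else x[[i]] <- rec(x[[i]], depth + 1L)
    x
  }
  rec(model, 1L)
}

#' Parameter specification for sensitivity analyses
#'
#' Describes one uncertain parameter (or one simplex group of proportions):
#' its path(s) into the model, base value(s), deterministic low/high bounds
#' and the sampling distribution for the probabilistic analysis. Default
#' bounds are base +/- 20% (a stand-in for unreported 95% confidence
#' intervals); defaults by domain: `beta` for utilities, `gamma` for costs,
#' `lognormal` for survival parameters, `dirichlet` for proportion groups.
#'
#' @param id Identifier (the path, or a group label for `dirichlet`).
#' @param path Path or (for `dirichlet`) character vector of paths.
#' @param base Base value(s).
#' @param low,high Deterministic bounds, `low <= base <= high` elementwise.
#' @param distribution One of `"beta"`, `"gamma"`, `"lognormal"`,
#'   `"dirichlet"`, `"fixed"`.
#' @param hyper Optional list of distribution hyperparameters (`sdlog` for
#'   lognormal, `concentration` for dirichlet).
#' @return A list of class `param_spec`.
#' @export
param_spec <- function(id, path, base, low = base * 0.8, high = base * 1.2,
                       distribution = "fixed", hyper = list()) {
  distribution <- match.arg(distribution,
                            c("beta", "gamma", "lognormal", "dirichlet",
                              "fixed"))
  if (any(low > base + 1e-12) || any(high < base - 1e-12))
    stop("need low <= base <= high for ", id)
  structure(list(id = id, path = path, base = base, low = low, high = high,
                 distribution = distribution, hyper = hyper),
            class = "param_spec")
}

# bounds for utilities: +/-20% capped into the EQ-5D domain
.utility_spec <- function(id, path, base) {
  param_spec(id, path, base,
             low = max(base * 0.8, EQ5D_UTILITY_MIN),
             high = min(base * 1.2, 1),
             distribution = "beta")
}

.cost_spec <- function(id, path, base) {
  if (base <= 0) return(NULL)  # zero costs stay fixed (nothing to scale)
  param_spec(id, path, base, distribution = "gamma")
}

#' Default parameter specifications for a loaded model
#'
#' Generates the conventional spec set: gamma-distributed +/- 20% for every
#' positive cost amount (one-time items, cycle amounts, death cost,
#' next-line course costs), beta for every utility (progression-free series
#' values, pre-death, next-line utilities), lognormal around the fitted
#' survival scale/shape of each curve (default 10% coefficient of
#' variation), and one Dirichlet group per arm over the next-line mixture
#' proportions.
#'
#' @param model A `cua_model`.
#' @return List of [param_spec()]s.
#' @export
default_param_specs <- function(model) {
  specs <- list()
  add <- function(s) if (!is.null(s)) specs[[length(specs) + 1L]] <<- s
  for (arm in model$arms) {
    ap <- paste0("arms/", arm$name)
    for (bundle in c("treatment_costs", "societal_costs")) {
      b <- arm[[bundle]]
      for (item in names(b$one_time_items))
        add(.cost_spec(paste(ap, bundle, item, sep = "/"),
                       paste(ap, bundle, "one_time_items", item, sep = "/"),
                       b$one_time_items[[item]]))
      for (f in c("first_cycle_amount", "per_cycle_amount", "annual_amount",
                  "death_cost"))
        add(.cost_spec(paste(ap, bundle, f, sep = "/"),
                       paste(ap, bundle, f, sep = "/"), b[[f]]))
    }
    for (o in arm$next_line_mix) {
      op <- paste(ap, "next_line_mix", o$label, sep = "/")
      add(.cost_spec(paste0(op, "/course_cost"), paste0(op, "/course_cost"),
                     o$course_cost))
      if (!is.na(o$utility))
        add(.utility_spec(paste0(op, "/utility"), paste0(op, "/utility"),
                          o$utility))
    }
    for (i in seq_along(arm$pfs_utilities$values))
      add(.utility_spec(paste(ap, "pfs_utility", i, sep = "/"),
                        paste(ap, "pfs_utilities", "values", i, sep = "/"),
                        arm$pfs_utilities$values[i]))
    add(.utility_spec(paste(ap, "pre_death_utility", sep = "/"),
                      paste(ap, "pfs_utilities", "pre_death_utility",
                            sep = "/"),
                      arm$pfs_utilities$pre_death_utility))
    for (curve in c("pfs_curve", "os_curve")) {
      cv <- arm[[curve]]
      add(param_spec(paste(ap, curve, "alpha", sep = "/"),
                     paste(ap, curve, "alpha", sep = "/"), cv$alpha,
                     distribution = "lognormal"))
      if (!is.na(cv$beta))
        add(param_spec(paste(ap, curve, "beta", sep = "/"),
                       paste(ap, curve, "beta", sep = "/"), cv$beta,
                       distribution = "lognormal"))
    }
    props <- vapply(arm$next_line_mix, `[[`, numeric(1), "proportion")
    labs <- vapply(arm$next_line_mix, `[[`, character(1), "label")
    add(param_spec(paste(ap, "next_line_proportions", sep = "/"),
                   paste(ap, "next_line_mix", labs, "proportion", sep = "/"),
                   base = props, low = pmax(props * 0.8, 0),
                   high = pmin(props * 1.2, 1),
                   distribution = "dirichlet"))
  }
  specs
}

# incremental lifetime result of the model (first arm vs second)
.evaluate_deltas <- function(model, discounted = TRUE) {
  res <- lapply(model$arms, evaluate_arm, scenario = model$scenario,
                discounted = discounted)
  ic <- icer(res[[1]], res[[2]], model$scenario$wtp_threshold)
  list(delta_cost = ic$delta_cost, delta_qaly = ic$delta_qaly,
       icer_value = ic$icer_value, classification = ic$classification,
       nmb = ic$nmb_at_wtp)
}

.apply_values <- function(model, spec, values) {
  paths <- spec$path
  for (j in seq_along(paths)) model <- set_param(model, paths[j], values[j])
  model
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-evaluates the incremental lifetime result with each parameter set to
#' its low and to its high bound, all others held at base, and ranks
#' parameters by the span of the net monetary benefit at the scenario's
#' threshold (a dominance-safe metric; the ICER is also reported but is
#' unstable across the dominance boundary). Components of a Dirichlet group
#' are varied one at a time with the remaining proportions rescaled to keep
#' the mixture on the simplex.
#'
#' @param model A `cua_model`.
#' @param specs List of [param_spec()]s; default [default_param_specs()].
#' @return Data frame sorted by descending NMB span: `parameter`, `low`,
#'   `high`, `icer_low`, `icer_high`, `nmb_low`, `nmb_high`, `span`.
#' @export
run_dsa <- function(model, specs = default_param_specs(model)) {
  rows <- list()
  eval_at <- function(spec, values) {
    .evaluate_deltas(.apply_values(model, spec, values))
  }
  for (spec in specs) {
    if (spec$distribution == "dirichlet") {
      # vary each component, renormalising the others proportionally
      for (j in seq_along(spec$base)) {
        for (side in c("low", "high")) {
          v <- spec$base
          v[j] <- spec[[side]][j]
          rest <- sum(spec$base[-j])
          if (rest > 0) v[-j] <- spec$base[-j] * (1 - v[j]) / rest
          res <- eval_at(spec, v)
          nm <- paste0(spec$path[j], ".", side)
          rows[[nm]] <- c(res$nmb, res$icer_value, spec$base[j], v[j])
        }
      }
      next
    }
    lo <- eval_at(spec, spec$low)
    hi <- eval_at(spec, spec$high)
    rows[[paste0(spec$id, ".low")]] <- c(lo$nmb, lo$icer_value,
                                         spec$base, spec$low)
    rows[[paste0(spec$id, ".high")]] <- c(hi$nmb, hi$icer_value,
                                          spec$base, spec$high)
  }
  nm <- names(rows)
  parameter <- sub("\\.(low|high)$", "", nm)
  side <- sub("^.*\\.", "", nm)
  m <- do.call(rbind, rows)
  long <- data.frame(parameter = parameter, side = side,
                     nmb = m[, 1], icer = m[, 2], base = m[, 3],
                     value = m[, 4])
  lo <- long[long$side == "low", ]
  hi <- long[long$side == "high", ]
  out <- data.frame(
    parameter = lo$parameter,
    low = lo$value, high = hi$value[match(lo$parameter, hi$parameter)],
    icer_low = lo$icer, icer_high = hi$icer[match(lo$parameter,
                                                  hi$parameter)],
    nmb_low = lo$nmb, nmb_high = hi$nmb[match(lo$parameter, hi$parameter)])
  out$span <- abs(out$nmb_high - out$nmb_low)
  out[order(-out$span), , drop = FALSE]
}

# moment-matched samplers; (high - low) is read as an approximate 95%
# interval, so sd = (high - low) / (2 * 1.96)
.sample_spec <- function(spec, n) {
  m <- spec$base
  switch(spec$distribution,
    fixed = matrix(rep(m, each = n), nrow = n),
    beta = {
      sd <- (spec$high - spec$low) / (2 * stats::qnorm(0.975))
      if (sd <= 0 || m <= 0 || m >= 1)
        return(matrix(m, nrow = n))
      v <- min(sd^2, m * (1 - m) * 0.99)
      nu <- m * (1 - m) / v - 1
      matrix(stats::rbeta(n, m * nu, (1 - m) * nu), nrow = n)
    },
    gamma = {
      sd <- (spec$high - spec$low) / (2 * stats::qnorm(0.975))
      if (sd <= 0 || m <= 0) return(matrix(m, nrow = n))
      shape <- (m / sd)^2
      matrix(stats::rgamma(n, shape = shape, rate = shape / m), nrow = n)
    },
    lognormal = {
      sdlog <- spec$hyper$sdlog
      if (is.null(sdlog)) {
        cv <- spec$hyper$cv %||% 0.1
        sdlog <- sqrt(log(1 + cv^2))
      }
      if (sdlog <= 0) return(matrix(m, nrow = n))
      # mean-preserving: E[X] = base
      matrix(stats::rlnorm(n, log(m) - sdlog^2 / 2, sdlog), nrow = n)
    },
    dirichlet = {
      k <- spec$hyper$concentration
      if (is.null(k)) {
        # back out the concentration from the +/-20%-as-95%-CI rule applied
        # to the largest component
        p <- max(m)
        sd <- 0.2 * p / stats::qnorm(0.975)
        k <- max(p * (1 - p) / sd^2 - 1, 1)
      }
      a <- m * k
      g <- matrix(stats::rgamma(n * length(a), shape = rep(a, each = n)),
                  nrow = n)
      g / rowSums(g)
    }
  )
}

#' Probabilistic sensitivity analysis
#'
#' Draws all parameters jointly from their specified distributions
#' (utilities beta, costs gamma, survival parameters lognormal, mixture
#' proportions Dirichlet), re-evaluates the full model per draw and records
#' the incremental discounted lifetime cost and QALY pair. Reproducible for
#' a given seed.
#'
#' @param model A `cua_model`.
#' @param n Number of draws, `>= 1`.
#' @param seed Integer seed; all randomness flows from it.
#' @param specs List of [param_spec()]s; default [default_param_specs()].
#' @return A list of class `psa_result`: `n`, `seed`, `draws` (data frame
#'   with `delta_cost`, `delta_qaly`) and `base` (base-case deltas).
#' @export
run_psa <- function(model, n = 10000, seed = 1,
                    specs = default_param_specs(model)) {
  stopifnot(n >= 1)
  set.seed(seed)
  samples <- do.call(cbind, lapply(specs, .sample_spec, n = n))
  # pre-resolve every parameter path to an integer index chain so the draw
  # loop does plain recursive [[<- assignments
  chains <- unlist(lapply(specs, function(s)
    lapply(s$path, .resolve_chain, model = model)), recursive = FALSE)
  stopifnot(length(chains) == ncol(samples))
  base <- .evaluate_deltas(model)
  dc <- numeric(n)
  dq <- numeric(n)
  for (i in seq_len(n)) {
    m_i <- model
    for (p in seq_along(chains)) m_i[[chains[[p]]]] <- samples[i, p]
    d <- .evaluate_deltas(m_i)
    dc[i] <- d$delta_cost
    dq[i] <- d$delta_qaly
  }
  structure(list(n = n, seed = seed,
                 draws = data.frame(delta_cost = dc, delta_qaly = dq),
                 base = base),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' strictly positive net monetary benefit (ties count as not
#' cost-effective).
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Willingness-to-pay values, currency per QALY.
#' @return Data frame of class `ceac_curve` with columns `wtp`,
#'   `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 200000, by = 5000)) {
  stopifnot(inherits(psa, "psa_result"), nrow(psa$draws) >= 1)
  prob <- vapply(wtp_grid, function(w) {
    mean(nmb(psa$draws$delta_cost, psa$draws$delta_qaly, w) > 0)
  }, numeric(1))
  structure(data.frame(wtp = wtp_grid, probability = prob),
            class = c("ceac_curve", "data.frame"))
}

#' Probability cost-effective at one threshold
#'
#' @param psa A [run_psa()] result.
#' @param wtp Willingness to pay per QALY.
#' @return Fraction of draws with positive net monetary benefit.
#' @export
prob_cost_effective <- function(psa, wtp) {
  ceac(psa, wtp)$probability
}
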