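# Synthetic repeated cross-sectional surveillance data with known constant
# and time-varying effects: the ground truth for validating the whole
# pipeline, since raw surveillance microdata are not public.

#' Time-varying effect shape constructors
#'
#' Building blocks for the generator's time-varying log-odds-ratio functions.
#' Every shape is centered to mean zero over the waves `1..n_waves` at
#' evaluation time, so the constant log-OR of a category always carries its
#' period-average effect and generator truth matches the fitted
#' constant-plus-centered-smooth decomposition directly.
#'
#' * `vfun_flat()` — identically zero (no time variation).
#' * `vfun_linear(change)` — straight line whose value changes by `change`
#'   (log-OR units) from the first to the last wave.
#' * `vfun_sine(amplitude, cycles, phase)` — sinusoid over the study period.
#' * `vfun_piecewise(t_nodes, values)` — linear interpolation through nodes.
#'
#' @param change Total first-to-last-wave change on the log-OR scale.
#' @param amplitude,cycles,phase Sinusoid parameters.
#' @param t_nodes,values Interpolation nodes (waves) and values.
#' @return A list of class `"vfun"`, serializable to JSON/YAML.
#' @name vfun
NULL

#' @rdname vfun
#' @export
vfun_flat <- function() structure(list(type = "flat"), class = "vfun")

#' @rdname vfun
#' @export
vfun_linear <- function(change)
  structure(list(type = "linear", change = change), class = "vfun")

#' @rdname vfun
#' @export
vfun_sine <- function(amplitude, cycles = 1, phase = 0)
  structure(list(type = "sine", amplitude = amplitude, cycles = cycles,
                 phase = phase), class = "vfun")

#' @rdname vfun
#' @export
vfun_piecewise <- function(t_nodes, values) {
  stopifnot(length(t_nodes) == length(values), length(t_nodes) >= 2)
  structure(list(type = "piecewise", t_nodes = t_nodes, values = values),
            class = "vfun")
}

vfun_raw <- function(vf, t, n_waves) {
  switch(vf$type,
    flat = rep(0, length(t)),
    linear = vf$change * (t - 1) / (n_waves - 1),
    sine = vf$amplitude * sin(2 * pi * vf$cycles * (t - 1) / (n_waves - 1) +
                              vf$phase),
    piecewise = stats::approx(vf$t_nodes, vf$values, xout = t,
                              rule = 2)$y,
    stop("unknown varying-function type '", vf$type, "'"))
}

# Evaluate one vfun (or an unclassed list of them, summed), centered to mean
# zero over waves 1..n_waves.
eval_vfun <- function(vf, t, n_waves) {
  if (!inherits(vf, "vfun") && is.list(vf)) {
    return(Reduce(`+`, lapply(vf, eval_vfun, t = t, n_waves = n_waves)))
  }
  raw <- vfun_raw(vf, t, n_waves)
  raw - mean(vfun_raw(vf, seq_len(n_waves), n_waves))
}

#' Published marginal distributions of the PASSI 2008-2012 sample
#'
#' Category counts and percentages of the Italian PASSI behaviour risk factor
#' surveillance sample for 2008-2012 (185,619 telephone interviews): smoking
#' status, the ten analysis covariates and the interview year. Shipped as a
#' plain-text file; used to parameterize the `"passi"` generator preset and
#' for arithmetic self-checks.
#'
#' @return Data frame with columns `variable`, `level`, `count`, `pct`.
#' @export
passi_margins <- function() {
  f <- system.file("extdata", "passi_margins.csv", package = "trendvcm",
                   mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Configuration of the synthetic surveillance-data generator
#'
#' Describes a repeated cross-sectional survey: independent monthly waves, a
#' fixed set of categorical covariates drawn independently from declared
#' marginals, and a Bernoulli outcome whose log-odds combine an intercept,
#' constant per-category log odds ratios and mean-zero time-varying log-OR
#' departures for selected categories. No respondent appears in more than one
#' wave (there is no longitudinal structure to emulate).
#'
#' @param covariates Named list; each element a named numeric vector of level
#'   probabilities (summing to 1). The first level of each covariate is its
#'   reference unless reordered via `reference`.
#' @param reference Optional named character vector of reference levels.
#' @param constant_log_or Named list; per covariate a named vector of log
#'   odds ratios for non-reference levels (unnamed levels default to 0).
#' @param varying List of entries `list(variable=, level=, fun=)` where `fun`
#'   is a [vfun] (or list of them, summed). Use `variable = ".intercept"` for
#'   a time-varying intercept.
#' @param intercept_log_odds Baseline log-odds. If `NULL`, calibrated by
#'   exact enumeration over the covariate marginals so the period-average
#'   outcome prevalence equals `target_prevalence`.
#' @param target_prevalence Desired overall outcome prevalence (default
#'   0.279, the smoking prevalence of the surveillance sample emulated).
#' @param n_waves Number of monthly waves (default 55).
#' @param monthly_n Respondents sampled per wave (default 1000).
#' @param preset `"custom"` (use the arguments), or one of the built-in
#'   scenarios: `"passi"` (marginals and constant ORs matching the published
#'   2008-2012 surveillance summary, with declining time-varying effects for
#'   the youngest age group, ages 40-49 and non-drinkers), `"null"` (same but
#'   all effects constant) and `"dense"` (many varying terms, stress test).
#' @param amplitude_scale Multiplier applied to all time-varying amplitudes
#'   (1 = as declared). Useful for variance-matched scaled-down simulation
#'   studies.
#' @return A list of class `"brfs_config"`.
#' @examples
#' cfg <- brfs_config(preset = "passi", monthly_n = 100)
#' d <- simulate_brfs(cfg, seed = 1)
#' head(d)
#' @export
brfs_config <- function(covariates = NULL, reference = NULL,
                        constant_log_or = list(), varying = list(),
                        intercept_log_odds = NULL, target_prevalence = 0.279,
                        n_waves = 55L, monthly_n = 1000L,
                        preset = c("custom", "passi", "null", "dense"),
                        amplitude_scale = 1) {
  preset <- match.arg(preset)
  if (preset != "custom") {
    pm <- passi_margins()
    pm <- pm[!pm$variable %in% c("smoking", "year"), , drop = FALSE]
    covariates <- lapply(split(pm, pm$variable), function(d) {
      stats::setNames(d$count / sum(d$count), d$level)
    })
    reference <- c(age = "60-69", sex = "Female", marital = "Married",
                   education = "University or higher", income = "High",
                   work = "Works", region = "North", physical = "Active",
                   alcohol = "High risk drinker",
                   depression = "Not depressed")
    constant_log_or <- list(
      age = log(c("18-29" = 2.08, "30-39" = 1.79, "40-49" = 1.75,
                  "50-59" = 1.46)),
      sex = log(c(Male = 1.61)),
      marital = log(c(Single = 1.47, "Widowed or divorced" = 1.84)),
      education = log(c("High school" = 1.36, "Middle school" = 1.81,
                        "Primary school or less" = 1.44)),
      income = log(c(Medium = 1.30, Low = 1.78)),
      work = log(c("Does not work" = 0.74)),
      region = log(c(Central = 1.21, South = 1.10)),
      physical = log(c("Partially active" = 0.95, Sedentary = 1.15)),
      alcohol = log(c("Low risk drinker" = 0.69, "Non-drinker" = 0.47)),
      depression = log(c(Depressed = 1.43)))
    varying <- switch(preset,
      passi = list(
        list(variable = "age", level = "18-29",
             fun = vfun_linear(-0.211)),
        list(variable = "age", level = "40-49",
             fun = vfun_linear(-0.12)),
        list(variable = "alcohol", level = "Non-drinker",
             fun = list(vfun_linear(-0.20), vfun_sine(0.05, cycles = 1)))),
      null = list(),
      dense = list(
        list(variable = "age", level = "18-29",
             fun = vfun_linear(-0.3)),
        list(variable = "age", level = "30-39",
             fun = vfun_sine(0.15, cycles = 1.5)),
        list(variable = "alcohol", level = "Non-drinker",
             fun = vfun_piecewise(c(1, 28, 55), c(0.15, 0, -0.25))),
        list(variable = "sex", level = "Male",
             fun = vfun_sine(0.1, cycles = 2)),
        list(variable = "income", level = "Low",
             fun = vfun_linear(0.2)),
        list(variable = ".intercept", level = "",
             fun = vfun_sine(0.1, cycles = 1))))
  }
  if (is.null(covariates) || !length(covariates))
    stop("config error: at least one covariate marginal is required")
  covariates <- lapply(covariates, function(p) {
    if (is.null(names(p)) || any(!is.finite(p)) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-6)
      stop("config error: covariate marginals must be named, nonnegative ",
           "and sum to 1")
    p / sum(p)
  })
  # put the declared reference level first
  for (v in names(reference)) {
    if (!v %in% names(covariates)) next
    p <- covariates[[v]]
    if (!reference[[v]] %in% names(p))
      stop("config error: reference level '", reference[[v]],
           "' not among levels of '", v, "'")
    covariates[[v]] <- p[c(reference[[v]],
                           setdiff(names(p), reference[[v]]))]
  }
  for (v in names(constant_log_or)) {
    if (!v %in% names(covariates))
      stop("config error: constant_log_or names unknown covariate '", v, "'")
    bad <- setdiff(names(constant_log_or[[v]]), names(covariates[[v]]))
    if (length(bad))
      stop("config error: unknown level(s) ", paste(bad, collapse = ", "),
           " for '", v, "'")
  }
  for (e in varying) {
    if (!identical(e$variable, ".intercept") &&
        (!e$variable %in% names(covariates) ||
         !e$level %in% names(covariates[[e$variable]])))
      stop("config error: varying entry names unknown variable/level")
  }
  if (amplitude_scale != 1) {
    varying <- lapply(varying, function(e) {
      scale1 <- function(vf) {
        if (!inherits(vf, "vfun")) return(lapply(vf, scale1))
        for (f in c("change", "amplitude", "values"))
          if (!is.null(vf[[f]])) vf[[f]] <- vf[[f]] * amplitude_scale
        vf
      }
      e$fun <- scale1(e$fun)
      e
    })
  }
  cfg <- structure(
    list(covariates = covariates, constant_log_or = constant_log_or,
         varying = varying, intercept_log_odds = intercept_log_odds,
         target_prevalence = target_prevalence, n_waves = as.integer(n_waves),
         monthly_n = as.integer(monthly_n), preset = preset),
    class = "brfs_config")
  if (is.null(cfg$intercept_log_odds))
    cfg$intercept_log_odds <- calibrate_intercept(cfg)
  cfg
}

# Exact enumeration over the product of independent covariate marginals:
# root-find the intercept so the expected prevalence hits the target.
calibrate_intercept <- function(cfg) {
  effs <- lapply(names(cfg$covariates), function(v) {
    lev <- names(cfg$covariates[[v]])
    e <- stats::setNames(rep(0, length(lev)), lev)
    cl <- cfg$constant_log_or[[v]]
    if (!is.null(cl)) e[names(cl)] <- cl
    e
  })
  probs <- lapply(cfg$covariates, as.numeric)
  # distribution of the summed constant effects
  dist <- data.frame(eff = 0, p = 1)
  for (i in seq_along(effs)) {
    g <- expand.grid(a = dist$eff, b = effs[[i]])
    gp <- expand.grid(pa = dist$p, pb = probs[[i]])
    dist <- stats::aggregate(p ~ eff,
                             data.frame(eff = round(g$a + g$b, 10),
                                        p = gp$pa * gp$pb),
                             sum)
  }
  f <- function(b0) sum(dist$p * stats::plogis(b0 + dist$eff)) -
    cfg$target_prevalence
  stats::uniroot(f, c(-15, 15), tol = 1e-10)$root
}

#' @export
print.brfs_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic surveillance config ('%s'): %d waves x %d respondents, %d covariates\n",
    x$preset, x$n_waves, x$monthly_n, length(x$covariates)))
  cat(sprintf("intercept log-odds %.4f; %d time-varying effect(s)\n",
              x$intercept_log_odds, length(x$varying)))
  invisible(x)
}

#' Generate a synthetic surveillance dataset
#'
#' Draws `n_waves * monthly_n` respondents: covariates independently from the
#' configured marginals, then a Bernoulli outcome with
#' `logit P(y=1) = intercept + sum(constant log-ORs) + sum(varying log-ORs at
#' the respondent's wave)`. Fully reproducible given `seed`; the caller's RNG
#' state is restored afterwards.
#'
#' @param config A [brfs_config()].
#' @param seed Integer seed.
#' @return Data frame with columns `wave` (1..n_waves), one factor per
#'   covariate (reference level first) and the 0/1 outcome `smoker`.
#' @export
simulate_brfs <- function(config, seed = NULL) {
  stopifnot(inherits(config, "brfs_config"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
  }
  nw <- config$n_waves; m <- config$monthly_n
  n <- nw * m
  wave <- rep(seq_len(nw), each = m)
  out <- data.frame(wave = wave)
  eta <- rep(config$intercept_log_odds, n)
  for (v in names(config$covariates)) {
    p <- config$covariates[[v]]
    x <- sample(names(p), n, replace = TRUE, prob = as.numeric(p))
    out[[v]] <- factor(x, levels = names(p))
    cl <- config$constant_log_or[[v]]
    if (!is.null(cl)) {
      e <- stats::setNames(rep(0, length(p)), names(p))
      e[names(cl)] <- cl
      eta <- eta + e[x]
    }
  }
  for (e in config$varying) {
    a <- eval_vfun(e$fun, seq_len(nw), nw)
    if (identical(e$variable, ".intercept")) {
      eta <- eta + a[wave]
    } else {
      sel <- out[[e$variable]] == e$level
      eta <- eta + a[wave] * sel
    }
  }
  out$smoker <- stats::rbinom(n, 1L, stats::plogis(unname(eta)))
  attr(out, "config") <- config
  out
}

#' True odds-ratio curve of a generator configuration
#'
#' The ground-truth curve `exp(constant_log_or + varying_log_or(t))` for a
#' non-reference category — the oracle against which fitted odds-ratio curves
#' are checked in recovery simulations. Like the fitted curves, it is
#' undefined for reference categories.
#'
#' @param config A [brfs_config()].
#' @param variable,level Category of interest.
#' @param t Wave values.
#' @return Positive numeric vector, the OR at each `t`.
#' @export
true_or_curve <- function(config, variable, level, t) {
  stopifnot(inherits(config, "brfs_config"))
  if (!variable %in% names(config$covariates))
    stop("unknown variable '", variable, "'")
  lev <- names(config$covariates[[variable]])
  if (identical(as.character(level), lev[1]))
    stop("no odds ratio is defined for the reference category '", lev[1],
         "' of '", variable, "'")
  if (!level %in% lev)
    stop("unknown level '", level, "' for '", variable, "'")
  const <- 0
  cl <- config$constant_log_or[[variable]]
  if (!is.null(cl) && level %in% names(cl)) const <- cl[[level]]
  a <- rep(0, length(t))
  for (e in config$varying)
    if (identical(e$variable, variable) && identical(e$level, level))
      a <- a + eval_vfun(e$fun, t, config$n_waves)
  exp(const + a)
}

#' Write / read a generator configuration
#'
#' Serializes a [brfs_config()] to JSON (or YAML, by file extension) and
#' reconstructs it, including the time-varying effect shapes, so scenarios
#' can be version-controlled and shared.
#'
#' @param config A [brfs_config()].
#' @param path File path ending in `.json`, `.yml` or `.yaml`.
#' @return `read_brfs_config()` returns a validated [brfs_config()];
#'   `write_brfs_config()` returns `path` invisibly.
#' @export
write_brfs_config <- function(config, path) {
  stopifnot(inherits(config, "brfs_config"))
  x <- unclass(config)
  x$covariates <- lapply(x$covariates, as.list)
  x$constant_log_or <- lapply(x$constant_log_or, as.list)
  x$varying <- lapply(x$varying, function(e) {
    e$fun <- if (inherits(e$fun, "vfun")) list(unclass(e$fun)) else
      lapply(e$fun, unclass)
    e
  })
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the 'yaml' package")
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_brfs_config
#' @export
read_brfs_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  revive <- function(f) structure(lapply(f, function(v)
    if (is.list(v)) unlist(v) else v), class = "vfun")
  varying <- lapply(x$varying, function(e) {
    e$fun <- lapply(e$fun, revive)
    if (length(e$fun) == 1L) e$fun <- e$fun[[1L]]
    e
  })
  brfs_config(covariates = lapply(x$covariates, unlist),
              constant_log_or = lapply(x$constant_log_or, unlist),
              varying = varying,
              intercept_log_odds = x$intercept_log_odds,
              target_prevalence = x$target_prevalence,
              n_waves = x$n_waves, monthly_n = x$monthly_n)
}
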