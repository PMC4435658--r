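# S3 methods for fitted "vcm" objects.

#' @export
print.vcm <- function(x, ...) {
  cat("Time-varying coefficient model (", x$family, ")\n", sep = "")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  nsm <- length(x$gamma)
  cat(sprintf("n = %d, deviance = %.3f, edf = %.2f, AIC = %.3f\n",
              x$n_obs, x$deviance, x$edf$total, x$aic))
  if (nsm) {
    cat("Smooth terms (lambda, edf):\n")
    sm <- names(x$gamma)
    edf_sm <- x$edf$by_term[sm]
    for (i in seq_along(sm))
      cat(sprintf("  %-28s lambda = %-10.4g edf = %.2f\n",
                  sm[i], x$lambda[i], edf_sm[i]))
  } else cat("No time-varying terms (parametric model)\n")
  invisible(x)
}

#' @export
coef.vcm <- function(object, ...) object$coefficients

#' @export
fitted.vcm <- function(object, ...) object$fitted.values

#' @export
logLik.vcm <- function(object, ...) {
  df <- object$edf$total + if (object$family == "gaussian") 1 else 0
  structure(object$loglik, df = df, nobs = object$n_obs, class = "logLik")
}

#' @export
deviance.vcm <- function(object, ...) object$deviance

#' Conditional AIC of a fitted varying coefficient model
#'
#' `deviance + 2 * edf` for binomial fits and `-2 loglik + 2 (edf + 1)` for
#' Gaussian fits, with the effective degrees of freedom playing the role of
#' the parameter count (equivalent to `stats::AIC` on the fit's `logLik`).
#'
#' @param fit A fitted `"vcm"`.
#' @return Numeric AIC value.
#' @export
model_aic <- function(fit) {
  stopifnot(inherits(fit, "vcm"))
  fit$aic
}

#' GCV score of a fitted varying coefficient model
#'
#' The generalized cross-validation criterion
#' `n * deviance / (n - edf_total)^2` recomputed from the stored fit.
#'
#' @param fit A fitted `"vcm"`.
#' @return Numeric GCV value.
#' @export
gcv_score <- function(fit) {
  stopifnot(inherits(fit, "vcm"))
  fit$n_obs * fit$deviance / (fit$n_obs - fit$edf$total)^2
}

#' @export
residuals.vcm <- function(object,
                          type = c("deviance", "pearson", "working",
                                   "response"),
                          ...) {
  type <- match.arg(type)
  y <- object$design$y
  if (is.null(y)) stop("fit was stored without its design; refit with keep_design = TRUE")
  mu <- object$fitted.values
  if (object$family == "gaussian") {
    r <- y - mu
    return(switch(type, deviance = r, pearson = r / sqrt(object$phi),
                  working = r, response = r))
  }
  switch(type,
    response = y - mu,
    working = (y - mu) / pmax(mu * (1 - mu), 1e-10),
    pearson = (y - mu) / sqrt(pmax(mu * (1 - mu), 1e-10)),
    deviance = {
      d <- -2 * (y * log(pmax(mu, 1e-16)) +
                 (1 - y) * log(pmax(1 - mu, 1e-16)))
      sign(y - mu) * sqrt(pmax(d, 0))
    })
}

# Build the centered model-matrix rows for new observations; used by
# predict(), posterior_bands() and or_curve(). `effects` restricts which
# blocks contribute ("all", or a list(constant=, smooths=) of block names).
row_design <- function(fit, newdata, blocks = NULL) {
  des <- fit$design
  spec <- des$spec
  m <- nrow(newdata)
  C <- matrix(0, m, des$pc)
  keep <- if (is.null(blocks)) vapply(des$blocks, `[[`, "", "name") else blocks
  bl1 <- des$blocks[[1]]
  if ("(constant)" %in% keep) {
    C[, bl1$cols_c[1]] <- 1
    for (i in seq_len(nrow(des$const_map))[-1]) {
      v <- des$const_map$variable[i]; lev <- des$const_map$level[i]
      if (!v %in% names(newdata))
        stop("schema error: column '", v, "' missing from newdata")
      x <- as.character(newdata[[v]])
      bad <- !x %in% des$levels[[v]]
      if (any(bad))
        stop("schema error: unknown level(s) for '", v, "': ",
             paste(unique(x[bad]), collapse = ", "))
      C[x == lev, bl1$cols_c[i]] <- 1
    }
  }
  if (length(des$smooth_idx)) {
    tnew <- as.numeric(newdata[[spec$modifier]])
    Bc <- bspline_basis(tnew, spec$basis) %*% des$Zn
    for (si in des$smooth_idx) {
      b <- des$blocks[[si]]
      if (!b$name %in% keep) next
      if (b$variable == ".intercept") {
        C[, b$cols_c] <- Bc
      } else {
        sel <- as.character(newdata[[b$variable]]) == b$level
        if (any(sel)) C[sel, b$cols_c] <- Bc[sel, , drop = FALSE]
      }
    }
  }
  C
}

#' @export
predict.vcm <- function(object, newdata = NULL,
                        type = c("link", "response"), se.fit = FALSE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear.predictors
    se <- NULL
    if (se.fit) stop("se.fit requires newdata")
  } else {
    C <- row_design(object, newdata)
    eta <- as.numeric(C %*% object$beta)
    se <- if (se.fit) sqrt(pmax(rowSums((C %*% object$Vb) * C), 0)) else NULL
  }
  out <- if (type == "response" && object$family == "binomial")
    stats::plogis(eta) else eta
  if (se.fit) list(fit = out, se.fit = se) else out
}

#' @export
simulate.vcm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  mu <- object$fitted.values
  n <- object$n_obs
  out <- as.data.frame(replicate(nsim, {
    if (object$family == "binomial") stats::rbinom(n, 1, mu)
    else stats::rnorm(n, mu, sqrt(object$phi))
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Summarize a fitted varying coefficient model
#'
#' Produces the usual surveillance-report layout: one row per non-reference
#' category with its constant odds ratio (binomial fits), Wald 95% confidence
#' interval and p-value, and one row per smooth term with its effective
#' degrees of freedom and an approximate significance test of the time-varying
#' part. Smooth-term p-values are approximate and tend to be optimistic; the
#' odds-ratio curves should be inspected alongside them.
#'
#' @param object A fitted `"vcm"`.
#' @param ci_level Confidence level for the constant-coefficient intervals.
#' @param ... Unused.
#' @return A `"summary.vcm"` list with data frames `constant` and `smooth`.
#' @export
summary.vcm <- function(object, ci_level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  bl1 <- object$design$blocks[[1]]
  se <- sqrt(pmax(diag(object$Vb)[bl1$cols_c], 0))
  b <- object$coefficients
  cm <- object$design$const_map
  const <- data.frame(
    variable = cm$variable, level = cm$level, estimate = unname(b), se = se,
    lower = b - z * se, upper = b + z * se,
    p_value = 2 * stats::pnorm(-abs(b / ifelse(se > 0, se, Inf))),
    row.names = NULL, stringsAsFactors = FALSE)
  if (object$family == "binomial") {
    const$or <- exp(const$estimate)
    const$or_lower <- exp(const$lower)
    const$or_upper <- exp(const$upper)
  }
  sm <- names(object$gamma)
  smooth <- NULL
  if (length(sm)) {
    tests <- lapply(sm, function(nm) smooth_term_test(object, nm))
    smooth <- data.frame(
      term = sm,
      edf = unname(object$edf$by_term[sm]),
      lambda = unname(object$lambda),
      statistic = vapply(tests, `[[`, numeric(1), "statistic"),
      df = vapply(tests, `[[`, numeric(1), "df"),
      p_value = vapply(tests, `[[`, numeric(1), "p_value"),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(constant = const, smooth = smooth, family = object$family,
                 n_obs = object$n_obs, deviance = object$deviance,
                 edf_total = object$edf$total, aic = object$aic,
                 ci_level = ci_level, call = object$call),
            class = "summary.vcm")
}

#' @export
print.summary.vcm <- function(x, digits = 3, ...) {
  cat("Time-varying coefficient model (", x$family, ")\n", sep = "")
  cat(sprintf("n = %d, deviance = %.3f, edf = %.2f, AIC = %.3f\n\n",
              x$n_obs, x$deviance, x$edf_total, x$aic))
  ct <- x$constant
  if (x$family == "binomial") {
    show <- data.frame(
      term = ifelse(ct$level == "", ct$variable,
                    paste0(ct$variable, ":", ct$level)),
      OR = round(ct$or, digits),
      CI = sprintf("(%.2f-%.2f)", ct$or_lower, ct$or_upper),
      p = format.pval(ct$p_value, digits = digits))
    names(show)[3] <- sprintf("%d%% CI", round(100 * x$ci_level))
  } else {
    show <- data.frame(
      term = ifelse(ct$level == "", ct$variable,
                    paste0(ct$variable, ":", ct$level)),
      estimate = round(ct$estimate, digits), se = round(ct$se, digits),
      p = format.pval(ct$p_value, digits = digits))
  }
  cat("Constant coefficients:\n")
  print(show, row.names = FALSE)
  if (!is.null(x$smooth)) {
    cat("\nTime-varying terms:\n")
    sm <- x$smooth
    print(data.frame(term = sm$term, edf = round(sm$edf, 2),
                     p = format.pval(sm$p_value, digits = digits)),
          row.names = FALSE)
    cat("Note: smooth-term p-values are approximate and tend to be",
        "optimistic;\ninspect the odds-ratio curves as well.\n")
  }
  invisible(x)
}

#' Compare nested varying coefficient models
#'
#' With two fits, performs the likelihood-ratio test of [lrt_nested()];
#' with one, prints the fit summary table.
#'
#' @param object,... Fitted `"vcm"` objects (null first, alternative second).
#' @return A `"vcm_test"` result (two fits) or summary.
#' @export
anova.vcm <- function(object, ...) {
  others <- Filter(function(o) inherits(o, "vcm"), list(...))
  if (!length(others)) return(summary(object))
  lrt_nested(object, others[[1]])
}

#' Plot odds-ratio-over-time curves of a fitted model
#'
#' One panel per non-reference level of each time-varying covariate, showing
#' `exp(b_level + a_level(t))` with its posterior band.
#'
#' @param x A fitted `"vcm"` with at least one varying covariate.
#' @param ci_level Band level.
#' @param t_grid Optional plotting grid (defaults to the observed waves).
#' @param ask Passed to `par`.
#' @param ... Passed to [plot.or_curve()].
#' @export
plot.vcm <- function(x, ci_level = 0.95, t_grid = NULL, ask = FALSE, ...) {
  vars <- x$spec$varying
  if (!length(vars)) {
    warning("no time-varying covariates to plot")
    return(invisible(x))
  }
  curves <- list()
  for (v in vars) {
    lev <- x$design$levels[[v]]
    for (l in lev[-1])
      curves[[paste(v, l, sep = ":")]] <-
        or_curve(x, v, l, t_grid = t_grid, ci_level = ci_level)
  }
  np <- length(curves)
  old <- graphics::par(mfrow = grDevices::n2mfrow(np), ask = ask)
  on.exit(graphics::par(old))
  for (nm in names(curves)) plot(curves[[nm]], ...)
  invisible(curves)
}
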