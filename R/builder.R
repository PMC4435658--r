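# Two-stage model building: screen every covariate for a time-varying
# coefficient, then forward-select varying terms by residual deviance
# explained.

# lrt_nested that never throws: a degenerate comparison (e.g. the larger
# model ends up with fewer effective df after smoothing re-selection) is
# evidence against the extra term, recorded as p = 1.
safe_lrt <- function(fit0, fit1) {
  tryCatch(lrt_nested(fit0, fit1), error = function(e) {
    structure(list(statistic = NA_real_,
                   df = fit1$edf$total - fit0$edf$total, p_value = 1,
                   null_model = "", alt_model = "",
                   error = conditionMessage(e)),
              class = "vcm_test")
  })
}

#' Screen covariates for time-varying coefficients
#'
#' For each covariate in turn (plus, optionally, a time-varying intercept),
#' fits the model in which only that covariate's coefficients vary with time
#' while all others stay constant, and tests it against the all-constant
#' (parametric logistic) model with a likelihood-ratio test. Rows are sorted
#' by p-value, then AIC. A fit failure is recorded in its row, not fatal.
#'
#' @param formula `response ~ covariate1 + ...`, all constant candidates.
#' @param data A data frame.
#' @param modifier Time column name.
#' @param alpha Significance level used to flag rows (default 0.05).
#' @param include_intercept Also screen a time-varying intercept (default
#'   `TRUE`).
#' @param k,degree,penalty_order,method,control Passed to [vcm()].
#' @return A `"vcm_screen"` data frame (variable, statistic, df, p_value,
#'   aic, edf, significant, error) with the null fit in
#'   `attr(, "null_fit")`.
#' @export
screen_varying <- function(formula, data, modifier, alpha = 0.05,
                           include_intercept = TRUE, k = 55, degree = 3,
                           penalty_order = 2, method = "gcv",
                           control = vcm_control()) {
  null_fit <- vcm(formula, data, modifier = modifier, family = "binomial",
                  k = k, degree = degree, penalty_order = penalty_order,
                  method = method, control = control)
  cand <- null_fit$spec$covariates
  if (include_intercept) cand <- c(cand, ".intercept")
  rows <- lapply(cand, function(v) {
    out <- data.frame(variable = v, statistic = NA_real_, df = NA_real_,
                      p_value = NA_real_, aic = NA_real_, edf = NA_real_,
                      significant = NA, error = NA_character_,
                      stringsAsFactors = FALSE)
    fit <- tryCatch({
      if (v == ".intercept")
        vcm(formula, data, modifier = modifier, varying_intercept = TRUE,
            family = "binomial", k = k, degree = degree,
            penalty_order = penalty_order, method = method,
            control = control)
      else
        vcm(formula, data, modifier = modifier, varying = v,
            family = "binomial", k = k, degree = degree,
            penalty_order = penalty_order, method = method,
            control = control)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      out$error <- conditionMessage(fit)
      return(out)
    }
    tst <- tryCatch(lrt_nested(null_fit, fit), error = function(e) e)
    if (inherits(tst, "error")) {
      out$error <- conditionMessage(tst)
      return(out)
    }
    out$statistic <- tst$statistic; out$df <- tst$df
    out$p_value <- tst$p_value; out$aic <- fit$aic
    out$edf <- fit$edf$total
    out$significant <- tst$p_value < alpha
    out
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$p_value, tab$aic, method = "radix",
                   na.last = TRUE), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("vcm_screen", "data.frame"),
            null_fit = null_fit, alpha = alpha, modifier = modifier,
            formula = formula)
}

#' @export
print.vcm_screen <- function(x, digits = 3, ...) {
  cat("Screening of time-varying coefficients (alpha =",
      attr(x, "alpha"), ")\n")
  df <- as.data.frame(x)
  df$p_value <- format.pval(df$p_value, digits = digits)
  df$aic <- round(df$aic, 1); df$df <- round(df$df, 2)
  df$edf <- round(df$edf, 2); df$statistic <- round(df$statistic, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Rank candidate varying terms by residual deviance explained
#'
#' Scores each candidate covariate by fitting a Gaussian smooth model of the
#' current model's deviance residuals on `s(t)` interacted with the
#' candidate's levels, and recording the proportion of residual variation
#' explained, `1 - RSS/TSS`. Candidates are returned in descending score
#' order with deterministic alphabetical tie-breaking.
#'
#' @param current_fit The current fitted `"vcm"` (with design kept).
#' @param data The data frame the current fit was estimated on (after any
#'   listwise deletion).
#' @param candidates Character vector of covariate names not yet varying.
#' @param k,degree,penalty_order,control Passed to the Gaussian residual fits.
#' @return Data frame `variable`, `score`, sorted descending.
#' @export
rank_candidates <- function(current_fit, data, candidates, k = NULL,
                            degree = 3, penalty_order = 2,
                            control = vcm_control()) {
  if (!length(candidates))
    return(data.frame(variable = character(0), score = numeric(0)))
  stopifnot(inherits(current_fit, "vcm"))
  r <- residuals(current_fit, type = "deviance")
  if (length(r) != nrow(data))
    stop("data rows do not align with the current fit")
  if (is.null(k)) k <- current_fit$spec$basis$n_basis
  modifier <- current_fit$spec$modifier
  df <- data
  df$.resid <- r
  tss <- sum((r - mean(r))^2)
  score <- vapply(candidates, function(v) {
    fit <- tryCatch({
      if (v == ".intercept")
        vcm(.resid ~ 1, df, modifier = modifier, varying_intercept = TRUE,
            family = "gaussian", k = k, degree = degree,
            penalty_order = penalty_order, control = control,
            domain = current_fit$spec$basis$domain)
      else
        vcm(stats::reformulate(v, ".resid"), df, modifier = modifier,
            varying = v, family = "gaussian", k = k, degree = degree,
            penalty_order = penalty_order, control = control,
            domain = current_fit$spec$basis$domain)
    }, error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    max(0, min(1, 1 - fit$deviance / tss))
  }, numeric(1))
  out <- data.frame(variable = candidates, score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$variable, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stepwise forward selection of time-varying terms
#'
#' Implements the second model-building stage: beginning with the most
#' significant screened varying term, candidates that passed screening are
#' repeatedly ranked by residual deviance explained and the best-ranked one
#' is added whenever its nested likelihood-ratio test against the current
#' model is significant at `alpha`. When the variable candidates are
#' exhausted, the addition of a time-varying intercept is tested (provided it
#' passed screening). Terms that failed screening are never added.
#'
#' @inheritParams screen_varying
#' @param screen A [screen_varying()] table; computed if `NULL`.
#' @return A `"vcm_select"` list: `fit` (final model), `trace` (one row per
#'   fitted/tested model, Table-style), `screen`, `varying` (selected
#'   variables), `varying_intercept`.
#' @export
forward_select <- function(formula, data, modifier, screen = NULL,
                           alpha = 0.05, include_intercept = TRUE, k = 55,
                           degree = 3, penalty_order = 2, method = "gcv",
                           control = vcm_control()) {
  used <- c(all.vars(formula), modifier)
  cc <- stats::complete.cases(data[intersect(used, names(data))])
  if (!all(cc)) data <- data[cc, , drop = FALSE]
  if (is.null(screen))
    screen <- screen_varying(formula, data, modifier, alpha = alpha,
                             include_intercept = include_intercept, k = k,
                             degree = degree, penalty_order = penalty_order,
                             method = method, control = control)
  null_fit <- attr(screen, "null_fit")
  refit <- function(varying, vi) {
    vcm(formula, data, modifier = modifier, varying = varying,
        varying_intercept = vi, family = "binomial", k = k, degree = degree,
        penalty_order = penalty_order, method = method, control = control)
  }
  sc <- as.data.frame(screen)
  ok <- !is.na(sc$p_value) & sc$significant
  sig_vars <- sc$variable[ok & sc$variable != ".intercept"]
  int_ok <- include_intercept && any(ok & sc$variable == ".intercept")
  trace <- data.frame(model = "LM", description = "parametric logistic model",
                      p_value = NA_real_, null_model = "",
                      aic = null_fit$aic, df = NA_real_,
                      edf = null_fit$edf$total, accepted = TRUE,
                      stringsAsFactors = FALSE)
  if (!length(sig_vars)) {
    fit <- null_fit
    included <- character(0)
    vi <- FALSE
  } else {
    first <- sig_vars[1]                 # screen is sorted by p then AIC
    fit <- refit(first, FALSE)
    t0 <- safe_lrt(null_fit, fit)
    trace <- rbind(trace, data.frame(
      model = "M1", description = paste0("LM + s(t):", first),
      p_value = t0$p_value, null_model = "LM", aic = fit$aic, df = t0$df,
      edf = fit$edf$total, accepted = TRUE, stringsAsFactors = FALSE))
    included <- first
    vi <- FALSE
    remaining <- setdiff(sig_vars, included)
    step <- 1L
    while (length(remaining)) {
      ranks <- rank_candidates(fit, data, remaining, k = k, degree = degree,
                               penalty_order = penalty_order,
                               control = control)
      added <- FALSE
      for (v in ranks$variable) {
        step <- step + 1L
        alt <- tryCatch(refit(c(included, v), FALSE),
                        error = function(e) NULL)
        if (is.null(alt)) { remaining <- setdiff(remaining, v); next }
        tst <- safe_lrt(fit, alt)
        acc <- tst$p_value < alpha
        trace <- rbind(trace, data.frame(
          model = paste0("M", step),
          description = paste0(utils::tail(trace$model[trace$accepted], 1),
                               " + s(t):", v),
          p_value = tst$p_value,
          null_model = utils::tail(trace$model[trace$accepted], 1),
          aic = alt$aic, df = tst$df, edf = alt$edf$total, accepted = acc,
          stringsAsFactors = FALSE))
        remaining <- setdiff(remaining, v)
        if (acc) { fit <- alt; included <- c(included, v); added <- TRUE
          break }
      }
      if (!added) break
    }
  }
  if (int_ok) {
    alt <- tryCatch(refit(included, TRUE), error = function(e) NULL)
    if (!is.null(alt)) {
      tst <- safe_lrt(fit, alt)
      acc <- tst$p_value < alpha
      trace <- rbind(trace, data.frame(
        model = "M+s(t)",
        description = paste0(utils::tail(trace$model[trace$accepted], 1),
                             " + s(t) [varying intercept]"),
        p_value = tst$p_value,
        null_model = utils::tail(trace$model[trace$accepted], 1),
        aic = alt$aic, df = tst$df, edf = alt$edf$total, accepted = acc,
        stringsAsFactors = FALSE))
      if (acc) { fit <- alt; vi <- TRUE }
    }
  }
  structure(list(fit = fit, trace = trace, screen = screen,
                 varying = included,
                 varying_intercept = vi, alpha = alpha),
            class = "vcm_select")
}

#' @export
print.vcm_select <- function(x, digits = 3, ...) {
  cat("Forward selection of time-varying coefficients (alpha =", x$alpha,
      ")\n")
  tr <- x$trace
  tr$p_value <- format.pval(tr$p_value, digits = digits)
  tr$aic <- round(tr$aic, 1); tr$df <- round(tr$df, 2)
  tr$edf <- round(tr$edf, 2)
  print(tr, row.names = FALSE)
  cat("Selected varying terms:",
      if (length(x$varying)) paste(x$varying, collapse = ", ") else "(none)",
      if (x$varying_intercept) "+ time-varying intercept" else "", "\n")
  invisible(x)
}
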