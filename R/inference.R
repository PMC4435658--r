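# Effective degrees of freedom, nested tests and posterior bands.

#' Effective degrees of freedom of a fit
#'
#' The trace of the penalized influence matrix `F = (X'WX + P)^{-1} X'WX` at
#' convergence, reported in total and per term. Unpenalized constant columns
#' contribute exactly 1 each, so the per-term values sum to the total. The
#' alternative convention `tr(2F - F'F)` (`total2`, `by_term2`), which defines
#' residual degrees of freedom in the reference GAM software, is also
#' reported; nested likelihood-ratio tests use its difference as their df.
#'
#' @param fit A fitted `"vcm"`.
#' @return List with `total`, the named per-term vector `by_term`, and their
#'   `tr(2F - F'F)` counterparts `total2`, `by_term2`.
#' @export
effective_df <- function(fit) {
  stopifnot(inherits(fit, "vcm"))
  fit$edf
}

# is `null` spec nested in `alt` spec (same data shape assumed)?
is_nested_spec <- function(s0, s1) {
  setequal(s0$covariates, s1$covariates) &&
    all(s0$varying %in% s1$varying) &&
    (!s0$varying_intercept || s1$varying_intercept) &&
    s0$response == s1$response && s0$family == s1$family
}

#' Likelihood-ratio test between nested fits
#'
#' Tests whether the extra time-varying terms of the alternative model are
#' needed: the statistic is the deviance drop (floored at zero), the degrees
#' of freedom the effective-df difference (possibly fractional), and the
#' p-value comes from the chi-square distribution with that (continuous)
#' df — valid here because the surveillance samples are large and the number
#' of parameters fixed.
#'
#' @param fit_null,fit_alt Fitted `"vcm"` objects on the same data, the null
#'   model's terms a subset of the alternative's.
#' @return A `"vcm_test"` list: `statistic`, `df`, `p_value`, model labels.
#' @export
lrt_nested <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "vcm"), inherits(fit_alt, "vcm"))
  if (fit_null$n_obs != fit_alt$n_obs)
    stop("nesting error: models were fitted to different numbers of rows")
  if (!is_nested_spec(fit_null$spec, fit_alt$spec))
    stop("nesting error: null model terms are not a subset of the alternative's")
  stat <- max(fit_null$deviance - fit_alt$deviance, 0)
  # df from the tr(2F - F^2) convention (see effective_df); for unpenalized
  # models both conventions equal the parameter count
  df <- fit_alt$edf$total2 - fit_null$edf$total2
  if (abs(df) < 1e-8 && stat < 1e-8) {
    return(structure(list(statistic = 0, df = 0, p_value = 1,
                          null_model = deparse1(fit_null$call),
                          alt_model = deparse1(fit_alt$call)),
                     class = "vcm_test"))
  }
  if (df <= 0)
    stop("degenerate test: effective-df difference is not positive (",
         signif(df, 4), ")")
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p,
                 null_model = deparse1(fit_null$call),
                 alt_model = deparse1(fit_alt$call)),
            class = "vcm_test")
}

#' @export
print.vcm_test <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test: chi^2 = %.4f on %.2f df, p = %s\n",
              x$statistic, x$df, format.pval(x$p_value, digits = 4)))
  invisible(x)
}

# resolve a smooth term identifier to its block index
find_smooth_block <- function(fit, term, level = NULL) {
  des <- fit$design
  nms <- vapply(des$blocks, `[[`, "", "name")
  if (!is.null(level)) term <- paste0("s(t):", term, ":", level)
  i <- match(term, nms)
  if (is.na(i) && term %in% c(".intercept", "time", "t"))
    i <- match("s(t)", nms)
  if (is.na(i)) {
    cand <- grep(paste0("^s\\(t\\):", term, ":"), nms)
    if (length(cand) == 1L) i <- cand
  }
  if (is.na(i) || des$blocks[[i]]$type != "smooth")
    stop("no smooth term '", term, "' in this fit; available: ",
         paste(nms[des$smooth_idx], collapse = ", "))
  i
}

#' Approximate significance test of one smooth term
#'
#' Wald-type test of whether a fitted time-varying departure differs from
#' zero: `gamma' V^- gamma` with the covariance pseudo-inverted at rank equal
#' to the rounded effective df of the smooth, referred to a chi-square law.
#' These p-values are approximate and tend to be optimistic
#' (anti-conservative); curves and bands should be inspected alongside them.
#'
#' @param fit A fitted `"vcm"`.
#' @param term Smooth name (e.g. `"s(t):alcohol:Non-drinker"`), or a varying
#'   variable name together with `level`. Use `"s(t)"` for the time-varying
#'   intercept.
#' @param level Optional level when `term` is a variable name.
#' @return A `"vcm_test"` list (`statistic`, `df`, `p_value`).
#' @export
smooth_term_test <- function(fit, term, level = NULL) {
  stopifnot(inherits(fit, "vcm"))
  i <- find_smooth_block(fit, term, level)
  b <- fit$design$blocks[[i]]
  beta_j <- fit$beta[b$cols_c]
  V <- fit$Vb[b$cols_c, b$cols_c, drop = FALSE]
  edf_j <- fit$edf$by_term[[b$name]]
  r <- max(1L, min(as.integer(round(edf_j)), length(beta_j)))
  if (all(abs(beta_j) < 1e-14)) {
    out <- list(statistic = 0, df = r, p_value = 1, term = b$name)
    return(structure(out, class = "vcm_test",
                     note = "approximate; may be optimistic"))
  }
  eg <- eigen(V, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  r <- min(r, sum(pos))
  if (r < 1L) stop("degenerate test: smooth term '", b$name,
                   "' has zero-rank covariance")
  U <- eg$vectors[, seq_len(r), drop = FALSE]
  d <- eg$values[seq_len(r)]
  proj <- as.numeric(crossprod(U, beta_j))
  stat <- sum(proj^2 / d)
  structure(list(statistic = stat, df = r,
                 p_value = stats::pchisq(stat, r, lower.tail = FALSE),
                 term = b$name),
            class = "vcm_test", note = "approximate; may be optimistic")
}

#' Pointwise posterior bands for a combined covariate effect
#'
#' Bayesian credible bands for `b_level + a_level(t)` (the constant category
#' effect plus its time-varying departure) on the linear-predictor scale,
#' from the Gaussian posterior of the coefficients with covariance
#' `(X'WX + P)^{-1} phi`. Reference levels and the time-varying intercept
#' have no constant dummy, so their band covers the smooth alone. Analytic
#' normal-quantile bands by default; optionally simulation-based from
#' posterior draws.
#'
#' @param fit A fitted `"vcm"`.
#' @param term Varying variable name (with `level`) or smooth name; `"s(t)"`
#'   for the time-varying intercept.
#' @param level Category level (see [smooth_term_test()]).
#' @param t_grid Modifier values at which to evaluate (default: observed
#'   waves).
#' @param ci_level Band level (default 0.95).
#' @param method `"analytic"` or `"simulate"`.
#' @param draws Number of posterior draws when simulating (>= 10000
#'   recommended).
#' @param seed Seed for the simulation method.
#' @return Data frame `t`, `estimate`, `se`, `lower`, `upper` with attributes
#'   `term` and `ci_level`.
#' @export
posterior_bands <- function(fit, term, level = NULL, t_grid = NULL,
                            ci_level = 0.95,
                            method = c("analytic", "simulate"),
                            draws = 10000L, seed = NULL) {
  stopifnot(inherits(fit, "vcm"))
  method <- match.arg(method)
  i <- find_smooth_block(fit, term, level)
  b <- fit$design$blocks[[i]]
  if (is.null(t_grid))
    t_grid <- if (!is.null(fit$design$t)) sort(unique(fit$design$t)) else
      seq(fit$spec$basis$domain[1], fit$spec$basis$domain[2], length.out = 55)
  bad <- t_grid < fit$spec$basis$domain[1] | t_grid > fit$spec$basis$domain[2]
  if (any(bad)) stop("t_grid values outside the basis domain")
  m <- length(t_grid)
  C <- matrix(0, m, fit$design$pc)
  C[, b$cols_c] <- bspline_basis(t_grid, fit$spec$basis) %*% fit$design$Zn
  # constant dummy of a non-reference level of the same variable
  if (b$variable != ".intercept") {
    cm <- fit$design$const_map
    j <- which(cm$variable == b$variable & cm$level == b$level)
    if (length(j) == 1L)
      C[, fit$design$blocks[[1]]$cols_c[j]] <- 1
  }
  est <- as.numeric(C %*% fit$beta)
  Vsub <- C %*% fit$Vb %*% t(C)
  se <- sqrt(pmax(diag(Vsub), 0))
  alpha <- 1 - ci_level
  if (method == "analytic") {
    z <- stats::qnorm(1 - alpha / 2)
    lower <- est - z * se
    upper <- est + z * se
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    L <- tryCatch(chol(Vsub), error = function(e) NULL)
    if (is.null(L)) {
      message("posterior covariance not positive definite; ",
              "clipping negative eigenvalues")
      eg <- eigen(Vsub, symmetric = TRUE)
      L <- t(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors)))
    }
    Zdraw <- matrix(stats::rnorm(draws * m), draws, m) %*% L
    sims <- sweep(Zdraw, 2, est, "+")
    lower <- apply(sims, 2, stats::quantile, probs = alpha / 2)
    upper <- apply(sims, 2, stats::quantile, probs = 1 - alpha / 2)
  }
  structure(data.frame(t = t_grid, estimate = est, se = se,
                       lower = lower, upper = upper),
            term = b$name, ci_level = ci_level, method = method)
}
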