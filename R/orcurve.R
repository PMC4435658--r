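# Odds-ratio-over-time curves.

#' Odds-ratio curve for one category of a time-varying covariate
#'
#' Adds the constant estimate of a category to its time-varying spline
#' estimate to obtain the overall effect on the log-odds scale, then
#' exponentiates: `OR(t) = exp(b_level + a_level(t))`. The band exponentiates
#' the posterior band of the combined effect. The curve is undefined for a
#' reference category (its effect is the baseline, identically one), so
#' requesting one is an error.
#'
#' @param fit A fitted binomial `"vcm"`.
#' @param variable A varying covariate of the fit.
#' @param level A non-reference level of that covariate.
#' @param t_grid Time values (default: the observed waves; pass e.g.
#'   `seq(1, 55, length.out = 550)` for a fine plotting grid).
#' @param ci_level Band level (default 0.95).
#' @return An `"or_curve"` data frame: `t`, `or`, `lower`, `upper`, with
#'   `variable`, `level` and `ci_level` attributes.
#' @export
or_curve <- function(fit, variable, level, t_grid = NULL, ci_level = 0.95) {
  stopifnot(inherits(fit, "vcm"))
  if (fit$family != "binomial")
    stop("odds-ratio curves are defined for binomial fits only")
  if (!variable %in% fit$spec$varying)
    stop("'", variable, "' is not a time-varying covariate of this fit")
  ref <- fit$design$levels[[variable]][1]
  if (identical(as.character(level), ref))
    stop("odds-ratio curves cannot be produced for the reference category ('",
         ref, "' is the baseline for '", variable, "')")
  if (!level %in% fit$design$levels[[variable]])
    stop("schema error: unknown level '", level, "' for '", variable, "'")
  pb <- posterior_bands(fit, variable, level = level, t_grid = t_grid,
                        ci_level = ci_level)
  structure(data.frame(t = pb$t, or = exp(pb$estimate),
                       lower = exp(pb$lower), upper = exp(pb$upper)),
            class = c("or_curve", "data.frame"),
            variable = variable, level = level, ci_level = ci_level)
}

#' @export
print.or_curve <- function(x, ...) {
  cat(sprintf("Odds-ratio curve for %s = %s (%d%% band), %d time points\n",
              attr(x, "variable"), attr(x, "level"),
              round(100 * attr(x, "ci_level")), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
plot.or_curve <- function(x, col = "steelblue4", band_col = grDevices::adjustcolor(col, 0.25),
                          xlab = "time (wave)", ylab = "odds ratio", ...) {
  ylim <- range(x$lower, x$upper, 1)
  graphics::plot(x$t, x$or, type = "n", ylim = ylim, xlab = xlab, ylab = ylab,
                 main = paste0(attr(x, "variable"), " = ", attr(x, "level")),
                 ...)
  graphics::polygon(c(x$t, rev(x$t)), c(x$lower, rev(x$upper)),
                    col = band_col, border = NA)
  graphics::lines(x$t, x$or, col = col, lwd = 2)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Write odds-ratio curves of a fit to CSV files
#'
#' One file per non-reference level of each varying covariate, named
#' `or_curve_<variable>_<level>.csv` with columns `t, or, lower, upper`.
#'
#' @param fit A fitted binomial `"vcm"`.
#' @param dir Output directory (created if needed).
#' @param t_grid,ci_level Passed to [or_curve()].
#' @return Invisibly, the vector of files written.
#' @export
write_or_curves <- function(fit, dir, t_grid = NULL, ci_level = 0.95) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (v in fit$spec$varying) {
    lev <- fit$design$levels[[v]]
    for (l in lev[-1]) {
      cur <- or_curve(fit, v, l, t_grid = t_grid, ci_level = ci_level)
      f <- file.path(dir, paste0("or_curve_", make.names(v), "_",
                                 make.names(l), ".csv"))
      utils::write.csv(as.data.frame(cur), f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  invisible(files)
}
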