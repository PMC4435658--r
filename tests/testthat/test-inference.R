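# Effective df, AIC, nested LRTs, smooth tests, posterior bands

test_that("effective df equals the column count at lambda = 0 and the null-space dimension as lambda grows", {
  set.seed(41)
  n <- 400
  d <- data.frame(wave = sample(1:15, n, TRUE))
  d$y <- rnorm(n, sin(d$wave / 2))
  f0 <- vcm(y ~ 1, d, modifier = "wave", varying_intercept = TRUE,
            family = "gaussian", k = 8, lambda = 0)
  expect_equal(f0$edf$total, 1 + 7, tolerance = 1e-8)  # intercept + k-1
  f1 <- vcm(y ~ 1, d, modifier = "wave", varying_intercept = TRUE,
            family = "gaussian", k = 8, lambda = 1e10)
  # order-2 penalty null space: the whole term (constant + centered smooth)
  # tends to intercept + linear trend = 2 df
  expect_equal(f1$edf$total, 2, tolerance = 0.01)
  # per-term edf sums exactly to the total, constants counting 1 each
  expect_equal(sum(f1$edf$by_term), f1$edf$total, tolerance = 1e-10)
  expect_equal(unname(f1$edf$by_term[["(constant)"]]), 1, tolerance = 1e-10)
})

test_that("blockwise edf equals the dense hat-matrix trace", {
  des <- local({
    set.seed(42)
    n <- 300
    d <- data.frame(wave = sample(1:12, n, TRUE),
                    g = factor(sample(c("A", "B", "C"), n, TRUE)))
    d$y <- rbinom(n, 1, plogis(0.3 * (d$g == "B") - 0.2 * (d$g == "C")))
    build_design(d, vcm_spec("y", "g", varying = "g", modifier = "wave",
                             basis = basis_spec(7, 3, c(1, 12))))
  })
  lam <- c(0.7, 3, 12)
  f <- fit_pirls(des, lam)
  # dense oracle: trace of the weighted hat matrix from raw matrices
  Xc <- dense_design(des)
  S <- dense_penalty(des, lam)
  w <- as.numeric(f$fitted.values * (1 - f$fitted.values))
  Xw <- sqrt(w) * Xc
  H <- Xw %*% solve(crossprod(Xw) + S, t(Xw))
  expect_equal(f$edf$total, sum(diag(H)), tolerance = 1e-6)
})

test_that("AIC matches the closed form and a reference GLM implementation", {
  d <- data.frame(wave = rep(1:10, 10), y = rep(c(1, 0), c(30, 70)),
                  g = factor(rep(c("A", "B"), 50)))
  f <- vcm(y ~ 1, d, modifier = "wave")
  expect_equal(model_aic(f), -2 * (30 * log(0.3) + 70 * log(0.7)) + 2,
               tolerance = 1e-8)
  set.seed(43)
  d2 <- data.frame(wave = sample(1:10, 500, TRUE),
                   g = factor(sample(letters[1:3], 500, TRUE)),
                   s = factor(sample(c("F", "M"), 500, TRUE)))
  d2$y <- rbinom(500, 1, plogis(-0.4 + 0.5 * (d2$g == "b") +
                                0.3 * (d2$s == "M")))
  f2 <- vcm(y ~ g + s, d2, modifier = "wave")
  g2 <- stats::glm(y ~ g + s, binomial, d2)
  expect_equal(model_aic(f2), AIC(g2), tolerance = 1e-6)
  expect_equal(AIC(f2), AIC(g2), tolerance = 1e-6)   # via logLik method too
})

test_that("AIC differences between nested fits equal deviance minus 2 edf differences", {
  d <- simulate_brfs(cfg_flat(monthly_n = 30, n_waves = 20), seed = 44)
  f0 <- vcm(smoker ~ g, d, modifier = "wave")
  f1 <- vcm(smoker ~ g, d, modifier = "wave", varying = "g", k = 8)
  expect_equal(f1$aic - f0$aic,
               (f1$deviance - f0$deviance) +
                 2 * (f1$edf$total - f0$edf$total),
               tolerance = 1e-12)
})

test_that("the nested LRT behaves at its boundary cases", {
  d <- simulate_brfs(cfg_flat(monthly_n = 30, n_waves = 20), seed = 45)
  f0 <- vcm(smoker ~ g, d, modifier = "wave")
  t_same <- lrt_nested(f0, f0)
  expect_equal(t_same$statistic, 0)
  expect_equal(t_same$p_value, 1)
  # chi-square mapping at a textbook value
  expect_equal(stats::pchisq(3.84, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  f1 <- vcm(smoker ~ g, d, modifier = "wave", varying = "g", k = 8)
  tt <- lrt_nested(f0, f1)
  expect_gte(tt$statistic, 0)
  expect_gt(tt$df, 0)
  expect_true(tt$p_value >= 0 && tt$p_value <= 1)
  # non-nested specs refuse
  d$z <- factor(sample(c("u", "v"), nrow(d), TRUE))
  f2 <- vcm(smoker ~ z, d, modifier = "wave")
  expect_error(lrt_nested(f2, f1), "nesting error")
})

test_that("LRT statistics are invariant to row order and term order", {
  d <- simulate_brfs(cfg_multi(monthly_n = 25, varying = FALSE), seed = 46)
  f0 <- vcm(smoker ~ age + sex + alcohol + income, d, modifier = "wave")
  f1 <- vcm(smoker ~ age + sex + alcohol + income, d, modifier = "wave",
            varying = "age", k = 8)
  t1 <- lrt_nested(f0, f1)
  perm <- sample(nrow(d))
  dp <- d[perm, ]
  f0p <- vcm(smoker ~ sex + income + age + alcohol, dp, modifier = "wave")
  f1p <- vcm(smoker ~ sex + income + age + alcohol, dp, modifier = "wave",
             varying = "age", k = 8)
  t1p <- lrt_nested(f0p, f1p)
  expect_equal(t1$statistic, t1p$statistic, tolerance = 1e-6)
  expect_equal(t1$df, t1p$df, tolerance = 1e-6)
})

test_that("smooth-term Wald test returns p = 1 for an exactly null smooth", {
  d <- simulate_brfs(cfg_flat(monthly_n = 30, n_waves = 20), seed = 47)
  f <- vcm(smoker ~ g, d, modifier = "wave", varying = "g", k = 8,
           lambda = 5)
  fake <- f
  fake$beta[f$design$blocks[[f$design$smooth_idx[1]]]$cols_c] <- 0
  tt <- smooth_term_test(fake, names(f$gamma)[1])
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)
})

test_that("smooth-term test detects strong time variation and respects flat truth", {
  # strongly varying truth: essentially always detected
  hits <- 0L
  for (s in 1:8) {
    d <- simulate_brfs(cfg_wiggly(monthly_n = 120, amplitude = 1.2),
                       seed = 500 + s)
    f <- vcm(smoker ~ g, d, modifier = "wave", varying = "g", k = 10,
             control = fast_control())
    tt <- smooth_term_test(f, "g", level = "B")
    if (tt$p_value < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 7L)
  # flat truth: rejections at 5% stay modest
  rej <- 0L
  for (s in 1:40) {
    d <- simulate_brfs(cfg_flat(monthly_n = 25, n_waves = 25),
                       seed = 600 + s)
    f <- vcm(smoker ~ g, d, modifier = "wave", varying = "g", k = 8,
             control = fast_control())
    tt <- smooth_term_test(f, "g", level = "B")
    if (tt$p_value < 0.05) rej <- rej + 1L
  }
  expect_lte(rej / 40, 0.125)
})

test_that("analytic posterior bands use the Gaussian quantile and match simulation", {
  d <- simulate_brfs(cfg_wiggly(monthly_n = 50, n_waves = 20), seed = 48)
  f <- vcm(smoker ~ g, d, modifier = "wave", varying = "g", k = 8)
  pb <- posterior_bands(f, "g", level = "B")
  expect_equal(pb$upper, pb$estimate + 1.959964 * pb$se, tolerance = 1e-6)
  expect_equal(pb$lower, pb$estimate - 1.959964 * pb$se, tolerance = 1e-6)
  # at 100k draws the MC error of a 97.5% quantile is ~0.0085 SE pointwise,
  # so the simulated band agrees with the analytic one to ~0.01 SE on
  # average (and within a few MC standard errors everywhere)
  ps <- posterior_bands(f, "g", level = "B", method = "simulate",
                        draws = 100000, seed = 1)
  expect_lt(mean(abs(ps$lower - pb$lower) / pb$se), 0.01)
  expect_lt(mean(abs(ps$upper - pb$upper) / pb$se), 0.01)
  expect_lt(max(abs(ps$upper - pb$upper) / pb$se), 0.04)
  expect_lt(max(abs(ps$lower - pb$lower) / pb$se), 0.04)
})

test_that("posterior bands cover the true combined effect at near-nominal rates", {
  # pointwise coverage of the true constant+varying log-OR, averaged over
  # the grid, across replicated small surveys
  cfg <- cfg_wiggly(monthly_n = 250, n_waves = 25, amplitude = 0.4,
                    cycles = 1)
  tg <- 1:25
  truth <- log(true_or_curve(cfg, "g", "B", tg))
  nrep <- 60
  cover <- matrix(NA, nrep, length(tg))
  for (s in seq_len(nrep)) {
    d <- simulate_brfs(cfg, seed = 700 + s)
    f <- vcm(smoker ~ g, d, modifier = "wave", varying = "g", k = 12,
             control = fast_control())
    pb <- posterior_bands(f, "g", level = "B", t_grid = tg)
    cover[s, ] <- pb$lower <= truth & truth <= pb$upper
  }
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})
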