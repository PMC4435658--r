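# Synthetic surveillance-data generator

test_that("generation is seed-deterministic and restores the RNG state", {
  cfg <- cfg_flat(monthly_n = 20, n_waves = 10)
  set.seed(999)
  before <- rnorm(1)
  set.seed(999)
  d1 <- simulate_brfs(cfg, seed = 5)
  d2 <- simulate_brfs(cfg, seed = 5)
  expect_identical(d1, d2)
  after <- rnorm(1)
  expect_identical(before, after)   # caller RNG stream untouched
  d3 <- simulate_brfs(cfg, seed = 6)
  expect_false(identical(d1$smoker, d3$smoker))
})

test_that("the passi preset carries the published sample marginals", {
  cfg <- brfs_config(preset = "passi", monthly_n = 10)
  expect_equal(unname(cfg$covariates$alcohol[c("High risk drinker",
                                               "Low risk drinker",
                                               "Non-drinker")]),
               c(0.102, 0.284, 0.614), tolerance = 0.005)
  # reference levels lead their factors
  expect_identical(names(cfg$covariates$age)[1], "60-69")
  expect_identical(names(cfg$covariates$alcohol)[1], "High risk drinker")
  # mean OR of the youngest age group matches the published constant OR
  or <- true_or_curve(cfg, "age", "18-29", 1:55)
  expect_equal(exp(mean(log(or))), 2.08, tolerance = 1e-10)
})

test_that("empirical covariate marginals and prevalence match the config", {
  cfg <- brfs_config(preset = "passi", monthly_n = 400)
  d <- simulate_brfs(cfg, seed = 21)
  n <- nrow(d)
  for (v in names(cfg$covariates)) {
    p <- cfg$covariates[[v]]
    emp <- as.numeric(table(d[[v]])[names(p)]) / n
    tol <- 3 * sqrt(p * (1 - p) / n)
    expect_true(all(abs(emp - p) < tol + 1e-12))
  }
  # calibrated intercept delivers the target prevalence
  expect_lt(abs(mean(d$smoker) - 0.279), 0.01)
})

test_that("zero effects and zero intercept give 50% prevalence", {
  cfg <- brfs_config(covariates = list(g = c(A = 0.5, B = 0.5)),
                     intercept_log_odds = 0, n_waves = 20, monthly_n = 500)
  d <- simulate_brfs(cfg, seed = 22)
  se <- sqrt(0.25 / nrow(d))
  expect_lt(abs(mean(d$smoker) - 0.5), 3 * se)
})

test_that("constant log-ORs are recovered by a large-sample logistic regression", {
  cfg <- brfs_config(
    covariates = list(g = c(A = 0.5, B = 0.5),
                      h = c(x = 0.6, y = 0.3, z = 0.1)),
    constant_log_or = list(g = c(B = 0.4), h = c(y = -0.3, z = 0.25)),
    intercept_log_odds = -1, n_waves = 10, monthly_n = 100000)
  d <- simulate_brfs(cfg, seed = 23)
  g <- stats::glm(smoker ~ g + h, binomial, d)
  est <- coef(g)
  expect_equal(unname(est[c("gB", "hy", "hz")]), c(0.4, -0.3, 0.25),
               tolerance = 0.02)
  expect_lt(abs(est[["(Intercept)"]] - (-1)), 0.02)
})

test_that("waves are exchangeable under flat effects", {
  cfg <- cfg_flat(monthly_n = 300, n_waves = 40)
  d <- simulate_brfs(cfg, seed = 24)
  prev <- tapply(d$smoker, d$wave, mean)
  sl <- stats::lm(prev ~ seq_along(prev))
  ci <- stats::confint(sl)[2, ]
  expect_true(ci[1] <= 0 && 0 <= ci[2])
})

test_that("true_or_curve reflects the declared truth exactly", {
  cfg <- brfs_config(
    covariates = list(g = c(A = 0.5, B = 0.5)),
    constant_log_or = list(g = c(B = log(2))),
    varying = list(list(variable = "g", level = "B",
                        fun = vfun_linear(-0.4))),
    intercept_log_odds = -1, n_waves = 21, monthly_n = 10)
  t <- 1:21
  or <- true_or_curve(cfg, "g", "B", t)
  # flat part: mean log OR equals the constant
  expect_equal(mean(log(or)), log(2), tolerance = 1e-12)
  # linear varying part: log OR is linear in t with the declared total change
  expect_equal(diff(log(or)), rep(-0.4 / 20, 20), tolerance = 1e-12)
  # flat function leaves the OR constant
  cfg2 <- brfs_config(covariates = cfg$covariates,
                      constant_log_or = list(g = c(B = log(2))),
                      varying = list(list(variable = "g", level = "B",
                                          fun = vfun_flat())),
                      intercept_log_odds = -1, n_waves = 21, monthly_n = 10)
  expect_equal(true_or_curve(cfg2, "g", "B", t), rep(2, 21))
  # reference level has no OR
  expect_error(true_or_curve(cfg, "g", "A", t), "reference")
})

test_that("varying shapes are mean-zero over the waves by construction", {
  nw <- 30
  for (vf in list(vfun_linear(0.7), vfun_sine(0.3, 2.5, 1),
                  vfun_piecewise(c(1, 10, 30), c(0.5, -0.2, 0.1)))) {
    vals <- trendvcm:::eval_vfun(vf, seq_len(nw), nw)
    expect_lt(abs(mean(vals)), 1e-12)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(brfs_config(covariates = list(g = c(A = 0.6, B = 0.6))),
               "config error")
  expect_error(brfs_config(covariates = list(g = c(0.5, 0.5))),
               "config error")
  expect_error(
    brfs_config(covariates = list(g = c(A = 0.5, B = 0.5)),
                varying = list(list(variable = "q", level = "B",
                                    fun = vfun_flat())),
                intercept_log_odds = 0),
    "config error")
})

test_that("generator configurations round-trip through JSON", {
  cfg <- cfg_wiggly(monthly_n = 15, n_waves = 12, amplitude = 0.4)
  f <- withr::local_tempfile(fileext = ".json")
  write_brfs_config(cfg, f)
  back <- read_brfs_config(f)
  expect_equal(back$covariates, cfg$covariates)
  expect_equal(back$intercept_log_odds, cfg$intercept_log_odds)
  d1 <- simulate_brfs(cfg, seed = 3)
  d2 <- simulate_brfs(back, seed = 3)
  attr(d1, "config") <- attr(d2, "config") <- NULL
  expect_identical(d1, d2)
})
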