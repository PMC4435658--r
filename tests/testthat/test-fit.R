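# Penalized least squares and penalized IRLS estimation

gaussian_design <- function(n = 200, k = 8, seed = 1, n_waves = 20) {
  set.seed(seed)
  d <- data.frame(
    wave = sample(seq_len(n_waves), n, replace = TRUE),
    g = factor(sample(c("A", "B"), n, TRUE)))
  d$y <- rnorm(n, 0.5 + 0.8 * (d$g == "B") + sin(d$wave / 3) *
                 ifelse(d$g == "B", 1, -1))
  sp <- vcm_spec("y", "g", varying = "g", modifier = "wave",
                 family = "gaussian", basis = basis_spec(k, 3, c(1, n_waves)))
  list(data = d, design = build_design(d, sp))
}

test_that("zero penalty reduces penalized least squares to OLS", {
  gd <- gaussian_design()
  f <- fit_gaussian(gd$design, 0)
  ol <- stats::lm.fit(dense_design(gd$design), gd$design$y)
  expect_equal(f$beta, unname(ol$coefficients), tolerance = 1e-8)
  expect_equal(f$deviance, sum(ol$residuals^2), tolerance = 1e-10)
  expect_equal(f$edf$total, gd$design$pc, tolerance = 1e-8)
})

test_that("huge order-2 penalties force each fitted smooth to a straight line", {
  gd <- gaussian_design(n = 400, seed = 3)
  f <- fit_gaussian(gd$design, 1e8)
  tg <- seq(1, 20, length.out = 60)
  B <- bspline_basis(tg, gd$design$spec$basis)
  for (nm in names(f$gamma)) {
    curve <- as.numeric(B %*% f$gamma[[nm]])
    line <- stats::lm.fit(cbind(1, tg), curve)
    rng <- diff(range(curve))
    if (rng < 1e-12) rng <- 1  # already flat
    expect_lt(max(abs(line$residuals)), 1e-6 * max(rng, 1e-6))
  }
})

test_that("penalized least squares matches an independent augmented-regression solution", {
  for (seed in 1:3) {
    gd <- gaussian_design(n = 200, k = 8, seed = seed)
    lam <- c(2.5, 40)
    f <- fit_gaussian(gd$design, lam)
    Xc <- dense_design(gd$design)
    S <- dense_penalty(gd$design, lam)
    beta_o <- augmented_ls(Xc, gd$design$y, S)
    expect_equal(f$beta, unname(beta_o), tolerance = 1e-8)
  }
})

test_that("intercept-only logistic PIRLS recovers the closed-form Bernoulli MLE", {
  d <- data.frame(wave = rep(1:10, 10), y = rep(c(1, 0), c(30, 70)),
                  g = factor(rep(c("A", "B"), 50)))
  f <- vcm(y ~ 1, d, modifier = "wave")
  expect_equal(unname(coef(f)[1]), log(30 / 70), tolerance = 1e-8)
  expect_equal(f$aic, -2 * (30 * log(0.3) + 70 * log(0.7)) + 2,
               tolerance = 1e-6)
})

test_that("the Gaussian family run through the PIRLS front end equals the closed form", {
  gd <- gaussian_design(seed = 5)
  f1 <- fit_gaussian(gd$design, 3)
  f2 <- fit_pirls(gd$design, 3)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$deviance, f2$deviance, tolerance = 1e-10)
})

logistic_instance <- function(seed, n = 300, k = 8, n_waves = 20) {
  set.seed(seed)
  d <- data.frame(
    wave = sample(seq_len(n_waves), n, replace = TRUE),
    g = factor(sample(c("A", "B"), n, TRUE)))
  eta <- -0.5 + 0.8 * (d$g == "B") + 0.8 * sin(d$wave / 3) * (d$g == "B")
  d$y <- rbinom(n, 1, plogis(eta))
  sp <- vcm_spec("y", "g", varying = "g", modifier = "wave",
                 basis = basis_spec(k, 3, c(1, n_waves)))
  build_design(d, sp)
}

test_that("PIRLS maximizes the penalized log-likelihood (optimizer oracle)", {
  for (seed in 1:3) {
    des <- logistic_instance(seed)
    lam <- c(1, 10)
    f <- fit_pirls(des, lam)
    Xc <- dense_design(des)
    S <- dense_penalty(des, lam)
    pd_fit <- pen_dev_logistic(f$beta, Xc, des$y, S)
    op <- optim_logistic(Xc, des$y, S)
    expect_equal(pd_fit, op$value, tolerance = 1e-6)
    # and beats random coefficient vectors
    set.seed(seed + 100)
    rand <- replicate(50, pen_dev_logistic(rnorm(des$pc, sd = 0.5), Xc,
                                           des$y, S))
    expect_true(all(pd_fit <= rand))
  }
})

test_that("penalized deviance is non-increasing across PIRLS iterations", {
  for (seed in 4:8) {
    des <- logistic_instance(seed)
    f <- fit_pirls(des, 0.5)
    expect_true(all(diff(f$dev_trace) <= 1e-8))
    expect_true(f$converged)
  }
})

test_that("total effective df is non-increasing in lambda", {
  des <- logistic_instance(11)
  edfs <- vapply(10^seq(-3, 5), function(l) fit_pirls(des, l)$edf$total,
                 numeric(1))
  expect_true(all(diff(edfs) < 1e-8))
})

test_that("adding a varying term never increases deviance at lambda = 0", {
  set.seed(21)
  d <- data.frame(
    wave = sample(1:12, 400, replace = TRUE),
    g = factor(sample(c("A", "B"), 400, TRUE)))
  d$y <- rbinom(400, 1, plogis(-0.3 + 0.4 * (d$g == "B")))
  f0 <- vcm(y ~ g, d, modifier = "wave", k = 6)
  f1 <- vcm(y ~ g, d, modifier = "wave", varying = "g", k = 6, lambda = 0)
  expect_lte(f1$deviance, f0$deviance + 1e-8)
})

test_that("quasi-separation triggers a warning and a ridge fallback", {
  set.seed(31)
  n <- 300
  d <- data.frame(wave = sample(1:10, n, TRUE),
                  g = factor(sample(c("A", "B"), n, TRUE)))
  d$y <- as.numeric(d$g == "B")  # perfectly separated
  expect_warning(vcm(y ~ g, d, modifier = "wave",
                     control = vcm_control(epsilon = 1e-14, maxit = 400)),
                 "quasi-separation")
})
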