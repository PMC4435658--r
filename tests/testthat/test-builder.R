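# Screening and forward selection of time-varying terms

test_that("screening flags the truly varying covariate with good power", {
  # variance-matched amplitudes at this reduced n keep detectability
  # comparable to the full surveillance setting
  hits <- 0L
  nrep <- 12L
  for (s in seq_len(nrep)) {
    cfg <- cfg_multi(monthly_n = 100, varying = TRUE, amplitude_scale = 5)
    d <- simulate_brfs(cfg, seed = 800 + s)
    sc <- screen_varying(smoker ~ age + sex + alcohol + income, d, "wave",
                         k = 10, include_intercept = FALSE,
                         control = fast_control())
    row <- sc[sc$variable == "age", ]
    if (isTRUE(row$significant)) hits <- hits + 1L
  }
  expect_gte(hits / nrep, 0.8)
})

test_that("screening output is sorted and records per-row failures non-fatally", {
  d <- simulate_brfs(cfg_multi(monthly_n = 60, varying = FALSE), seed = 81)
  sc <- screen_varying(smoker ~ age + sex + alcohol + income, d, "wave",
                       k = 8, control = fast_control())
  expect_s3_class(sc, "vcm_screen")
  expect_setequal(sc$variable,
                  c("age", "sex", "alcohol", "income", ".intercept"))
  p <- sc$p_value
  expect_true(all(diff(p[!is.na(p)]) >= 0))
  expect_s3_class(attr(sc, "null_fit"), "vcm")
})

test_that("candidate ranking scores lie in [0,1] and included terms score near zero", {
  cfg <- cfg_multi(monthly_n = 120, varying = TRUE, amplitude_scale = 5)
  d <- simulate_brfs(cfg, seed = 82)
  f <- vcm(smoker ~ age + sex + alcohol + income, d, "wave",
           varying = "age", k = 10, control = fast_control())
  rk <- rank_candidates(f, d, c("alcohol", "sex", "income"), k = 8)
  expect_true(all(rk$score >= 0 & rk$score <= 1))
  # a candidate already accounted for explains essentially nothing
  rk2 <- rank_candidates(f, d, "age", k = 8)
  expect_lt(rk2$score, 0.005)
  expect_identical(rank_candidates(f, d, character(0))$variable,
                   character(0))
})

test_that("higher-amplitude varying terms rank above lower-amplitude ones", {
  wins <- 0L
  nrep <- 10L
  for (s in seq_len(nrep)) {
    cfg <- brfs_config(
      covariates = list(big = c(A = 0.5, B = 0.5),
                        small = c(u = 0.5, v = 0.5)),
      constant_log_or = list(big = c(B = 0.4), small = c(v = 0.3)),
      varying = list(
        list(variable = "big", level = "B", fun = vfun_linear(-1.6)),
        list(variable = "small", level = "v", fun = vfun_linear(-0.5))),
      target_prevalence = 0.3, n_waves = 30, monthly_n = 150)
    d <- simulate_brfs(cfg, seed = 830 + s)
    f <- vcm(smoker ~ big + small, d, "wave", k = 8,
             control = fast_control())
    rk <- rank_candidates(f, d, c("big", "small"), k = 8)
    if (rk$variable[1] == "big") wins <- wins + 1L
  }
  expect_gte(wins / nrep, 0.9)
})

test_that("forward selection recovers the truly varying pair and nothing else (most of the time)", {
  nrep <- 12L
  exact <- 0L
  for (s in seq_len(nrep)) {
    cfg <- cfg_multi(monthly_n = 100, varying = TRUE, amplitude_scale = 5)
    d <- simulate_brfs(cfg, seed = 840 + s)
    sel <- forward_select(smoker ~ age + sex + alcohol + income, d, "wave",
                          k = 10, control = fast_control())
    if (setequal(sel$varying, c("age", "alcohol"))) exact <- exact + 1L
  }
  expect_gte(exact / nrep, 0.7)
})

test_that("a single significant screened candidate degenerates to a one-step trace", {
  cfg <- cfg_wiggly(monthly_n = 150, n_waves = 30, amplitude = 1.2)
  d <- simulate_brfs(cfg, seed = 85)
  sel <- forward_select(smoker ~ g, d, "wave", k = 10,
                        include_intercept = FALSE,
                        control = fast_control())
  expect_identical(sel$varying, "g")
  expect_identical(sel$trace$model, c("LM", "M1"))
  expect_lt(sel$trace$p_value[2], 0.05)
})

test_that("selection never adds a term that failed screening", {
  d <- simulate_brfs(cfg_multi(monthly_n = 60, varying = FALSE), seed = 86)
  sel <- forward_select(smoker ~ age + sex + alcohol + income, d, "wave",
                        k = 8, control = fast_control())
  sc <- as.data.frame(sel$screen)
  failed <- sc$variable[!is.na(sc$significant) & !sc$significant]
  expect_length(intersect(sel$varying, failed), 0)
  if (".intercept" %in% failed) expect_false(sel$varying_intercept)
})

test_that("the selection trace is reproducible by refitting the named models", {
  cfg <- cfg_multi(monthly_n = 80, varying = TRUE, amplitude_scale = 5)
  d <- simulate_brfs(cfg, seed = 87)
  sel <- forward_select(smoker ~ age + sex + alcohol + income, d, "wave",
                        k = 8, include_intercept = FALSE,
                        control = fast_control())
  tr <- sel$trace
  m1 <- tr[tr$model == "M1", ]
  first <- sub("LM \\+ s\\(t\\):", "", m1$description)
  f0 <- vcm(smoker ~ age + sex + alcohol + income, d, "wave", k = 8,
            control = fast_control())
  f1 <- vcm(smoker ~ age + sex + alcohol + income, d, "wave",
            varying = first, k = 8, control = fast_control())
  tt <- lrt_nested(f0, f1)
  expect_equal(tt$p_value, m1$p_value, tolerance = 1e-8)
  expect_equal(f1$aic, m1$aic, tolerance = 1e-6)
})
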