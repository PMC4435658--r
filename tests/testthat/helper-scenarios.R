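# Small generator configurations shared across tests. Effect sizes for the
# reduced-n scenarios are variance-matched (amplitudes scaled up by roughly
# sqrt(n_full / n_test)) so detectability mirrors the full-scale surveillance
# setting; marginals and the outcome prevalence stay realistic.

# one binary covariate, flat truth
cfg_flat <- function(monthly_n = 60, n_waves = 55) {
  brfs_config(covariates = list(g = c(A = 0.5, B = 0.5)),
              constant_log_or = list(g = c(B = 0.5)),
              target_prevalence = 0.3, n_waves = n_waves,
              monthly_n = monthly_n)
}

# one binary covariate with a strongly varying effect
cfg_wiggly <- function(monthly_n = 60, n_waves = 55, amplitude = 1,
                       cycles = 1.5) {
  brfs_config(covariates = list(g = c(A = 0.5, B = 0.5)),
              constant_log_or = list(g = c(B = 0.5)),
              varying = list(list(variable = "g", level = "B",
                                  fun = vfun_sine(amplitude, cycles = cycles))),
              target_prevalence = 0.3, n_waves = n_waves,
              monthly_n = monthly_n)
}

# several covariates; `varying` switches the age/alcohol-like truth on
cfg_multi <- function(monthly_n = 150, n_waves = 55, varying = TRUE,
                      amplitude_scale = 1) {
  vy <- if (varying) list(
    list(variable = "age", level = "young",
         fun = vfun_linear(-0.211 * amplitude_scale)),
    list(variable = "alcohol", level = "none",
         fun = vfun_linear(-0.20 * amplitude_scale))) else list()
  brfs_config(
    covariates = list(
      age = c(old = 0.35, young = 0.30, mid = 0.35),
      sex = c(F = 0.51, M = 0.49),
      alcohol = c(high = 0.10, low = 0.28, none = 0.62),
      income = c(high = 0.47, low = 0.53)),
    constant_log_or = list(
      age = c(young = log(2.08), mid = log(1.75)),
      sex = c(M = log(1.61)),
      alcohol = c(low = log(0.69), none = log(0.47)),
      income = c(low = log(1.5))),
    varying = vy, target_prevalence = 0.279,
    n_waves = n_waves, monthly_n = monthly_n)
}

# quick fitting options for replicated simulations
fast_control <- function() vcm_control(refine_maxit = 40L)
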