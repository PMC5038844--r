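# Shared fixtures, all built in code.

# Posterior-median parameter set (the package defaults) and default constants.
fix_params <- function(...) model_parameters(...)
fix_consts <- function(...) leaf_constants(...)
fix_fconsts <- function(...) farquhar_constants(...)

# Step-change light protocol: 30 min at 100 then 2 h at 1000 umol m^-2 s^-1.
fix_step_env <- function(ppfd_low = 100, ppfd_high = 1000) {
  environment_series(c(-1800, 0, 0, 7200),
                     c(ppfd_low, ppfd_low, ppfd_high, ppfd_high),
                     interp = "constant")
}

# Diurnal fluctuating regime with 30-min dark margins on both sides, the
# calibration design used for parameter-recovery checks (dark data identify
# the minimum pore area, as in the measurement protocol the model emulates).
fix_recovery_env <- function(seed = 5) {
  genv <- gaussian_fluctuating_light(day_length = 21600, peak_ppfd = 1000,
                                     sd_time = 3600,
                                     fluctuation_amplitude = 0.3,
                                     correlation_time = 600,
                                     sampling_interval = 120, seed = seed)
  environment_series(c(0, 1799, genv$time + 1800, 25201, 27000),
                     c(0, 0, genv$PPFD, 0, 0))
}

# Identifiable subset fitted in recovery tests (electron-transport limited
# under these conditions, so J_max rather than Vc_max).
fix_fit_names <- c("a_min", "alpha_L", "k_i", "k_d", "J_max", "alpha")

fix_fit_priors <- function() {
  pr <- default_priors()
  pr[pr$parameter %in% fix_fit_names, ]
}

# CDF of a Gaussian truncated to [lo, hi], for KS checks against the prior.
ptrunc_norm <- function(q, mean, sd, lo = -Inf, hi = Inf) {
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  pmin(pmax((pnorm(q, mean, sd) - p_lo) / (p_hi - p_lo), 0), 1)
}
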