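# Light-regime and observation generators: determinism, noise statistics and
# robustness of the simulator across generated regimes.

test_that("the fluctuating generator is deterministic and reduces to the envelope", {
  e1 <- gaussian_fluctuating_light(seed = 11)
  e2 <- gaussian_fluctuating_light(seed = 11)
  expect_identical(e1$PPFD, e2$PPFD)
  e3 <- gaussian_fluctuating_light(seed = 12)
  expect_false(identical(e1$PPFD, e3$PPFD))
  smooth <- gaussian_fluctuating_light(fluctuation_amplitude = 0)
  tt <- smooth$time
  envl <- 1000 * exp(-(tt - 21600)^2 / (2 * 7200^2))
  expect_equal(smooth$PPFD, envl)
  # symmetric about the peak
  expect_equal(smooth$PPFD, rev(smooth$PPFD))
  expect_true(all(e1$PPFD >= 0))
})

test_that("the multiplicative noise has unit mean at the envelope peak", {
  vals <- vapply(1:100, function(s) {
    e <- gaussian_fluctuating_light(day_length = 7200, peak_time = 3600,
                                    sd_time = 1200, sampling_interval = 300,
                                    seed = s)
    e$PPFD[e$time == 3600]
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1000), 3 * se)
})

test_that("the natural-like regime matches its change-interval statistics", {
  env <- natural_like_light(day_length = 43200, mean_change_interval = 480,
                            sampling_interval = 60, seed = 4)
  expect_true(all(env$PPFD >= 0 & env$PPFD <= 1000))
  changes <- which(diff(env$PPFD) != 0)
  mean_interval <- 43200 / (length(changes) + 1)
  expect_lt(abs(mean_interval - 480) / 480, 0.10)
  c1 <- natural_like_light(mean_change_interval = Inf, seed = 1)
  c2 <- natural_like_light(mean_change_interval = Inf, seed = 99)
  expect_identical(c1$PPFD, c2$PPFD)   # infinite interval: no random changes
  expect_true(all(diff(c1$PPFD[c1$time <= 21600]) >= 0))  # pure envelope
})

test_that("observation noise is additive with the configured spread", {
  env <- environment_series(c(0, 1800, 1800, 14400), c(100, 100, 700, 700),
                            interp = "constant")
  syn0 <- synthetic_observations(env, sigma_A = 0, sigma_gs = 0, seed = 1)
  expect_equal(syn0$obs$A, syn0$truth$A)     # zero noise: exact model output
  expect_equal(syn0$obs$g_s, syn0$truth$g_s)
  syn1 <- synthetic_observations(env, sigma_A = 0.6, sigma_gs = 0.014, seed = 1)
  syn2 <- synthetic_observations(env, sigma_A = 0.6, sigma_gs = 0.014, seed = 2)
  # the latent trajectory is shared; only the noise differs between seeds
  expect_equal(syn1$truth$A, syn2$truth$A)
  expect_false(identical(syn1$obs$A, syn2$obs$A))
  resid_A <- unlist(lapply(1:12, function(s)
    synthetic_observations(env, sigma_A = 0.6, sigma_gs = 0.014,
                           seed = s)$obs$A - syn0$truth$A))
  expect_lt(abs(sd(resid_A) - 0.6) / 0.6, 0.10)
  resid_g <- unlist(lapply(1:12, function(s)
    synthetic_observations(env, sigma_A = 0.6, sigma_gs = 0.014,
                           seed = s)$obs$g_s - syn0$truth$g_s))
  expect_lt(abs(sd(resid_g) - 0.014) / 0.014, 0.10)
})

test_that("generated regimes drive the simulator without failure across seeds", {
  for (s in 1:25) {
    env <- if (s %% 2 == 0)
      gaussian_fluctuating_light(day_length = 10800, peak_time = 5400,
                                 sd_time = 1800, sampling_interval = 120,
                                 seed = s)
    else natural_like_light(day_length = 10800, peak_time = 5400,
                            sd_time = 1800, sampling_interval = 120, seed = s)
    sim <- simulate_gas_exchange(env, output_times = seq(0, 10800, 600))
    expect_true(all(is.finite(sim$a)), info = paste("seed", s))
    expect_true(all(sim$L >= 0 & sim$L <= 1), info = paste("seed", s))
  }
})
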