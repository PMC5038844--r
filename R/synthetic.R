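# Synthetic data generators: diurnal light regimes (a smooth Gaussian envelope
# with autocorrelated fluctuations, and a piecewise-constant 'natural-like'
# regime) and noisy gas-exchange observations with known generating
# parameters, so that calibration can be exercised without any recorded data.

#' Gaussian diurnal light regime with autocorrelated fluctuations
#'
#' A Gaussian irradiance envelope over the photoperiod multiplied by unit-mean
#' log-normal AR(1) noise (multiplicative, so fluctuations scale with the
#' envelope), clipped at zero. Deterministic for a fixed seed.
#'
#' @param day_length Photoperiod length (s), default 12 h.
#' @param peak_ppfd Envelope peak (umol m^-2 s^-1).
#' @param peak_time Time of the envelope peak (s); default mid-photoperiod.
#' @param sd_time Envelope standard deviation (s); default `day_length / 6`.
#' @param fluctuation_amplitude Coefficient of variation of the multiplicative
#'   noise (0 disables fluctuations).
#' @param correlation_time Autocorrelation time of the noise (s).
#' @param sampling_interval Output sampling interval (s).
#' @param Ca,T_leaf Constant cuvette conditions.
#' @param seed Integer seed.
#' @return An [environment_series()] covering `[0, day_length]`.
#' @examples
#' env <- gaussian_fluctuating_light(seed = 1)
#' @export
gaussian_fluctuating_light <- function(day_length = 43200, peak_ppfd = 1000,
                                       peak_time = day_length / 2,
                                       sd_time = day_length / 6,
                                       fluctuation_amplitude = 0.3,
                                       correlation_time = 600,
                                       sampling_interval = 60,
                                       Ca = 400, T_leaf = 25, seed = 1) {
  stopifnot(day_length > 0, peak_ppfd > 0, sd_time > 0,
            fluctuation_amplitude >= 0, correlation_time > 0,
            sampling_interval > 0)
  tt <- seq(0, day_length, by = sampling_interval)
  envelope <- peak_ppfd * exp(-(tt - peak_time)^2 / (2 * sd_time^2))
  mult <- rep(1, length(tt))
  if (fluctuation_amplitude > 0) {
    set.seed(seed)
    s2 <- log(1 + fluctuation_amplitude^2)   # log-scale variance for the CV
    phi <- exp(-sampling_interval / correlation_time)
    x <- numeric(length(tt))
    x[1] <- rnorm(1, 0, sqrt(s2))
    for (i in seq_along(tt)[-1])
      x[i] <- phi * x[i - 1] + rnorm(1, 0, sqrt(s2 * (1 - phi^2)))
    mult <- exp(x - s2 / 2)                  # unit-mean log-normal
  }
  environment_series(tt, pmax(envelope * mult, 0), Ca = Ca, T_leaf = T_leaf)
}

#' Natural-like piecewise-constant light regime
#'
#' Emulates the statistics of a recorded field irradiance series: the light
#' changes at exponentially distributed intervals (configurable mean time
#' between changes), each segment drawing a level uniformly between zero and a
#' Gaussian diurnal envelope evaluated at the segment start. All values lie in
#' `[0, peak_ppfd]`; an infinite `mean_change_interval` yields constant light
#' at the envelope.
#'
#' @param day_length Photoperiod length (s).
#' @param peak_ppfd Envelope peak (umol m^-2 s^-1).
#' @param mean_change_interval Mean time between light changes (s),
#'   default 480 s (8 min).
#' @param peak_time,sd_time Envelope location and width (s).
#' @param min_fraction Lower bound of the segment level as a fraction of the
#'   envelope.
#' @param sampling_interval Output sampling interval (s).
#' @param Ca,T_leaf Constant cuvette conditions.
#' @param seed Integer seed.
#' @return An [environment_series()] (constant interpolation).
#' @export
natural_like_light <- function(day_length = 43200, peak_ppfd = 1000,
                               mean_change_interval = 480,
                               peak_time = day_length / 2,
                               sd_time = day_length / 6,
                               min_fraction = 0.1,
                               sampling_interval = 60,
                               Ca = 400, T_leaf = 25, seed = 1) {
  stopifnot(day_length > 0, peak_ppfd > 0, mean_change_interval > 0,
            min_fraction >= 0, min_fraction <= 1)
  envelope <- function(t) peak_ppfd * exp(-(t - peak_time)^2 / (2 * sd_time^2))
  tt <- seq(0, day_length, by = sampling_interval)
  if (!is.finite(mean_change_interval))
    return(environment_series(tt, envelope(tt), Ca = Ca, T_leaf = T_leaf,
                              interp = "constant"))
  set.seed(seed)
  change_times <- 0
  while (max(change_times) < day_length)
    change_times <- c(change_times,
                      max(change_times) + stats::rexp(1, 1 / mean_change_interval))
  levels <- stats::runif(length(change_times), min_fraction, 1) *
    envelope(change_times)
  lev_fun <- approxfun(change_times, levels, method = "constant",
                       rule = 2, f = 0)
  environment_series(tt, pmin(pmax(lev_fun(tt), 0), peak_ppfd),
                     Ca = Ca, T_leaf = T_leaf, interp = "constant")
}

#' Synthetic noisy gas-exchange observations
#'
#' Simulates the model under known ('generating') parameters, samples the
#' trajectory at a fixed interval and adds independent Gaussian observation
#' noise to `A` and `g_s` — emulating an infra-red gas-analyser log recorded
#' every 2 min. The noiseless truth and the generating parameters are
#' returned alongside the observations so that calibration can be scored.
#'
#' The RNG is used for the noise only: two seeds differ in the noise but share
#' the latent trajectory.
#'
#' @param env An [environment_series()].
#' @param params Generating [model_parameters()].
#' @param consts,fconsts Constants objects.
#' @param sigma_A Observation noise SD on `A` (umol m^-2 s^-1).
#' @param sigma_gs Observation noise SD on `g_s` (mol m^-2 s^-1).
#' @param sampling_interval Observation interval (s), default 120 s.
#' @param seed Integer seed for the noise.
#' @param ... Passed to [simulate_gas_exchange()].
#' @return A list with `obs` (an [observation_set()]), `truth` (the noiseless
#'   trajectory) and `params`.
#' @export
synthetic_observations <- function(env, params = model_parameters(),
                                   consts = leaf_constants(),
                                   fconsts = farquhar_constants(),
                                   sigma_A = 0.6, sigma_gs = 0.014,
                                   sampling_interval = 120, seed = 1, ...) {
  stopifnot(inherits(env, "environment_series"),
            sigma_A >= 0, sigma_gs >= 0, sampling_interval > 0)
  times <- seq(min(env$time), max(env$time), by = sampling_interval)
  truth <- simulate_gas_exchange(env, params, consts, fconsts,
                                 output_times = times, ...)
  set.seed(seed)
  A_obs <- truth$A + rnorm(nrow(truth), 0, sigma_A)
  gs_obs <- truth$g_s + rnorm(nrow(truth), 0, sigma_gs)
  list(obs = observation_set(truth$time, A_obs, gs_obs, env),
       truth = truth, params = params)
}
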