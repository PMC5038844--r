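# Bayesian calibration of the dynamic model against observed A and g_s series:
# independent truncated-Gaussian priors, a two-output Gaussian likelihood, an
# adaptive-covariance warm-up followed by fixed-covariance random-walk
# Metropolis, and the chain diagnostics used to accept a fit (acceptance rate,
# effective sample size, Monte-Carlo standard error).

#' Default prior specification
#'
#' Independent Gaussian priors for the eleven adjustable parameters, truncated
#' to each parameter's physical domain. Means and standard deviations are the
#' literature-derived values used to calibrate the model; parameters with no
#' usable literature constraint carry a vague prior (zero mean, large SD) on
#' their positive domain.
#'
#' @return A data frame of class `prior_spec` with columns `parameter`,
#'   `mean`, `sd`, `lower`, `upper`.
#' @export
default_priors <- function() {
  p <- data.frame(
    parameter = c("a_min", "a_max", "alpha_L", "k_i", "k_d",
                  "Vc_max", "J_max", "R_d", "alpha", "S_e", "S_a"),
    mean = c(3.56, 100, 0, 100, 100, 65.5, 102.4, 0, 0, 0, 0),
    sd   = c(0.2, 10, 10, 1e4, 1e4, 22.6, 21.9, 10, 1, 10, 10),
    lower = c(1e-6, 1e-6, 0, 1e-3, 1e-3, 1e-3, 1e-3, 0, 1e-6, 0, 0),
    upper = c(Inf, Inf, Inf, Inf, Inf, Inf, Inf, Inf, 1 - 1e-6, Inf, Inf),
    stringsAsFactors = FALSE)
  class(p) <- c("prior_spec", "data.frame")
  p
}

validate_priors <- function(priors) {
  stopifnot(is.data.frame(priors),
            all(c("parameter", "mean", "sd", "lower", "upper") %in% names(priors)))
  if (any(priors$sd <= 0)) stop("prior SDs must be > 0", call. = FALSE)
  if (any(priors$lower >= priors$upper))
    stop("prior truncation bounds must satisfy lower < upper", call. = FALSE)
  invisible(priors)
}

#' Log prior density
#'
#' Sum of independent truncated-Gaussian log densities (unnormalised: the
#' truncation mass is not renormalised, which cancels in Metropolis ratios).
#' Returns `-Inf` outside the support, including the joint constraint
#' `a_max > a_min` when both parameters are present.
#'
#' @param theta Named numeric vector of parameter values; names must match
#'   `priors$parameter`.
#' @param priors A prior specification from [default_priors()] (possibly
#'   subset).
#' @return The log prior density (scalar).
#' @export
log_prior <- function(theta, priors = default_priors()) {
  validate_priors(priors)
  v <- theta[priors$parameter]
  if (any(is.na(v))) stop("theta is missing parameters named in priors", call. = FALSE)
  if (any(v < priors$lower | v > priors$upper)) return(-Inf)
  if (all(c("a_min", "a_max") %in% names(theta)) &&
      theta[["a_max"]] <= theta[["a_min"]]) return(-Inf)
  sum(dnorm(v, priors$mean, priors$sd, log = TRUE))
}

#' Observed gas-exchange time series
#'
#' Pairs observed net assimilation and stomatal conductance with the light
#' regime under which they were recorded.
#'
#' @param time Observation times (s), strictly increasing.
#' @param A Observed net CO2 assimilation (umol m^-2 s^-1).
#' @param g_s Observed stomatal conductance to water vapour (mol m^-2 s^-1).
#' @param env The [environment_series()] the observations were recorded under;
#'   must span the observation times.
#' @return An object of class `observation_set`.
#' @export
observation_set <- function(time, A, g_s, env) {
  stopifnot(inherits(env, "environment_series"))
  if (length(time) == 0L || length(A) != length(time) || length(g_s) != length(time))
    stop("time, A and g_s must be non-empty and of equal length", call. = FALSE)
  if (any(diff(time) <= 0)) stop("observation times must be strictly increasing", call. = FALSE)
  if (min(time) < min(env$time) || max(time) > max(env$time))
    stop("environment series must span the observation times", call. = FALSE)
  structure(list(time = as.numeric(time), A = as.numeric(A),
                 g_s = as.numeric(g_s), env = env),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("Observation set: %d time points over [%g, %g] s\n",
              length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' Log likelihood of observed A and g_s series
#'
#' Runs the forward model at the observation times and scores the two outputs
#' under independent homoscedastic Gaussian observation models (the two
#' objective functions of the calibration). A failed simulation is treated as
#' a rejected proposal: the function warns and returns `-Inf`.
#'
#' @param theta Named numeric vector of the sampled parameters; entries
#'   override the corresponding fields of `params`.
#' @param obs An [observation_set()].
#' @param params Baseline [model_parameters()] supplying the non-sampled
#'   fields.
#' @param consts A [leaf_constants()] object.
#' @param fconsts A [farquhar_constants()] object.
#' @param sigma_A,sigma_gs Observation noise SDs for A (umol m^-2 s^-1) and
#'   g_s (mol m^-2 s^-1).
#' @param atol,rtol Solver tolerances; much tighter than the plain simulation
#'   defaults because sampler moves probe likelihood differences far below the
#'   observation noise, and integration error would otherwise roughen the
#'   likelihood surface.
#' @param ... Passed to [simulate_gas_exchange()].
#' @return The log likelihood (scalar), `-Inf` on simulation failure.
#' @export
log_likelihood <- function(theta, obs, params = model_parameters(),
                           consts = leaf_constants(),
                           fconsts = farquhar_constants(),
                           sigma_A = 0.6, sigma_gs = 0.014,
                           atol = 1e-6, rtol = 1e-8, ...) {
  stopifnot(inherits(obs, "observation_set"))
  if (sigma_A <= 0 || sigma_gs <= 0) return(-Inf)
  p <- merge_parameters(params, theta)
  if (inherits(p, "error")) return(-Inf)
  sim <- tryCatch(
    simulate_gas_exchange(obs$env, p, consts, fconsts,
                          output_times = obs$time, atol = atol, rtol = rtol,
                          ...),
    error = function(e) e)
  if (inherits(sim, "error")) {
    warning("simulation failed during likelihood evaluation: ",
            conditionMessage(sim), call. = FALSE)
    return(-Inf)
  }
  sum(dnorm(obs$A, sim$A, sigma_A, log = TRUE)) +
    sum(dnorm(obs$g_s, sim$g_s, sigma_gs, log = TRUE))
}

merge_parameters <- function(params, theta) {
  p <- unclass(params)
  model_par_names <- setdiff(names(theta), c("sigma_A", "sigma_gs"))
  p[model_par_names] <- as.list(theta[model_par_names])
  tryCatch(do.call(model_parameters, p), error = function(e) e)
}

# log of the half-Cauchy density (up to support), used for sampled noise SDs
log_half_cauchy <- function(x, scale) {
  if (x <= 0) return(-Inf)
  log(2) + dcauchy(x, 0, scale, log = TRUE)
}

#' Sample the posterior distribution
#'
#' Two-phase Markov chain Monte Carlo over the model parameters: an
#' adaptive-covariance warm-up in which the multivariate normal proposal is
#' repeatedly re-estimated from the pooled history of all chains (scaled by the
#' standard `2.38^2 / d` factor), followed by fixed-covariance random-walk
#' Metropolis using the adapted covariance. Adaptation is disabled in the
#' second phase so the retained samples come from a Markovian kernel; only
#' second-phase samples are retained and thinned.
#'
#' Observation noise is handled per the `noise` argument: `"sampled"` (default)
#' adds `sigma_A` and `sigma_gs` as nuisance parameters under half-Cauchy
#' priors; `"fixed"` keeps them at the supplied values.
#'
#' With `obs = NULL` the likelihood is identically zero and the sampler draws
#' from the truncated prior (used to validate the sampler itself).
#'
#' @param obs An [observation_set()], or `NULL` for prior-only sampling.
#' @param priors Prior specification; rows define which model parameters are
#'   sampled (subset `default_priors()` to fix the rest at `params`).
#' @param params Baseline [model_parameters()] supplying non-sampled fields.
#' @param consts,fconsts Constants objects.
#' @param iterations Iterations per chain (warm-up included).
#' @param chains Number of chains.
#' @param thin Thinning interval applied to the retained phase.
#' @param warmup_fraction Fraction of iterations used for the adaptive warm-up
#'   and discarded.
#' @param noise `"sampled"` or `"fixed"`.
#' @param sigma_A,sigma_gs Fixed noise SDs (initial values when sampled).
#' @param sigma_scales Half-Cauchy scales for the sampled noise SDs.
#' @param seed Integer seed; every stochastic element of the sampler derives
#'   from it.
#' @param init Starting values: `"map"` (default) runs a short Nelder-Mead
#'   posterior-mode search from the clipped prior means before sampling
#'   (prior means directly when there are no observations), `"prior_mean"`
#'   uses the clipped prior means as-is, or a named vector of values.
#' @param map_iterations Iteration budget of the mode search.
#' @param adapt_every Warm-up covariance re-estimation interval (iterations).
#' @param ... Passed to [log_likelihood()] / [simulate_gas_exchange()].
#'
#' @return An object of class `gx_chains`: a list with `chains` (one retained
#'   sample matrix per chain), `log_post`, `acceptance_rate` (second phase,
#'   per chain), `proposal_cov`, and the settings used.
#' @export
sample_posterior <- function(obs = NULL, priors = default_priors(),
                             params = model_parameters(),
                             consts = leaf_constants(),
                             fconsts = farquhar_constants(),
                             iterations = 30000, chains = 2, thin = 2,
                             warmup_fraction = 0.5,
                             noise = c("sampled", "fixed"),
                             sigma_A = 0.6, sigma_gs = 0.014,
                             sigma_scales = c(sigma_A = 1, sigma_gs = 0.05),
                             seed = NULL, init = "map", map_iterations = 3000,
                             adapt_every = 25, ...) {
  validate_priors(priors)
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  sample_noise <- noise == "sampled" && !is.null(obs)

  par_names <- priors$parameter
  d <- length(par_names) + if (sample_noise) 2L else 0L
  all_names <- c(par_names, if (sample_noise) c("sigma_A", "sigma_gs"))

  log_post <- function(theta) {
    lp <- log_prior(theta[par_names], priors)
    if (sample_noise) {
      lp <- lp + log_half_cauchy(theta[["sigma_A"]], sigma_scales[[1]]) +
        log_half_cauchy(theta[["sigma_gs"]], sigma_scales[[2]])
    }
    if (!is.finite(lp)) return(-Inf)
    if (is.null(obs)) return(lp)
    sA <- if (sample_noise) theta[["sigma_A"]] else sigma_A
    sg <- if (sample_noise) theta[["sigma_gs"]] else sigma_gs
    lp + log_likelihood(theta[par_names], obs, params, consts, fconsts,
                        sigma_A = sA, sigma_gs = sg, ...)
  }

  prior_mean_init <- function() {
    v <- pmin(pmax(priors$mean, priors$lower + 0.1 * priors$sd),
              ifelse(is.finite(priors$upper),
                     priors$upper - 0.01 * priors$sd, Inf))
    names(v) <- par_names
    if (all(c("a_min", "a_max") %in% par_names) && v[["a_max"]] <= v[["a_min"]])
      v[["a_max"]] <- v[["a_min"]] * 2
    v
  }
  if (is.character(init) && length(init) == 1L) {
    init0 <- prior_mean_init()
    if (sample_noise) init0 <- c(init0, sigma_A = sigma_A, sigma_gs = sigma_gs)
    names(init0) <- all_names
    if (identical(init, "map") && !is.null(obs)) {
      # short mode search so the short adaptive warm-up starts near the
      # posterior bulk; parameters scaled by their prior SDs
      pscale <- c(priors$sd, if (sample_noise) c(sigma_A / 2, sigma_gs / 2))
      opt <- stats::optim(init0, function(v) {
        names(v) <- all_names
        lp <- log_post(v)
        if (!is.finite(lp)) 1e10 else -lp
      }, method = "Nelder-Mead",
      control = list(maxit = map_iterations, parscale = pscale))
      init <- opt$par
      names(init) <- all_names
    } else init <- init0
  } else {
    init <- init[par_names]
    if (sample_noise) init <- c(init, sigma_A = sigma_A, sigma_gs = sigma_gs)
    names(init) <- all_names
  }

  scale0 <- c(priors$sd, if (sample_noise) c(sigma_A / 2, sigma_gs / 2))
  prop_chol <- chol(2.38^2 / d * diag(pmin(scale0, 1e3)^2 * 0.01, d))

  n_warm <- floor(warmup_fraction * iterations)
  cur <- matrix(rep(init, chains), nrow = chains, byrow = TRUE,
                dimnames = list(NULL, all_names))
  cur_lp <- apply(cur, 1, log_post)
  if (any(!is.finite(cur_lp)))
    stop("initial state has zero posterior density", call. = FALSE)

  history <- array(NA_real_, c(iterations, chains, d))
  accept_warm <- accept_main <- recent_acc <- integer(chains)
  adapting <- TRUE
  frozen_chol <- NULL
  log_lambda <- 0   # global scale on top of the 2.38^2/d covariance rule

  for (i in seq_len(iterations)) {
    if (i == n_warm + 1L) {          # freeze the kernel for the sampling phase
      adapting <- FALSE
      frozen_chol <- prop_chol
    }
    z <- matrix(rnorm(chains * d), chains, d) %*% prop_chol
    for (ch in seq_len(chains)) {
      prop <- cur[ch, ] + z[ch, ]
      lp <- log_post(prop)
      if (is.finite(lp) && log(runif(1)) < lp - cur_lp[ch]) {
        cur[ch, ] <- prop
        cur_lp[ch] <- lp
        if (i > n_warm) accept_main[ch] <- accept_main[ch] + 1L
        else {
          accept_warm[ch] <- accept_warm[ch] + 1L
          recent_acc[ch] <- recent_acc[ch] + 1L
        }
      }
      history[i, ch, ] <- cur[ch, ]
    }
    if (adapting && i >= max(100, 4 * d) && i %% adapt_every == 0L) {
      # covariance from the trailing half of the pooled history (drops the
      # initial transient), scale tuned towards the 0.234 acceptance target
      win <- seq(ceiling(i / 2), i)
      pooled <- do.call(rbind, lapply(seq_len(chains), function(ch)
        matrix(history[win, ch, ], ncol = d)))
      S <- stats::cov(pooled)
      acc_rate <- sum(recent_acc) / (chains * adapt_every)
      recent_acc[] <- 0L
      log_lambda <- min(4, max(-4, log_lambda + 0.5 * (acc_rate - 0.234)))
      if (any(!is.finite(S)) || any(diag(S) <= 0)) {
        S[!is.finite(S)] <- 0
        S <- S + diag(pmax(diag(S), 1e-8) * 1e-6, d)
        message("degenerate proposal covariance regularised with diagonal jitter")
      }
      S <- exp(log_lambda) * 2.38^2 / d * S + diag(1e-300, d)
      ch_try <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(ch_try)) {
        S <- S + diag(1e-8 * pmax(diag(S), 1e-12), d)
        message("degenerate proposal covariance regularised with diagonal jitter")
        ch_try <- tryCatch(chol(S), error = function(e) prop_chol)
      }
      prop_chol <- ch_try
    }
  }

  keep <- seq(n_warm + thin, iterations, by = thin)
  out_chains <- lapply(seq_len(chains), function(ch) {
    m <- matrix(history[keep, ch, ], ncol = d)
    colnames(m) <- all_names
    m
  })
  structure(list(
    chains = out_chains,
    acceptance_rate = accept_main / (iterations - n_warm),
    warmup_acceptance_rate = accept_warm / n_warm,
    proposal_cov = crossprod(if (is.null(frozen_chol)) prop_chol else frozen_chol),
    parameters = all_names, iterations = iterations, warmup = n_warm,
    thin = thin, seed = seed),
    class = "gx_chains")
}

#' @export
print.gx_chains <- function(x, ...) {
  cat(sprintf("MCMC chains: %d chain(s) x %d retained samples of %d parameter(s)\n",
              length(x$chains), nrow(x$chains[[1]]), ncol(x$chains[[1]])))
  cat(sprintf("  sampling-phase acceptance: %s\n",
              paste(sprintf("%.1f%%", 100 * x$acceptance_rate), collapse = ", ")))
  invisible(x)
}

#' Effective sample size of a chain
#'
#' Autocorrelation-based ESS, `n / (1 + 2 * sum(rho_k))` with the sum
#' truncated by Geyer's initial positive sequence (consecutive pairs of
#' autocorrelations are accumulated while their sum stays positive). Equals
#' `n` in the iid limit; a constant chain is degenerate and reports 1 with a
#' warning.
#'
#' @param x Numeric vector (one chain of one parameter) of length >= 10, or a
#'   matrix whose columns are parameters (a vector per column is returned).
#' @return Effective sample size(s), capped at `n`.
#' @export
effective_sample_size <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, effective_sample_size))
  n <- length(x)
  if (n < 10) stop("chain too short for an ESS estimate (need >= 10)", call. = FALSE)
  if (stats::var(x) == 0) {
    warning("constant chain: ESS is degenerate", call. = FALSE)
    return(1)
  }
  rho <- stats::acf(x, lag.max = min(n - 1, 10 * floor(sqrt(n))),
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
  # rho[1] is lag 0 (=1); accumulate pairs (rho_{2k-1} + rho_{2k}) while positive
  tau <- 1
  k <- 2
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair <= 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  min(n, n / tau)
}

#' Monte-Carlo standard error of a chain, as a percentage of the posterior SD
#'
#' Batch-means MCSE of the chain mean, divided by the sample SD and expressed
#' in percent. On iid chains this is approximately `100 / sqrt(n)`; the
#' conventional convergence threshold of 6.27% corresponds to roughly 254
#' independent samples.
#'
#' @param x Numeric vector of length >= 100, or a matrix whose columns are
#'   parameters.
#' @param threshold Convergence threshold in percent.
#' @return A list with `mcse` (units of `x`), `pct` (percent of posterior SD)
#'   and `converged` (`pct < threshold`). For matrices, one list per column.
#' @export
monte_carlo_standard_error <- function(x, threshold = 6.27) {
  if (is.matrix(x))
    return(apply(x, 2, monte_carlo_standard_error, threshold = threshold,
                 simplify = FALSE))
  n <- length(x)
  if (n < 100) stop("chain too short for a batch-means MCSE (need >= 100)", call. = FALSE)
  b <- floor(sqrt(n))
  nb <- floor(n / b)
  bm <- vapply(seq_len(nb), function(i) mean(x[((i - 1) * b + 1):(i * b)]),
               numeric(1))
  mcse <- stats::sd(bm) / sqrt(nb)
  s <- stats::sd(x)
  pct <- if (s > 0) 100 * mcse / s else Inf
  list(mcse = mcse, pct = pct, converged = is.finite(pct) && pct < threshold)
}

#' Summarise posterior chains
#'
#' Pools all retained samples and reports per-parameter quantiles at 2.5, 50
#' and 97.5% (the credible interval and median), the effective sample size and
#' the Monte-Carlo standard error, plus the sampling-phase acceptance rate.
#' When per-chain medians are far apart relative to the pooled spread (a sign
#' of multi-modality or non-convergence) a between-chain spread warning is
#' issued, but the pooled summary is still returned.
#'
#' @param chains A `gx_chains` object from [sample_posterior()], or a list of
#'   sample matrices with common column names.
#' @param mcse_threshold Convergence threshold for the MCSE criterion (%).
#' @return A data frame of class `posterior_summary` with one row per
#'   parameter: `q2.5`, `q50`, `q97.5`, `ess`, `mcse_pct`, `converged`.
#'   Acceptance rates (if known) are attached as attribute `acceptance_rate`.
#' @export
summarize_posterior <- function(chains, mcse_threshold = 6.27) {
  acc <- NULL
  if (inherits(chains, "gx_chains")) {
    acc <- chains$acceptance_rate
    chains <- chains$chains
  }
  stopifnot(is.list(chains), length(chains) >= 1)
  pooled <- do.call(rbind, chains)
  if (is.null(pooled) || nrow(pooled) == 0) stop("no samples to summarise", call. = FALSE)
  if (length(chains) > 1) {
    meds <- sapply(chains, function(m) apply(m, 2, stats::median))
    meds <- matrix(meds, ncol = length(chains))
    spread <- apply(meds, 1, function(v) diff(range(v)))
    within <- rowMeans(matrix(sapply(chains, function(m) apply(m, 2, stats::sd)),
                              ncol = length(chains)))
    bad <- spread > 3 * pmax(within, 1e-300)
    if (any(bad))
      warning("large between-chain spread for: ",
              paste(colnames(pooled)[bad], collapse = ", "),
              " (possible multi-modality or non-convergence)", call. = FALSE)
  }
  q <- t(apply(pooled, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
               names = FALSE))
  ess_per_chain <- suppressWarnings(
    sapply(chains, function(m) effective_sample_size(m)))
  ess <- rowSums(matrix(ess_per_chain, nrow = ncol(pooled)))
  mc <- suppressWarnings(monte_carlo_standard_error(pooled,
                                                    threshold = mcse_threshold))
  out <- data.frame(parameter = colnames(pooled),
                    q2.5 = q[, 1], q50 = q[, 2], q97.5 = q[, 3],
                    ess = as.numeric(ess),
                    mcse_pct = vapply(mc, `[[`, numeric(1), "pct"),
                    converged = vapply(mc, `[[`, logical(1), "converged"),
                    row.names = NULL)
  stopifnot(all(out$q2.5 <= out$q50 & out$q50 <= out$q97.5))
  attr(out, "acceptance_rate") <- acc
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Root mean square error
#'
#' `sqrt(mean((observed - modelled)^2))`, in the units of the series.
#'
#' @param observed,modelled Numeric vectors of equal nonzero length.
#' @return Non-negative scalar; 0 iff the series are identical.
#' @export
rmse <- function(observed, modelled) {
  if (length(observed) == 0L || length(observed) != length(modelled))
    stop("observed and modelled must have equal nonzero length", call. = FALSE)
  sqrt(mean((observed - modelled)^2))
}
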