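# Sampler and diagnostics, validated against analytic targets: the truncated
# prior itself (null case of the posterior), closed-form ESS of an AR(1)
# process, and the iid scaling law of the batch-means MCSE.

test_that("log prior is the sum of truncated Gaussians with exact unit drops", {
  pr <- default_priors()
  at_mean <- setNames(pr$mean, pr$parameter)
  at_mean["alpha"] <- 0.5; at_mean["a_min"] <- 3; at_mean["a_max"] <- 100
  lp0 <- log_prior(at_mean, pr)
  expect_true(is.finite(lp0))
  # +1 prior SD on one parameter lowers the log density by exactly 0.5
  shifted <- at_mean
  shifted["Vc_max"] <- shifted["Vc_max"] + pr$sd[pr$parameter == "Vc_max"]
  expect_equal(lp0 - log_prior(shifted, pr), 0.5)
  # outside the physical domain
  neg <- at_mean; neg["k_i"] <- -5
  expect_identical(log_prior(neg, pr), -Inf)
  swapped <- at_mean; swapped["a_max"] <- 2   # violates a_max > a_min
  expect_identical(log_prior(swapped, pr), -Inf)
})

test_that("log likelihood attains the Gaussian maximum at zero residuals", {
  env <- environment_series(c(0, 1800, 1800, 3600), c(100, 100, 600, 600),
                            interp = "constant")
  syn <- synthetic_observations(env, sigma_A = 0, sigma_gs = 0, seed = 1,
                                atol = 1e-6, rtol = 1e-8)
  th <- c(k_i = 1430)
  n <- length(syn$obs$time)
  ll <- log_likelihood(th, syn$obs, sigma_A = 0.6, sigma_gs = 0.014)
  expect_equal(ll, -n * (log(0.6) + log(0.014)) - n * log(2 * pi),
               tolerance = 1e-4)
  # doubling both sigmas at zero residuals costs exactly 2n log 2
  ll2 <- log_likelihood(th, syn$obs, sigma_A = 1.2, sigma_gs = 0.028)
  expect_equal(ll - ll2, 2 * n * log(2), tolerance = 1e-4)
})

test_that("the likelihood prefers the generating parameters over a +50% k_i distortion", {
  env <- environment_series(c(0, 1800, 1800, 3600), c(100, 100, 600, 600),
                            interp = "constant")
  truth <- c(k_i = 1430)
  wrong <- c(k_i = 1430 * 1.5)
  diffs <- vapply(1:20, function(s) {
    syn <- synthetic_observations(env, sigma_A = 0.6, sigma_gs = 0.014, seed = s,
                                  atol = 1e-6, rtol = 1e-8)
    log_likelihood(truth, syn$obs) - log_likelihood(wrong, syn$obs)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("rmse matches its definition", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2), c(2, 2)), sqrt(0.5))
  expect_equal(rmse(c(5, 9, -2), c(5, 9, -2) + 0.7), 0.7)
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("prior-only sampling reproduces the truncated priors", {
  pr <- default_priors()
  pr <- pr[pr$parameter %in% c("a_min", "alpha", "Vc_max"), ]
  ch <- suppressMessages(
    sample_posterior(NULL, priors = pr, iterations = 30000, chains = 2,
                     thin = 3, seed = 7))
  pooled <- do.call(rbind, ch$chains)
  expect_gte(nrow(pooled), 5000)
  # near-iid subsample for the distributional test
  sub <- pooled[seq(1, nrow(pooled), by = 10), ]
  for (nm in pr$parameter) {
    row <- pr[pr$parameter == nm, ]
    pv <- suppressWarnings(stats::ks.test(
      sub[, nm],
      function(q) ptrunc_norm(q, row$mean, row$sd,
                              row$lower, row$upper))$p.value)
    expect_gt(pv, 0.01)
  }
  # mean of the near-Gaussian marginal within 3 Monte-Carlo SEs of its truth
  ess <- effective_sample_size(pooled[, "a_min"])
  mc_se <- sd(pooled[, "a_min"]) / sqrt(ess)
  expect_lt(abs(mean(pooled[, "a_min"]) - 3.56), 3 * mc_se + 0.002)
})

test_that("ESS matches iid, degenerate and AR(1) closed forms", {
  set.seed(1)
  x <- rnorm(5000)
  expect_gt(effective_sample_size(x), 4500)
  expect_lte(effective_sample_size(x), 5000)
  expect_warning(e1 <- effective_sample_size(rep(2, 100)), "constant")
  expect_equal(e1, 1)
  rho <- 0.5; n <- 10000
  ar <- as.numeric(arima.sim(list(ar = rho), n, sd = 1, n.start = 500))
  expect_equal(effective_sample_size(ar), n * (1 - rho) / (1 + rho),
               tolerance = 0.15)
  expect_error(effective_sample_size(rnorm(5)), "short")
})

test_that("batch-means MCSE follows the iid 100/sqrt(n) law", {
  set.seed(2)
  m254 <- replicate(40, monte_carlo_standard_error(rnorm(254))$pct)
  expect_equal(mean(m254), 100 / sqrt(254), tolerance = 0.12)
  m1000 <- replicate(40, monte_carlo_standard_error(rnorm(1016))$pct)
  expect_equal(mean(m254) / mean(m1000), 2, tolerance = 0.15)
  expect_error(monte_carlo_standard_error(rnorm(50)), "short")
})

test_that("posterior summaries keep quantile order and flag disjoint chains", {
  m <- matrix(5, nrow = 200, ncol = 1, dimnames = list(NULL, "x"))
  s <- suppressWarnings(summarize_posterior(list(m)))
  expect_equal(unlist(s[1, c("q2.5", "q50", "q97.5")], use.names = FALSE),
               c(5, 5, 5))
  set.seed(3)
  u <- matrix(runif(10000), ncol = 1, dimnames = list(NULL, "u"))
  su <- summarize_posterior(list(u))
  expect_equal(su$q2.5, 0.025, tolerance = 0.4)
  expect_equal(su$q50, 0.5, tolerance = 0.02)
  expect_lt(abs(su$q97.5 - 0.975), 0.01)
  m1 <- matrix(rnorm(500, 0, 0.1), ncol = 1, dimnames = list(NULL, "x"))
  m2 <- matrix(rnorm(500, 10, 0.1), ncol = 1, dimnames = list(NULL, "x"))
  expect_warning(summarize_posterior(list(m1, m2)), "between-chain")
})
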