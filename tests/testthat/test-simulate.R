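# Trajectory-level behaviour of the coupled system: closed-form checks with
# the feedback disabled, equivalence with the independent algebraic
# steady-state solver, and the structural invariants of every record.

test_that("with feedback off, the aperture follows the single-exponential solution", {
  p <- fix_params(S_e = 0, S_a = 0)
  env <- environment_series(c(0, 6000), c(500, 500))
  a_inf <- steady_state_aperture(500, 1, p)
  for (a0 in c(10, 80)) {        # opening (k_i) and closing (k_d) branches
    k <- if (a0 < a_inf) p$k_i else p$k_d
    sim <- simulate_gas_exchange(env, p,
                                 init = c(a = a0, C_i = 380, C_c = 350, L = 1),
                                 output_times = seq(0, 6000, 250),
                                 atol = 1e-10, rtol = 1e-10)
    closed <- a_inf + (a0 - a_inf) * exp(-sim$time / k)
    expect_lt(max(abs(sim$a - closed) / closed), 1e-6)
    expect_equal(sim$L, rep(1, nrow(sim)))
  }
})

test_that("long-horizon simulation converges to the algebraic steady state", {
  for (ppfd in c(0, 50, 100, 500, 1000)) {
    ss <- steady_state(ppfd)
    env <- environment_series(c(0, 6e5), c(ppfd, ppfd))
    sim <- simulate_gas_exchange(env, output_times = c(0, 6e5), atol = 1e-8)
    last <- sim[nrow(sim), ]
    expect_equal(last$a, unname(ss$state["a"]), tolerance = 1e-5)
    expect_equal(last$C_i, unname(ss$state["C_i"]), tolerance = 1e-5)
    expect_equal(last$C_c, unname(ss$state["C_c"]), tolerance = 1e-5)
    expect_equal(last$L, unname(ss$state["L"]), tolerance = 1e-5)
  }
})

test_that("steady states satisfy the balance residuals and flux conservation", {
  for (ppfd in c(0, 50, 100, 500, 1000)) {
    ss <- steady_state(ppfd)
    expect_true(all(abs(ss$residuals) < 1e-9))
    rec <- ss$record
    # the three CO2 fluxes agree: boundary+stomata, mesophyll, net biochemistry
    p <- fix_params()
    f_in <- rec$g_t * (400 - rec$C_i)
    f_mes <- p$g_m * (rec$C_i - rec$C_c)
    f_bio <- rec$A_G * rec$L - p$R_d
    scale <- max(abs(c(f_in, f_mes, f_bio, 1e-6)))
    expect_lt(max(abs(c(f_in - f_mes, f_in - f_bio))) / scale, 1e-3)
  }
})

test_that("the dark steady state shows respiration structure", {
  ss <- steady_state(0)
  p <- fix_params()
  expect_equal(unname(ss$state["L"]), 1)                 # no assimilation, L* = 1
  expect_equal(unname(ss$state["a"]), p$a_min)
  expect_equal(ss$record$A_G, 0)
  expect_gt(ss$record$C_c, ss$record$C_i)                # respiration raises C_c
  expect_gt(ss$record$C_i, 400)
})

test_that("every record satisfies the definitional invariants", {
  env <- gaussian_fluctuating_light(day_length = 14400, sd_time = 2400,
                                    peak_time = 7200, seed = 3)
  sim <- simulate_gas_exchange(env)
  p <- fix_params(); cc <- fix_consts()
  expect_true(all(sim$L >= 0 & sim$L <= 1))
  expect_true(all(sim$a >= 0 & sim$a <= p$a_max + 1e-9))
  expect_true(all(is.finite(sim$W_i[sim$g_s > 0])))
  expect_equal(sim$W_i, sim$A / sim$g_s)                 # record-wise identity
  expect_true(all(sim$g_t < sim$g_s / 1.6))
  expect_true(all(sim$g_t < cc$g_b / 1.37))
})

test_that("the conductance trajectory scales with stomatal density", {
  env <- fix_step_env()
  times <- seq(-1800, 7200, 60)
  p0 <- fix_params(S_e = 0, S_a = 0)   # freeze the weak feedback so the
  init <- c(a = 20, C_i = 380, C_c = 350, L = 1)  # scaling is exact
  s1 <- simulate_gas_exchange(env, p0, fix_consts(SD = 400), init = init,
                              output_times = times, atol = 1e-8)
  s2 <- simulate_gas_exchange(env, p0, fix_consts(SD = 800), init = init,
                              output_times = times, atol = 1e-8)
  expect_equal(s2$a, s1$a, tolerance = 1e-6)   # aperture dynamics unchanged
  expect_equal(s2$g_s, 2 * s1$g_s, tolerance = 1e-6)
})

test_that("conductance rises monotonically towards target after a light step", {
  st <- steady_state(100)
  env <- fix_step_env()
  sim <- simulate_gas_exchange(env, init = st$state,
                               output_times = seq(0, 7200, 60), atol = 1e-8)
  rising <- sim$a < sim$a_s - 0.5
  expect_gt(sum(rising), 10)
  expect_true(all(diff(sim$g_s)[rising[-length(rising)]] > 0))
})

test_that("the compiled and reference R right-hand sides agree", {
  env <- fix_step_env()
  times <- seq(-1800, 7200, 300)
  sc <- simulate_gas_exchange(env, output_times = times, atol = 1e-9, rtol = 1e-9,
                              engine = "compiled")
  sr <- simulate_gas_exchange(env, output_times = times, atol = 1e-9, rtol = 1e-9,
                              engine = "R")
  expect_equal(sc$a, sr$a, tolerance = 1e-6)
  expect_equal(sc$C_i, sr$C_i, tolerance = 1e-6)
  expect_equal(sc$A, sr$A, tolerance = 1e-6)
})

test_that("simulation rejects invalid requests", {
  env <- environment_series(c(0, 100), c(10, 10))
  expect_error(simulate_gas_exchange(env, output_times = c(0, 200)), "span")
  expect_error(simulate_gas_exchange(env, init = c(a = -1, C_i = 1, C_c = 1, L = 1)),
               "initial state")
})
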