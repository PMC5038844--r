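# Single-step kernels, checked against hand / arbitrary-precision evaluations
# of the closed forms (frozen below) and against their structural limits.

test_that("steady-state aperture follows the non-rectangular hyperbola", {
  p <- fix_params()
  # dark limit: the hyperbola term vanishes, leaving a_min * L
  expect_equal(steady_state_aperture(0, 1), p$a_min)
  expect_equal(steady_state_aperture(0, 0.5), p$a_min * 0.5)
  # saturation limit: a_max * L
  expect_equal(steady_state_aperture(1e9, 0.5), p$a_max * 0.5, tolerance = 1e-4)
  # frozen closed-form value at PPFD = 100 (independent hand evaluation)
  expect_equal(steady_state_aperture(100, 1), 57.2954974, tolerance = 1e-8)
  # monotone non-decreasing in PPFD, bounded by a_max * L
  ppfd <- seq(0, 2000, by = 10)
  as <- steady_state_aperture(ppfd, 0.8)
  expect_true(all(diff(as) >= 0))
  expect_true(all(as >= 0 & as <= p$a_max * 0.8 + 1e-12))
  expect_error(steady_state_aperture(-1, 1), "PPFD")
  expect_error(steady_state_aperture(10, 1.5), "L")
})

test_that("aperture relaxation uses the opening/closing branch time constants", {
  p <- fix_params(k_i = 1430, k_d = 541)
  expect_equal(aperture_rate(5, 5, p), 0)
  expect_equal(aperture_rate(4, 14, p), 10 / 1430)
  expect_equal(aperture_rate(14, 4, p), -10 / 541)
  expect_identical(sign(aperture_rate(c(1, 9), c(5, 5), p)), c(1, -1))
  p_bad <- unclass(p); p_bad$k_d <- 0
  expect_error(aperture_rate(1, 2, p_bad), "time constants")
})

test_that("pore-to-leaf conductance scaling reproduces the frozen oracle and is linear in density", {
  # frozen unit-tracked hand evaluation at a = 4.16 um^2, default anatomy
  expect_equal(stomatal_conductance(4.16), 0.213828106, tolerance = 1e-8)
  expect_equal(stomatal_conductance(0), 0)
  a <- c(0.5, 2, 10, 50)
  g1 <- stomatal_conductance(a, fix_consts(SD = 400))
  g2 <- stomatal_conductance(a, fix_consts(SD = 800))
  expect_equal(g2, 2 * g1)                      # exactly proportional to SD
  expect_true(all(diff(stomatal_conductance(seq(0.01, 100, 0.5))) > 0))
  expect_error(stomatal_conductance(-1), "pore area")
})

test_that("total CO2 conductance combines stomata and boundary layer in series", {
  expect_equal(total_co2_conductance(0.3, 9.29), 0.1824549918, tolerance = 1e-8)
  expect_equal(total_co2_conductance(0, 9.29), 0)
  expect_equal(total_co2_conductance(1e9, 9.29), 9.29 / 1.37, tolerance = 1e-6)
  expect_equal(total_co2_conductance(2, 2), 2 / 2.97)
  expect_error(total_co2_conductance(0.3, 0), "g_b")
})

test_that("conductance inversion is the exact inverse of the forward map", {
  expect_equal(invert_conductance(0), 0)
  expect_equal(invert_conductance(stomatal_conductance(10)), 10, tolerance = 1e-6)
  expect_equal(invert_conductance(0.213828106), 4.16, tolerance = 1e-5)
  g <- stomatal_conductance(c(0.3, 3, 30, 90))
  for (gi in g)
    expect_lt(abs(stomatal_conductance(invert_conductance(gi)) - gi), 1e-10)
  expect_error(invert_conductance(1, a_upper = 0.5), "exceeds")
})

test_that("electron transport saturates at J_max and has the rectangular limit", {
  p <- fix_params()
  expect_equal(electron_transport(0), 0)
  expect_equal(electron_transport(1e12), p$J_max, tolerance = 1e-4)
  # theta_J -> 0 limit equals the rectangular hyperbola
  fc0 <- fix_fconsts(theta_J = 1e-13)
  I <- c(50, 200, 1000)
  expect_equal(electron_transport(I, p, fc0),
               p$alpha * I * p$J_max / (p$alpha * I + p$J_max),
               tolerance = 1e-6)
  expect_true(all(diff(electron_transport(seq(0, 3000, 10))) >= 0))
})

test_that("gross assimilation is the floored minimum of the two limitations", {
  p <- fix_params(); fc <- fix_fconsts(); cc <- fix_consts()
  expect_equal(gross_assimilation(fc$Gamma_star, 1000), 0)
  expect_equal(gross_assimilation(300, 0), 0)         # dark: J = 0 wins the min
  expect_equal(gross_assimilation(10, 1000), 0)       # below compensation, floored
  # grid scan: monotone in C_c and never above either limitation alone
  Cc <- seq(0, 1500, by = 5)
  AG <- gross_assimilation(Cc, 1500)
  expect_true(all(diff(AG) >= -1e-12))
  J <- electron_transport(1500, p, fc)
  Wc <- p$Vc_max * (Cc - fc$Gamma_star) / (Cc + fc$Kc * (1 + cc$O2 / fc$Ko))
  Wj <- (J / 4) * (Cc - fc$Gamma_star) / (Cc + 2 * fc$Gamma_star)
  expect_true(all(AG <= pmax(Wc, 0) + 1e-12))
  expect_true(all(AG <= pmax(Wj, 0) + 1e-12))
  expect_true(all(AG == pmax(pmin(Wc, Wj), 0)))
})

test_that("compartment CO2 balances carry the frozen unit-conversion factors", {
  cc <- fix_consts(); p <- fix_params()
  # flux balance and full equilibrium give zero rate
  expect_equal(intercellular_co2_rate(350, 330, 0.2, 0.2 * (400 - 350) / (350 - 330),
                                      C_a = 400, consts = cc), 0, tolerance = 1e-10)
  expect_equal(intercellular_co2_rate(400, 400, 0.5, 0.2, C_a = 400, consts = cc), 0)
  # conversion factors (hand unit calculations, mol^-1 m^2):
  # R*T/(d_a*P_a) ~ 477.45 and R*T/(d_p*P_a) ~ 163.42 at 25 C, 101.8 kPa
  unit_flux <- intercellular_co2_rate(399, 400, 1, 0, C_a = 400, consts = cc)
  expect_equal(unit_flux, 477.4488809, tolerance = 1e-4)
  p0 <- fix_params(R_d = 1)
  dark <- carboxylation_co2_rate(300, 300, 0.2, 0, 1, params = p0, consts = cc)
  expect_equal(dark, 163.4221002, tolerance = 1e-4)   # respiration raises C_c
  expect_gt(dark, 0)
  # sink/source balance
  expect_equal(carboxylation_co2_rate(320, 300, 0.2, (0.2 * 20 + p$R_d) / 0.9, 0.9,
                                      params = p, consts = cc), 0, tolerance = 1e-9)
})

test_that("efficiency drift has the analytic fixed point and barrier property", {
  p <- fix_params(S_e = 8.486e-6, S_a = 0.280e-6)
  expect_equal(efficiency_rate(1, 0, p), 0)
  Lstar <- p$S_e / (p$S_e + p$S_a * 10)
  expect_equal(Lstar, 0.7519050151, tolerance = 1e-8)
  expect_equal(efficiency_rate(Lstar, 10, p), 0, tolerance = 1e-20)
  expect_gte(efficiency_rate(0, 50, p), 0)   # pushes up at the lower barrier
  expect_lte(efficiency_rate(1, 50, p), 0)   # pushes down at the upper barrier
})
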