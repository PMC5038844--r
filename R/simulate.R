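#' Light regime and cuvette environment
#'
#' Pairs a PPFD time series with the constant cuvette conditions under which it
#' was (or is to be) applied. Between the tabulated points the light is
#' interpolated either linearly or as a left-continuous step function
#' (`interp = "constant"`, appropriate for programmed step changes); beyond the
#' tabulated range the nearest value is held.
#'
#' @param time Time (s), strictly increasing.
#' @param PPFD Photosynthetic photon flux density (umol m^-2 s^-1), >= 0, one
#'   value per time point.
#' @param Ca Atmospheric CO2 mole fraction (umol mol^-1), constant.
#' @param T_leaf Leaf temperature (C), constant.
#' @param interp Interpolation rule between tabulated light values.
#'
#' @return An object of class `environment_series`.
#' @examples
#' env <- environment_series(c(0, 1800, 1800, 9000), c(100, 100, 1000, 1000))
#' @export
environment_series <- function(time, PPFD, Ca = 400, T_leaf = 25,
                               interp = c("linear", "constant")) {
  interp <- match.arg(interp)
  if (length(time) != length(PPFD) || length(time) < 2L)
    stop("time and PPFD must have equal length >= 2", call. = FALSE)
  if (any(!is.finite(time)) || any(diff(time) < 0))
    stop("time must be finite and non-decreasing", call. = FALSE)
  if (any(!is.finite(PPFD)) || any(PPFD < 0))
    stop("PPFD must be finite and >= 0", call. = FALSE)
  if (length(Ca) != 1L || Ca <= 0) stop("Ca must be a single positive value", call. = FALSE)
  structure(list(time = as.numeric(time), PPFD = as.numeric(PPFD),
                 Ca = Ca, T_leaf = T_leaf, interp = interp),
            class = "environment_series")
}

#' @export
print.environment_series <- function(x, ...) {
  cat(sprintf("Light regime: %d points over [%g, %g] s, PPFD %g-%g umol m^-2 s^-1\n",
              length(x$time), min(x$time), max(x$time), min(x$PPFD), max(x$PPFD)))
  cat(sprintf("  Ca %g umol mol^-1, T_leaf %g C, %s interpolation\n",
              x$Ca, x$T_leaf, x$interp))
  invisible(x)
}

ppfd_fun <- function(env) {
  approxfun(env$time, env$PPFD, method = env$interp, rule = 2, ties = "ordered")
}

# Parameter vector handed to the compiled right-hand side; order must match
# src/stomdyn_ode.c.
stomdyn_parm_vector <- function(params, consts, fconsts, Ca, T_leaf) {
  kin <- farquhar_at_temperature(fconsts, T_leaf, consts$R_gas)
  Pa_pa <- consts$P_a * 1e3
  TK <- T_leaf + 273.15
  c(params$a_min, params$a_max, params$alpha_L, params$k_i, params$k_d,
    params$Vc_max, params$J_max, params$R_d, params$alpha, params$S_e,
    params$S_a, params$g_m,
    consts$theta_L, fconsts$theta_J,
    consts$SD * 1e6, consts$l * 1e-6, consts$D, consts$V, consts$g_b,
    Ca, consts$O2,
    kin$Kc, kin$Ko, kin$Gamma_star,
    consts$R_gas * TK / (consts$d_a * Pa_pa),
    consts$R_gas * TK / (consts$d_p * Pa_pa))
}

# Pure-R right-hand side, mirrored on the compiled one. Kept as the reference
# implementation (cross-checked in the tests) and as a fallback engine.
stomdyn_derivs_r <- function(t, y, parms, light) {
  a <- y[[1]]; Ci <- y[[2]]; Cc <- y[[3]]; L <- y[[4]]
  if (any(!is.finite(y)))
    stop(sprintf("non-finite state at t = %g: a=%g Ci=%g Cc=%g L=%g",
                 t, y[[1]], y[[2]], y[[3]], y[[4]]), call. = FALSE)
  Lc <- min(max(L, 0), 1)
  ac <- max(a, 0)
  Ccc <- max(Cc, 0)
  I <- max(light(t), 0)
  p <- parms
  nrh <- function(x, asym, theta) {
    if (theta < 1e-12) return(x * asym / (x + asym))
    s <- x + asym
    (s - sqrt(max(s^2 - 4 * theta * x * asym, 0))) / (2 * theta)
  }
  as <- (p[1] + nrh(p[3] * I, p[2] - p[1], p[13])) * Lc
  da <- if (a < as) (as - a) / p[4] else (as - a) / p[5]
  a_si <- ac * 1e-12
  gs <- p[15] * p[17] * a_si / (p[18] * (p[16] + (pi / 2) * sqrt(a_si / pi)))
  gt <- if (gs > 0) 1 / (1.6 / gs + 1.37 / p[19]) else 0
  J <- nrh(p[9] * I, p[7], p[14])
  Wc <- p[6] * (Ccc - p[24]) / (Ccc + p[22] * (1 + p[21] / p[23]))
  Wj <- (J / 4) * (Ccc - p[24]) / (Ccc + 2 * p[24])
  AG <- max(min(Wc, Wj), 0)
  list(c(da,
         (gt * (p[20] - Ci) - p[12] * (Ci - Cc)) * p[25],
         (p[12] * (Ci - Cc) + p[8] - AG * Lc) * p[26],
         p[10] * (1 - Lc) - p[11] * AG * Lc))
}

#' Simulate leaf gas exchange over a light regime
#'
#' Integrates the coupled four-state system (pore area, intercellular CO2,
#' carboxylation-site CO2, efficiency state) over an arbitrary light regime and
#' reports the full gas-exchange record at the requested output times. The
#' system is solved with a stiff-capable adaptive integrator; the opening /
#' closing branch switch of the aperture equation is a discontinuity of the
#' vector field only (the state stays continuous) and is handled by the
#' adaptive step control without event detection.
#'
#' On solver failure the absolute tolerance is divided by 10 and the
#' integration retried, up to `max_retries` times.
#'
#' @param env An [environment_series()].
#' @param params A [model_parameters()] object.
#' @param consts A [leaf_constants()] object.
#' @param fconsts A [farquhar_constants()] object.
#' @param init Initial state: named list or vector with `a` (um^2), `C_i`,
#'   `C_c` (umol mol^-1) and `L`. Defaults to the full steady state at the
#'   first light level of `env`.
#' @param output_times Times (s) at which to report the record; default the
#'   tabulated times of `env`.
#' @param net_assimilation How the reported net assimilation is formed:
#'   `"gross_times_L"` (default) uses `A = A_G * L - R_d`, consistent with the
#'   biochemical sink term of the CO2 balance; `"gross"` uses `A = A_G - R_d`.
#' @param atol Initial absolute solver tolerance (native units).
#' @param rtol Relative solver tolerance.
#' @param max_retries Maximum number of tolerance-tightening retries.
#' @param method deSolve integration method.
#' @param engine `"compiled"` (C right-hand side) or `"R"` (reference
#'   implementation); both evaluate the same model.
#'
#' @return A data frame of class `gas_exchange` with one row per output time
#'   and columns `time`, `ppfd`, `a`, `a_s`, `g_s`, `g_t`, `C_i`, `C_c`, `L`,
#'   `A_G`, `A`, `W_i`. `W_i = A / g_s` is `NaN` where `g_s = 0`.
#' @examples
#' env <- environment_series(c(0, 1800, 1800.1, 9000), c(100, 100, 1000, 1000))
#' sim <- simulate_gas_exchange(env, output_times = seq(0, 9000, 60))
#' @export
simulate_gas_exchange <- function(env, params = model_parameters(),
                                  consts = leaf_constants(),
                                  fconsts = farquhar_constants(),
                                  init = NULL, output_times = NULL,
                                  net_assimilation = c("gross_times_L", "gross"),
                                  atol = 0.01, rtol = 1e-8, max_retries = 5,
                                  method = c("lsoda", "lsodes"),
                                  engine = c("compiled", "R")) {
  stopifnot(inherits(env, "environment_series"))
  validate_model_parameters(params)
  net_assimilation <- match.arg(net_assimilation)
  method <- match.arg(method)
  engine <- match.arg(engine)
  if (is.null(output_times)) output_times <- env$time
  output_times <- sort(unique(as.numeric(output_times)))
  if (min(output_times) < min(env$time) || max(output_times) > max(env$time))
    stop("output_times must lie within the span of the light regime", call. = FALSE)

  light <- ppfd_fun(env)
  if (is.null(init)) {
    ss <- steady_state(light(min(output_times)), params, consts, fconsts,
                       Ca = env$Ca, T_leaf = env$T_leaf)
    init <- ss$state
  }
  y0 <- c(a = as.numeric(init[["a"]]), C_i = as.numeric(init[["C_i"]]),
          C_c = as.numeric(init[["C_c"]]), L = as.numeric(init[["L"]]))
  if (any(!is.finite(y0)) || y0[["a"]] < 0 || y0[["C_i"]] < 0 ||
      y0[["C_c"]] < 0 || y0[["L"]] < 0 || y0[["L"]] > 1)
    stop("invalid initial state", call. = FALSE)

  pv <- stomdyn_parm_vector(params, consts, fconsts, env$Ca, env$T_leaf)
  times <- output_times
  if (times[1] > min(env$time)) times <- c(min(env$time), times)

  run <- function(tol) {
    if (engine == "compiled") {
      fmethod <- if (env$interp == "constant") "constant" else "linear"
      deSolve::ode(y = y0, times = times, parms = pv, method = method,
                   dllname = "stomdyn", func = "stomdyn_derivs",
                   initfunc = "stomdyn_initparms",
                   initforc = "stomdyn_initforcs",
                   forcings = cbind(env$time, env$PPFD),
                   fcontrol = list(method = fmethod, rule = 2,
                                   ties = "ordered", f = 0),
                   atol = tol, rtol = rtol)
    } else {
      deSolve::ode(y = y0, times = times, parms = pv, method = method,
                   func = stomdyn_derivs_r, light = light,
                   atol = tol, rtol = rtol)
    }
  }

  tol <- atol
  for (attempt in seq_len(max_retries + 1L)) {
    out <- tryCatch(suppressWarnings(run(tol)), error = function(e) e)
    istate <- if (inherits(out, "error")) -1 else attributes(out)$istate[1]
    ok <- !inherits(out, "error") &&
      nrow(out) == length(times) &&
      all(is.finite(as.matrix(out[, 1:5]))) &&
      (is.null(istate) || istate >= 0)
    if (inherits(out, "error") && grepl("non-finite state", conditionMessage(out)))
      stop(out)
    if (ok) break
    if (attempt > max_retries)
      stop("solver failed to converge after ", max_retries,
           " tolerance retries (last atol = ", tol, ")", call. = FALSE)
    tol <- tol / 10
    message("solver retry ", attempt, ": tightening atol to ", tol)
  }

  out <- as.data.frame(out)
  names(out) <- c("time", "a", "C_i", "C_c", "L")
  out <- out[out$time %in% output_times, , drop = FALSE]
  gas_exchange_record(out, light, params, consts, fconsts, env, net_assimilation)
}

# Augments integrated states with the derived gas-exchange quantities
# (vectorised over rows; inputs were validated when the run started).
gas_exchange_record <- function(states, light, params, consts, fconsts, env,
                                net_assimilation = "gross_times_L") {
  ppfd <- light(states$time)
  Lc <- pmin(pmax(states$L, 0), 1)
  a_s <- (params$a_min +
            nonrect_hyperbola(params$alpha_L * ppfd,
                              params$a_max - params$a_min, consts$theta_L)) * Lc
  g_s <- stomatal_conductance(pmax(states$a, 0), consts)
  g_t <- total_co2_conductance(g_s, consts$g_b)
  kin <- farquhar_at_temperature(fconsts, env$T_leaf, consts$R_gas)
  J <- nonrect_hyperbola(params$alpha * ppfd, params$J_max, fconsts$theta_J)
  Cc <- pmax(states$C_c, 0)
  Wc <- params$Vc_max * (Cc - kin$Gamma_star) /
    (Cc + kin$Kc * (1 + consts$O2 / kin$Ko))
  Wj <- (J / 4) * (Cc - kin$Gamma_star) / (Cc + 2 * kin$Gamma_star)
  A_G <- pmax(pmin(Wc, Wj), 0)
  A <- if (net_assimilation == "gross_times_L")
    A_G * states$L - params$R_d else A_G - params$R_d
  W_i <- ifelse(g_s > 0, A / g_s, NaN)
  res <- data.frame(time = states$time, ppfd = ppfd, a = states$a, a_s = a_s,
                    g_s = g_s, g_t = g_t, C_i = states$C_i, C_c = states$C_c,
                    L = states$L, A_G = A_G, A = A, W_i = W_i)
  class(res) <- c("gas_exchange", "data.frame")
  res
}

#' Algebraic steady state of the full model
#'
#' Solves the four coupled balance equations (aperture relaxation, the two CO2
#' balances, and the efficiency drift) set to zero simultaneously for a
#' constant light level, by nested bracketed root finding: for a trial
#' efficiency `L` the aperture and conductances are explicit, the CO2 balances
#' reduce to a single equation in `C_c`, and the efficiency drift closes the
#' outer equation in `L`. This is an algebraic route entirely independent of
#' the ODE integrator and serves as its oracle in the tests.
#'
#' @param PPFD Constant light level (umol m^-2 s^-1), >= 0.
#' @param params A [model_parameters()] object.
#' @param consts A [leaf_constants()] object.
#' @param fconsts A [farquhar_constants()] object.
#' @param Ca Atmospheric CO2 mole fraction (umol mol^-1).
#' @param T_leaf Leaf temperature (C).
#' @param tol Residual tolerance on each balance (native units).
#'
#' @return A list with `state` (named vector `a`, `C_i`, `C_c`, `L`), `record`
#'   (one-row [simulate_gas_exchange()]-style data frame) and `residuals` (the
#'   four right-hand sides at the solution).
#' @examples
#' steady_state(0)$record$C_c > steady_state(0)$record$C_i  # respiration in the dark
#' @export
steady_state <- function(PPFD, params = model_parameters(),
                         consts = leaf_constants(),
                         fconsts = farquhar_constants(),
                         Ca = 400, T_leaf = 25, tol = 1e-12) {
  if (length(PPFD) != 1L || !is.finite(PPFD) || PPFD < 0)
    stop("PPFD must be a single finite value >= 0", call. = FALSE)
  validate_model_parameters(params)

  kin <- farquhar_at_temperature(fconsts, T_leaf, consts$R_gas)
  J <- nonrect_hyperbola(params$alpha * PPFD, params$J_max, fconsts$theta_J)
  AG_of_cc <- function(Cc) {
    Wc <- params$Vc_max * (Cc - kin$Gamma_star) /
      (Cc + kin$Kc * (1 + consts$O2 / kin$Ko))
    Wj <- (J / 4) * (Cc - kin$Gamma_star) / (Cc + 2 * kin$Gamma_star)
    max(min(Wc, Wj), 0)
  }
  a_of_L <- function(L)
    (params$a_min + nonrect_hyperbola(params$alpha_L * PPFD,
                                      params$a_max - params$a_min,
                                      consts$theta_L)) * L
  cc_given_L <- function(L) {
    a <- a_of_L(L)
    g_s <- stomatal_conductance(a, consts)
    g_t <- total_co2_conductance(g_s, consts$g_b)
    ci_of_cc <- function(Cc) (g_t * Ca + params$g_m * Cc) / (g_t + params$g_m)
    bal <- function(Cc) {
      Ci <- ci_of_cc(Cc)
      params$g_m * (Ci - Cc) + params$R_d - AG_of_cc(Cc) * L
    }
    upper <- Ca + params$R_d * (1 / params$g_m + 1.6 / max(g_s, 1e-12) +
                                  1.37 / consts$g_b) + 100
    Cc <- uniroot(bal, c(0, upper), tol = 1e-13)$root
    list(a = a, g_s = g_s, g_t = g_t, C_i = ci_of_cc(Cc), C_c = Cc,
         A_G = AG_of_cc(Cc))
  }

  if (params$S_e == 0 && params$S_a == 0) {
    L <- 1   # dL/dt identically zero; take the no-feedback convention
  } else if (params$S_e == 0) {
    L <- if (cc_given_L(1e-9)$A_G > 0) 0 else 1
  } else {
    gL <- function(L) {
      s <- cc_given_L(L)
      params$S_e * (1 - L) - params$S_a * s$A_G * L
    }
    # gL(0+) = S_e > 0 analytically, so a small positive lower bracket
    # suffices; below it the stomata are effectively closed anyway.
    L_lo <- 1e-6
    L <- if (gL(1) >= 0) 1
    else if (gL(L_lo) <= 0) L_lo
    else uniroot(gL, c(L_lo, 1), tol = 1e-14)$root
  }
  s <- cc_given_L(L)

  state <- c(a = s$a, C_i = s$C_i, C_c = s$C_c, L = L)
  resid <- c(aperture = aperture_rate(s$a, steady_state_aperture(PPFD, L, params, consts), params),
             C_i = intercellular_co2_rate(s$C_i, s$C_c, s$g_t, params$g_m, Ca, T_leaf, consts),
             C_c = carboxylation_co2_rate(s$C_i, s$C_c, params$g_m, s$A_G, L,
                                          T_leaf, params, consts),
             L = efficiency_rate(L, s$A_G, params))
  if (any(abs(resid) > 1e-9))
    warning("steady-state residuals above 1e-9: ",
            paste(sprintf("%s=%.3g", names(resid), resid), collapse = ", "))

  env1 <- environment_series(c(0, 1), c(PPFD, PPFD), Ca = Ca, T_leaf = T_leaf)
  rec <- gas_exchange_record(
    data.frame(time = 0, a = s$a, C_i = s$C_i, C_c = s$C_c, L = L),
    function(t) PPFD, params, consts, fconsts, env1)
  list(state = state, record = rec, residuals = resid)
}
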