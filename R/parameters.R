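#' Adjustable model parameters
#'
#' Bundles the eleven adjustable quantities of the dynamic gas-exchange model
#' together with the (constant) mesophyll conductance `g_m`. Defaults are the
#' posterior medians obtained by Bayesian calibration against diurnal
#' Arabidopsis gas-exchange data, so that `model_parameters()` with no
#' arguments is a complete, runnable parameter set.
#'
#' @param a_min Minimum stomatal pore area in darkness (um^2).
#' @param a_max Maximum stomatal pore area (um^2); must exceed `a_min`.
#' @param alpha_L Initial slope of the pore-area light response
#'   (um^2 per umol m^-2 s^-1 of PPFD).
#' @param k_i Time constant for an increase of pore area (s).
#' @param k_d Time constant for a decrease of pore area (s).
#' @param Vc_max Maximum Rubisco carboxylation rate (umol m^-2 s^-1).
#' @param J_max Maximum electron transport rate (umol m^-2 s^-1).
#' @param R_d Mitochondrial (day) respiration (umol m^-2 s^-1), applied
#'   identically in light and darkness.
#' @param alpha Proportion of incident light absorbed by photosystem II
#'   (umol electron per umol photon), in (0, 1).
#' @param S_e Sugar-export relaxation factor of the efficiency state (s^-1).
#' @param S_a Sugar-accumulation feedback factor
#'   ((umol m^-2 s^-1)^-1 s^-1).
#' @param g_m Mesophyll conductance to CO2 (mol m^-2 s^-1), treated as a
#'   constant at fixed leaf temperature.
#'
#' @return An object of class `model_parameters` (a validated named list).
#' @examples
#' p <- model_parameters()
#' p$k_i / p$k_d   # opening is ~2.6x slower than closing
#' @export
model_parameters <- function(a_min = 4.16, a_max = 93.24, alpha_L = 0.767,
                             k_i = 1430, k_d = 541,
                             Vc_max = 99.3, J_max = 186.4, R_d = 0.14,
                             alpha = 0.183, S_e = 8.486e-6, S_a = 0.280e-6,
                             g_m = 0.2) {
  p <- list(a_min = a_min, a_max = a_max, alpha_L = alpha_L, k_i = k_i,
            k_d = k_d, Vc_max = Vc_max, J_max = J_max, R_d = R_d,
            alpha = alpha, S_e = S_e, S_a = S_a, g_m = g_m)
  validate_model_parameters(p)
  structure(p, class = "model_parameters")
}

validate_model_parameters <- function(p) {
  num1 <- function(x, nm) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  for (nm in names(p)) num1(p[[nm]], nm)
  stopifnot_param(p$a_min > 0, "a_min must be > 0")
  stopifnot_param(p$a_max > p$a_min, "a_max must exceed a_min")
  stopifnot_param(p$alpha_L >= 0, "alpha_L must be >= 0")
  stopifnot_param(p$k_i > 0 && p$k_d > 0, "time constants k_i, k_d must be > 0")
  stopifnot_param(p$Vc_max > 0 && p$J_max > 0, "Vc_max and J_max must be > 0")
  stopifnot_param(p$R_d >= 0, "R_d must be >= 0")
  stopifnot_param(p$alpha > 0 && p$alpha < 1, "alpha must lie in (0, 1)")
  stopifnot_param(p$S_e >= 0 && p$S_a >= 0, "S_e and S_a must be >= 0")
  stopifnot_param(p$g_m > 0, "g_m must be > 0")
  invisible(p)
}

stopifnot_param <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

#' @export
print.model_parameters <- function(x, ...) {
  cat("Dynamic gas-exchange model parameters\n")
  cat(sprintf("  pore area: a_min %.3g, a_max %.3g um^2; alpha_L %.3g um^2/(umol m^-2 s^-1)\n",
              x$a_min, x$a_max, x$alpha_L))
  cat(sprintf("  kinetics:  k_i %.4g s (opening), k_d %.4g s (closing)\n", x$k_i, x$k_d))
  cat(sprintf("  biochemistry: Vc_max %.4g, J_max %.4g, R_d %.3g umol m^-2 s^-1; alpha %.3g\n",
              x$Vc_max, x$J_max, x$R_d, x$alpha))
  cat(sprintf("  feedback:  S_e %.4g s^-1, S_a %.4g (umol m^-2 s^-1)^-1 s^-1\n", x$S_e, x$S_a))
  cat(sprintf("  mesophyll: g_m %.3g mol m^-2 s^-1\n", x$g_m))
  invisible(x)
}

#' Fixed anatomical and physical leaf constants
#'
#' Quantities held constant during a simulated diurnal period. Defaults follow
#' standard Arabidopsis leaf anatomy and cuvette conditions: summed stomatal
#' density of both leaf faces, pore depth from stomatal anatomy surveys, leaf
#' thickness 200 um with an airspace fraction of 0.255, and boundary-layer
#' conductance / atmospheric pressure as reported by an LI-6400-class cuvette.
#'
#' The depths of the intercellular airspace (`d_a`) and of the photosynthetic
#' tissue (`d_p`) are derived as `leaf_thickness * airspace_fraction` and
#' `leaf_thickness * (1 - airspace_fraction)` and stored in metres.
#'
#' @param SD Stomatal density, both faces summed (mm^-2).
#' @param l Depth of the stomatal pore (um).
#' @param D Diffusivity of water vapour in air at 25 C (m^2 s^-1).
#' @param V Molar volume of air at 25 C (m^3 mol^-1).
#' @param theta_L Curvature of the pore-area light response, in (0, 1].
#' @param leaf_thickness Leaf thickness (um).
#' @param airspace_fraction Fraction of leaf volume that is airspace, in (0, 1).
#' @param g_b Boundary-layer conductance to water vapour (mol m^-2 s^-1).
#' @param P_a Atmospheric pressure (kPa).
#' @param R_gas Universal gas constant (J mol^-1 K^-1).
#' @param O2 Oxygen mole fraction (mmol mol^-1).
#'
#' @return An object of class `leaf_constants` with derived elements `d_a` and
#'   `d_p` (m).
#' @examples
#' leaf_constants()$d_a   # 51 um of airspace depth, in metres
#' @export
leaf_constants <- function(SD = 400, l = 5.89, D = 24.2e-6, V = 0.02446533,
                           theta_L = 0.7, leaf_thickness = 200,
                           airspace_fraction = 0.255, g_b = 9.29,
                           P_a = 101.8, R_gas = 8.314462618, O2 = 210) {
  cc <- list(SD = SD, l = l, D = D, V = V, theta_L = theta_L,
             leaf_thickness = leaf_thickness,
             airspace_fraction = airspace_fraction,
             g_b = g_b, P_a = P_a, R_gas = R_gas, O2 = O2)
  for (nm in names(cc)) {
    if (!is.numeric(cc[[nm]]) || length(cc[[nm]]) != 1L || !is.finite(cc[[nm]]) ||
        cc[[nm]] <= 0)
      stop("leaf constant '", nm, "' must be a single positive number", call. = FALSE)
  }
  stopifnot_param(cc$airspace_fraction < 1, "airspace_fraction must lie in (0, 1)")
  stopifnot_param(cc$theta_L <= 1, "theta_L must lie in (0, 1]")
  cc$d_a <- cc$leaf_thickness * 1e-6 * cc$airspace_fraction
  cc$d_p <- cc$leaf_thickness * 1e-6 * (1 - cc$airspace_fraction)
  structure(cc, class = "leaf_constants")
}

#' @export
print.leaf_constants <- function(x, ...) {
  cat("Leaf constants\n")
  cat(sprintf("  SD %.4g mm^-2; pore depth %.3g um; leaf %.4g um, airspace %.3g\n",
              x$SD, x$l, x$leaf_thickness, x$airspace_fraction))
  cat(sprintf("  g_b %.4g mol m^-2 s^-1; P_a %.4g kPa; theta_L %.2g\n",
              x$g_b, x$P_a, x$theta_L))
  invisible(x)
}

#' Biochemical photosynthesis constants
#'
#' Michaelis constants, CO2 compensation point and temperature responses of the
#' biochemical photosynthesis model. The default preset carries the widely used
#' in-vivo tobacco kinetics (25 C reference values with Arrhenius activation
#' energies); it is shipped as an explicit, overridable configuration so that
#' simulations are reproducible bit-for-bit against the values recorded here.
#'
#' Temperature scaling uses `k(T) = k25 * exp(E * (T - 298.15) /
#' (298.15 * R * T))` with `T` in kelvin and activation energies in J mol^-1.
#' Only `Kc`, `Ko` and `Gamma_star` are temperature-adjusted; `Vc_max`, `J_max`
#' and `R_d` are calibrated quantities interpreted at the measurement
#' temperature.
#'
#' @param Kc Michaelis constant of Rubisco for CO2 at 25 C (umol mol^-1).
#' @param Ko Michaelis constant of Rubisco for O2 at 25 C (mmol mol^-1).
#' @param Gamma_star CO2 compensation point in the absence of mitochondrial
#'   respiration at 25 C (umol mol^-1).
#' @param theta_J Curvature of the electron-transport light response, in (0, 1].
#' @param E_Kc,E_Ko,E_Gamma_star Arrhenius activation energies (J mol^-1).
#'
#' @return An object of class `farquhar_constants`.
#' @export
farquhar_constants <- function(Kc = 404.9, Ko = 278.4, Gamma_star = 42.75,
                               theta_J = 0.7,
                               E_Kc = 79430, E_Ko = 36380,
                               E_Gamma_star = 37830) {
  fc <- list(Kc = Kc, Ko = Ko, Gamma_star = Gamma_star, theta_J = theta_J,
             E_Kc = E_Kc, E_Ko = E_Ko, E_Gamma_star = E_Gamma_star)
  for (nm in c("Kc", "Ko", "Gamma_star", "theta_J")) {
    if (!is.numeric(fc[[nm]]) || length(fc[[nm]]) != 1L || !is.finite(fc[[nm]]) ||
        fc[[nm]] <= 0)
      stop("Farquhar constant '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  stopifnot_param(fc$theta_J <= 1, "theta_J must lie in (0, 1]")
  structure(fc, class = "farquhar_constants")
}

#' @export
print.farquhar_constants <- function(x, ...) {
  cat("Farquhar kinetic constants (25 C reference)\n")
  cat(sprintf("  Kc %.4g umol mol^-1, Ko %.4g mmol mol^-1, Gamma* %.4g umol mol^-1, theta_J %.2g\n",
              x$Kc, x$Ko, x$Gamma_star, x$theta_J))
  invisible(x)
}

# Arrhenius scaling of the kinetic constants to leaf temperature (C).
# Returns list(Kc, Ko, Gamma_star) at T_leaf.
farquhar_at_temperature <- function(fconsts, T_leaf, R_gas = 8.314462618) {
  TK <- T_leaf + 273.15
  arrh <- function(k25, E) k25 * exp(E * (TK - 298.15) / (298.15 * R_gas * TK))
  list(Kc = arrh(fconsts$Kc, fconsts$E_Kc),
       Ko = arrh(fconsts$Ko, fconsts$E_Ko),
       Gamma_star = arrh(fconsts$Gamma_star, fconsts$E_Gamma_star))
}
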