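# Core single-step operations of the dynamic gas-exchange model.
# All user-facing quantities use field units (pore areas in um^2, mole
# fractions in umol mol^-1, conductances in mol m^-2 s^-1, pressures in kPa);
# conversion to SI happens once, inside each kernel.

# Lower root of the non-rectangular hyperbola
#   theta * y^2 - (x + asym) * y + x * asym = 0
# where x is the scaled driver and asym the asymptote. Used for both the
# pore-area light response and the electron-transport light response.
nonrect_hyperbola <- function(x, asym, theta) {
  if (theta < 1e-12) return(x * asym / (x + asym))  # rectangular limit
  disc <- (x + asym)^2 - 4 * theta * x * asym
  if (any(disc < -1e-8 * (x + asym)^2))
    stop("negative discriminant in non-rectangular hyperbola; ",
         "this indicates an implementation bug", call. = FALSE)
  (x + asym - sqrt(pmax(disc, 0))) / (2 * theta)
}

#' Steady-state target of the stomatal pore area
#'
#' Light response of the pore-area target `a_s`: a non-rectangular hyperbola in
#' PPFD rising from `a_min` towards `a_max`, multiplied by the efficiency state
#' `L` that carries the sugar-accumulation feedback.
#'
#' @param PPFD Photosynthetic photon flux density (umol m^-2 s^-1), >= 0.
#'   Vectorised.
#' @param L Efficiency state in \[0, 1\].
#' @param params A [model_parameters()] object.
#' @param consts A [leaf_constants()] object (supplies the curvature `theta_L`).
#' @return Pore-area target `a_s` (um^2), in `[0, a_max * L]`.
#' @examples
#' steady_state_aperture(0, 1)     # dark target = a_min
#' steady_state_aperture(100, 1)   # ~57.3 um^2 at the default parameters
#' @export
steady_state_aperture <- function(PPFD, L = 1, params = model_parameters(),
                                  consts = leaf_constants()) {
  if (any(!is.finite(PPFD)) || any(PPFD < 0))
    stop("PPFD must be finite and >= 0", call. = FALSE)
  if (length(L) != 1L || !is.finite(L) || L < 0 || L > 1)
    stop("L must be a single value in [0, 1]", call. = FALSE)
  validate_model_parameters(params)
  asym <- params$a_max - params$a_min
  (params$a_min + nonrect_hyperbola(params$alpha_L * PPFD, asym, consts$theta_L)) * L
}

#' Rate of change of the stomatal pore area
#'
#' Relaxation of the pore area `a` towards its target `a_s`, with distinct time
#' constants for opening (`k_i`, when `a < a_s`) and closing (`k_d`).
#'
#' @param a Current pore area (um^2).
#' @param a_s Pore-area target (um^2).
#' @param params A [model_parameters()] object.
#' @return `da/dt` (um^2 s^-1); same sign as `a_s - a`.
#' @export
aperture_rate <- function(a, a_s, params = model_parameters()) {
  if (any(a < 0) || any(a_s < 0)) stop("pore areas must be >= 0", call. = FALSE)
  if (params$k_i <= 0 || params$k_d <= 0)
    stop("time constants must be > 0", call. = FALSE)
  ifelse(a < a_s, (a_s - a) / params$k_i, (a_s - a) / params$k_d)
}

#' Stomatal conductance from pore area
#'
#' Scales the representative ('big stoma') pore area to leaf-level stomatal
#' conductance to water vapour through stomatal density and pore geometry
#' (pore depth plus the end-correction of a circular pore):
#' `g_s = SD * D * a / (V * (l + (pi/2) * sqrt(a / pi)))`, evaluated in SI.
#'
#' @param a Pore area (um^2), >= 0. Vectorised.
#' @param consts A [leaf_constants()] object.
#' @return Stomatal conductance to water vapour (mol m^-2 s^-1). Zero iff
#'   `a = 0`; strictly increasing in `a`; exactly proportional to `SD`.
#' @examples
#' stomatal_conductance(4.16)   # ~0.214 mol m^-2 s^-1 at default anatomy
#' @export
stomatal_conductance <- function(a, consts = leaf_constants()) {
  if (any(!is.finite(a)) || any(a < 0))
    stop("pore area must be finite and >= 0", call. = FALSE)
  a_si <- a * 1e-12                       # um^2 -> m^2
  SD_si <- consts$SD * 1e6                # mm^-2 -> m^-2
  l_si <- consts$l * 1e-6                 # um -> m
  SD_si * consts$D * a_si / (consts$V * (l_si + (pi / 2) * sqrt(a_si / pi)))
}

#' Total conductance to CO2
#'
#' Series combination of stomatal and boundary-layer conductances, converted
#' from water vapour to CO2 by the diffusivity ratios 1.6 (stomata) and 1.37
#' (boundary layer): `g_t = 1 / (1.6/g_s + 1.37/g_b)`.
#'
#' @param g_s Stomatal conductance to water vapour (mol m^-2 s^-1), >= 0.
#' @param g_b Boundary-layer conductance to water vapour (mol m^-2 s^-1), > 0.
#' @return Total conductance to CO2 (mol m^-2 s^-1); 0 when `g_s = 0`.
#' @export
total_co2_conductance <- function(g_s, g_b = leaf_constants()$g_b) {
  if (any(g_s < 0)) stop("g_s must be >= 0", call. = FALSE)
  if (g_b <= 0) stop("g_b must be > 0", call. = FALSE)
  ifelse(g_s == 0, 0, 1 / (1.6 / g_s + 1.37 / g_b))
}

#' Invert the pore area - conductance relationship
#'
#' Finds the unique pore area whose leaf-level stomatal conductance equals a
#' given `g_s`, by bracketed root finding on the strictly increasing
#' [stomatal_conductance()] curve. Used to initialise simulations from an
#' observed conductance.
#'
#' @param g_s Target stomatal conductance (mol m^-2 s^-1), >= 0.
#' @param consts A [leaf_constants()] object.
#' @param a_upper Upper bracket for the search (um^2); conductances beyond the
#'   bracket raise an error.
#' @param tol Absolute conductance tolerance of the root.
#' @return Pore area (um^2) with `stomatal_conductance(a) == g_s` to `tol`.
#' @export
invert_conductance <- function(g_s, consts = leaf_constants(),
                               a_upper = 1e6, tol = 1e-12) {
  if (length(g_s) != 1L || !is.finite(g_s) || g_s < 0)
    stop("g_s must be a single finite value >= 0", call. = FALSE)
  if (g_s == 0) return(0)
  if (stomatal_conductance(a_upper, consts) < g_s)
    stop("g_s = ", g_s, " exceeds the conductance of any pore area within ",
         "the physical bracket [0, ", a_upper, "] um^2", call. = FALSE)
  f <- function(a) stomatal_conductance(a, consts) - g_s
  uniroot(f, c(0, a_upper), tol = 1e-14, f.lower = -g_s)$root
}

#' Electron transport rate
#'
#' Non-rectangular hyperbola of the absorbed light `alpha * PPFD`, saturating
#' at `J_max` with curvature `theta_J`.
#'
#' @param PPFD Photosynthetic photon flux density (umol m^-2 s^-1), >= 0.
#'   Vectorised.
#' @param params A [model_parameters()] object (`alpha`, `J_max`).
#' @param fconsts A [farquhar_constants()] object (`theta_J`).
#' @return Electron transport rate J (umol m^-2 s^-1).
#' @export
electron_transport <- function(PPFD, params = model_parameters(),
                               fconsts = farquhar_constants()) {
  if (any(!is.finite(PPFD)) || any(PPFD < 0))
    stop("PPFD must be finite and >= 0", call. = FALSE)
  nonrect_hyperbola(params$alpha * PPFD, params$J_max, fconsts$theta_J)
}

#' Gross CO2 assimilation
#'
#' Biochemical photosynthesis model: the minimum of the Rubisco-limited rate
#' `Vc_max * (C_c - Gamma*) / (C_c + Kc * (1 + O/Ko))` and the
#' electron-transport-limited rate `(J/4) * (C_c - Gamma*) / (C_c + 2 Gamma*)`,
#' floored at zero below the compensation point. Kinetic constants are
#' Arrhenius-adjusted to `T_leaf`.
#'
#' @param C_c CO2 mole fraction at the carboxylation sites (umol mol^-1), >= 0.
#'   Vectorised.
#' @param PPFD Photosynthetic photon flux density (umol m^-2 s^-1).
#' @param T_leaf Leaf temperature (C).
#' @param params A [model_parameters()] object.
#' @param fconsts A [farquhar_constants()] object.
#' @param consts A [leaf_constants()] object (oxygen mole fraction, gas
#'   constant).
#' @return Gross assimilation A_G (umol m^-2 s^-1), >= 0.
#' @export
gross_assimilation <- function(C_c, PPFD, T_leaf = 25,
                               params = model_parameters(),
                               fconsts = farquhar_constants(),
                               consts = leaf_constants()) {
  if (any(C_c < 0)) stop("C_c must be >= 0", call. = FALSE)
  kin <- farquhar_at_temperature(fconsts, T_leaf, consts$R_gas)
  J <- electron_transport(PPFD, params, fconsts)
  Wc <- params$Vc_max * (C_c - kin$Gamma_star) /
    (C_c + kin$Kc * (1 + consts$O2 / kin$Ko))
  Wj <- (J / 4) * (C_c - kin$Gamma_star) / (C_c + 2 * kin$Gamma_star)
  pmax(pmin(Wc, Wj), 0)
}

#' Rate of change of intercellular CO2
#'
#' Balance of the CO2 flux entering through boundary layer and stomata and the
#' flux leaving into the mesophyll, converted from an area flux to a mole
#' fraction rate by `R * T_l / (d_a * P_a)` with `d_a` the depth of the
#' intercellular airspace.
#'
#' @param C_i,C_c CO2 mole fractions (umol mol^-1).
#' @param g_t Total conductance to CO2 (mol m^-2 s^-1).
#' @param g_m Mesophyll conductance to CO2 (mol m^-2 s^-1).
#' @param C_a Atmospheric CO2 mole fraction (umol mol^-1).
#' @param T_leaf Leaf temperature (C).
#' @param consts A [leaf_constants()] object.
#' @return `dC_i/dt` (umol mol^-1 s^-1).
#' @export
intercellular_co2_rate <- function(C_i, C_c, g_t, g_m, C_a = 400, T_leaf = 25,
                                   consts = leaf_constants()) {
  if (consts$d_a <= 0) stop("d_a must be > 0", call. = FALSE)
  conv <- consts$R_gas * (T_leaf + 273.15) / (consts$d_a * consts$P_a * 1e3)
  (g_t * (C_a - C_i) - g_m * (C_i - C_c)) * conv
}

#' Rate of change of CO2 at the carboxylation sites
#'
#' Balance of mesophyll inflow, mitochondrial respiration and the biochemical
#' sink `A_G * L`, converted by `R * T_l / (d_p * P_a)` with `d_p` the depth of
#' the photosynthetic tissue.
#'
#' @param C_i,C_c CO2 mole fractions (umol mol^-1).
#' @param g_m Mesophyll conductance to CO2 (mol m^-2 s^-1).
#' @param A_G Gross assimilation (umol m^-2 s^-1).
#' @param L Efficiency state in \[0, 1\].
#' @param T_leaf Leaf temperature (C).
#' @param params A [model_parameters()] object (`R_d`).
#' @param consts A [leaf_constants()] object.
#' @return `dC_c/dt` (umol mol^-1 s^-1).
#' @export
carboxylation_co2_rate <- function(C_i, C_c, g_m, A_G, L, T_leaf = 25,
                                   params = model_parameters(),
                                   consts = leaf_constants()) {
  if (consts$d_p <= 0) stop("d_p must be > 0", call. = FALSE)
  conv <- consts$R_gas * (T_leaf + 273.15) / (consts$d_p * consts$P_a * 1e3)
  (g_m * (C_i - C_c) + params$R_d - A_G * L) * conv
}

#' Rate of change of the efficiency state
#'
#' Sugar-accumulation feedback: `dL/dt = S_e * (1 - L) - S_a * A_G * L`.
#' The drift is non-negative at `L = 0` and non-positive at `L = 1` whenever
#' `A_G >= 0`, confining `L` to \[0, 1\] along every trajectory.
#'
#' @param L Efficiency state in \[0, 1\].
#' @param A_G Gross assimilation (umol m^-2 s^-1), >= 0.
#' @param params A [model_parameters()] object (`S_e`, `S_a`).
#' @return `dL/dt` (s^-1).
#' @export
efficiency_rate <- function(L, A_G, params = model_parameters()) {
  if (any(L < 0) || any(L > 1)) stop("L must lie in [0, 1]", call. = FALSE)
  if (any(A_G < 0)) stop("A_G must be >= 0", call. = FALSE)
  params$S_e * (1 - L) - params$S_a * A_G * L
}
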