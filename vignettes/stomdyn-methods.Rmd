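---
title: "The stomdyn dynamic gas-exchange model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The stomdyn dynamic gas-exchange model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`stomdyn` simulates leaf gas exchange under fluctuating light with a "big
stoma" approach: one representative stomatal pore stands in for the
heterogeneous population, and its behaviour is scaled to the leaf through
stomatal density. Four coupled state variables are integrated in time:

* $a$ — the pore area (µm²) of the representative stoma,
* $C_i$ — the CO₂ mole fraction in the intercellular airspaces (µmol mol⁻¹),
* $C_c$ — the CO₂ mole fraction at the carboxylation sites (µmol mol⁻¹),
* $L$ — a dimensionless efficiency state in $[0,1]$ carrying the slow
  negative feedback of sugar accumulation.

The pore area relaxes towards a light-dependent target with asymmetric
kinetics,

$$\frac{da}{dt} = \begin{cases}(a_s - a)/k_i & a < a_s\\
(a_s - a)/k_d & a \ge a_s,\end{cases}$$

where the target $a_s$ is a non-rectangular hyperbola in PPFD rising from
$a_{\min}$ towards $a_{\max}$ with initial slope $\alpha_L$ and curvature
$\theta_L$, multiplied by $L$. Leaf-level stomatal conductance to water
vapour follows from pore geometry and stomatal density,

$$g_s = \frac{SD \cdot D \cdot a}{V\,(l + \tfrac{\pi}{2}\sqrt{a/\pi})},$$

and the total conductance to CO₂ combines stomata and boundary layer in
series with the diffusivity ratios 1.6 and 1.37. The two CO₂ balances convert
area fluxes into mole-fraction rates through $R\,T_l/(d\,P_a)$, with $d$ the
depth of the intercellular airspace ($d_a$) or of the photosynthetic tissue
($d_p$):

$$\frac{dC_i}{dt} = \big[g_t (C_a - C_i) - g_m (C_i - C_c)\big]
  \frac{R\,T_l}{d_a P_a}, \qquad
\frac{dC_c}{dt} = \big[g_m (C_i - C_c) + R_d - A_G L\big]
  \frac{R\,T_l}{d_p P_a}.$$

Gross assimilation $A_G$ is the classical biochemical model — the minimum of
the Rubisco-limited and electron-transport-limited rates, floored at zero
below the compensation point — evaluated at the current $C_c$. The efficiency
state obeys

$$\frac{dL}{dt} = S_e (1 - L) - S_a A_G L,$$

whose drift is non-negative at $L=0$ and non-positive at $L=1$, so $L$ is
confined to $[0,1]$ along every trajectory; its fixed point
$L^* = S_e/(S_e + S_a A_G)$ makes both the aperture target and the realised
assimilation sag slowly under sustained photosynthesis.

Mesophyll conductance $g_m$ is a scalar constant (leaf temperature is held
fixed in all protocols the package targets); it is never computed
mechanistically.

### Units

Users supply quantities in the field's customary units (pore areas in µm²,
densities in mm⁻², mole fractions in µmol mol⁻¹, pressures in kPa,
temperatures in °C). Every kernel converts to SI once, internally — the two
balance equations above mix unit systems notoriously easily, and a single
conversion point keeps the factors auditable. The frozen conversion factors
at the default anatomy (477.45 and 163.42 mol⁻¹ m² at 25 °C and 101.8 kPa)
are asserted in the unit tests against hand calculations.

### Reported net assimilation

The biochemical sink in the $C_c$ balance is $A_G\,L$, so the package reports
$A = A_G L - R_d$ by default: anything else would let the reported flux
disagree with the mass balance that produced the trajectory, and only this
form reproduces the slow diurnal decline of $A$ that the feedback state
exists to describe. The alternative convention $A = A_G - R_d$ is available
via `net_assimilation = "gross"` in `simulate_gas_exchange()`.

### Default parameter values

`model_parameters()` defaults to the posterior medians of a Bayesian
calibration against diurnal Arabidopsis gas exchange: $a_{\min} = 4.16$,
$a_{\max} = 93.24$ µm², $\alpha_L = 0.767$ µm²/(µmol m⁻² s⁻¹),
$k_i = 1430$ s, $k_d = 541$ s, $V_{c,\max} = 99.3$,
$J_{\max} = 186.4$, $R_d = 0.14$ µmol m⁻² s⁻¹, $\alpha = 0.183$,
$S_e = 8.486\times10^{-6}$ s⁻¹, $S_a = 0.280\times10^{-6}$
(µmol m⁻² s⁻¹)⁻¹ s⁻¹. The biochemical kinetic constants
(`farquhar_constants()`) ship as an explicit preset — the standard in-vivo
tobacco values $K_c = 404.9$ µmol mol⁻¹, $K_o = 278.4$ mmol mol⁻¹,
$\Gamma^* = 42.75$ µmol mol⁻¹ at 25 °C with Arrhenius temperature scaling —
because the calibration literature cites rather than prints them; every value
is overridable and recorded, so any run is reproducible bit-for-bit from its
configuration echo. $g_m$ defaults to 0.2 mol m⁻² s⁻¹, a mid-range
Arabidopsis value. Only $K_c$, $K_o$ and $\Gamma^*$ are temperature-adjusted;
$V_{c,\max}$, $J_{\max}$ and $R_d$ are calibrated quantities interpreted at
the measurement temperature.

The electron-transport light response is not printed in the calibration
literature either; by the same analogy that fixes $\theta_L = 0.7$ for the
aperture response, the package uses the non-rectangular hyperbola in absorbed
light $\alpha\,\mathrm{PPFD}$ saturating at $J_{\max}$ with
$\theta_J = 0.7$.

## Numerical choices

**Integration.** The system is mildly stiff (time scales from seconds for the
CO₂ pools to hours for $L$), and is solved with `deSolve`'s `lsoda` by
default (`lsodes` is available). The opening/closing switch at $a = a_s$ is a
discontinuity of the vector field only — the state stays continuous — and is
handled by the adaptive step control without event detection. The absolute
tolerance starts at 0.01 in native units and is divided by 10 on solver
failure, with bounded retries.

**Likelihood evaluations** integrate much tighter (atol $10^{-6}$, rtol
$10^{-8}$). Sampler moves probe log-likelihood differences far below the
observation noise, and integration error at the 0.01 tolerance is large
enough to create artificial local optima that trap chains; the tight
tolerance restores a smooth surface at roughly double the per-evaluation
cost.

**Steady states** (`steady_state()`) are found algebraically, not by long
integration: for a trial $L$ the aperture and conductances are explicit and
the two CO₂ balances collapse to one monotone equation in $C_c$ (solved by
bracketed bisection with an upper bracket
$C_a + R_d(1/g_m + 1.6/g_s + 1.37/g_b) + 100$); the efficiency drift then
closes an outer bracketed solve in $L \in [10^{-6}, 1]$, whose lower endpoint
is safe because the drift is analytically positive as $L \to 0^+$. Residuals
of all four balances are checked against $10^{-9}$ at the solution. This
route shares no code with the integrator and serves as its oracle in the
tests: the long-horizon limit of `simulate_gas_exchange()` matches it at
PPFD ∈ {0, 50, 100, 500, 1000} with flux imbalance below 0.1%.

**Initial conditions.** Pure simulations start at the full steady state under
the first light level. When fitting, the first observed conductance can pin
the initial aperture through `invert_conductance()` (bracketed root finding
on the strictly increasing pore-to-leaf map).

**Edge conventions.** $W_i = A/g_s$ is reported as `NaN` where $g_s = 0$;
$A_G$ is floored at zero below the compensation point; $R_d$ applies
identically in light and darkness.

## Bayesian calibration

The likelihood treats the observed $A$ and $g_s$ series as two independent
homoscedastic Gaussian channels — the two objective functions of the
calibration. The noise SDs are either fixed from configuration or (default)
sampled as nuisance parameters under half-Cauchy priors, since the
calibration literature states only that two objectives were used. Priors are
independent Gaussians truncated to each parameter's physical domain, with
literature means and SDs (`default_priors()`); the truncation mass is not
renormalised, which cancels in Metropolis ratios, and the joint constraint
$a_{\max} > a_{\min}$ is enforced in the support.

Sampling is two-phase. Phase 1 is an adaptive-covariance warm-up in the
spirit of inter-chain adaptation: the multivariate-normal proposal is
re-estimated every 25 iterations from the pooled trailing half of all
chains' history, scaled by $2.38^2/d$ with a global factor tuned towards the
0.234 acceptance target; degenerate covariances are regularised with diagonal
jitter and logged. Phase 2 freezes the kernel — plain random-walk Metropolis
with the adapted covariance, so the retained (thinned) samples come from a
Markovian kernel with no adaptive effect. The warm-up is the first 50% of
iterations and is discarded.

Because the production setting (2 chains × 30 000 iterations) is often run
scaled down, chains start from a short Nelder–Mead posterior-mode search
(3 000 evaluations, parameters scaled by their prior SDs) rather than from
the prior means: at a few thousand iterations an adaptive warm-up cannot
reliably travel from vague prior means (e.g. a prior mean of 100 s for a
time constant whose posterior sits near 1 430 s) to the posterior bulk, and
chains that fail to arrive report confidently wrong intervals. With no
observations the sampler draws from the truncated prior, which is how the
sampler itself is validated (Kolmogorov–Smirnov against the closed-form
truncated-normal CDFs).

Diagnostics follow the conventional acceptance thresholds: sampling-phase
acceptance rate above 15%, autocorrelation-based effective sample size
(Geyer initial-positive-sequence truncation) above 100, and batch-means
Monte-Carlo standard error below 6.27% of the posterior SD — the value at
which the estimated mean is within 5% of the posterior mass of the true
mean, reached by roughly 254 independent samples. MCSE is computed and
thresholded per parameter. Rather than asserting unimodality — two
simultaneously fitted outputs carry a real risk of bimodal posteriors — the
summary compares per-chain medians against within-chain spread and warns
when chains disagree, while still returning the pooled summary.

## The in-silico experiments

**Sensitivity scan.** Each adjustable parameter (the eleven calibrated ones
plus $g_m$ and $SD$) is scaled by $1 \pm 0.5$ one at a time and the
photoperiod means of $A$ and $g_s$ are expressed as ratios to the baseline
run. "Daily mean" uses the lights-on window only, matching the diurnal
framing of the protocol. The scan is continuous in the fraction: as it goes
to zero all ratios go to 1, which the tests assert.

**Step change.** 30 min at 100 µmol m⁻² s⁻¹, then 2 h at
1000 µmol m⁻² s⁻¹, with $C_a = 400$ µmol mol⁻¹ and 25 °C throughout; each
run (reference and variants scaling one of $SD$, $k_i$, $\alpha_L$ by 2 or
½) is initialised at its own pre-step steady state. The initial conductance
slope is an ordinary least-squares regression of $g_s$ on time over the
first 10 min after the step, reported both per second and per hour — the
per-hour convention gives the physiologically readable magnitude, and the
2:1 slope ratio under density halving is exact up to the weak $L$ feedback.
Mean responses are $100\,(\text{variant} - \text{reference})/\text{reference}$
over the 2-h post-step window; $W_i$ is aggregated as the mean of the
instantaneous $A/g_s$ (the `ratio_of_means` alternative is exposed as a
flag, since either aggregation is defensible).

At the default posterior-median parameters the aperture light response is
essentially saturated at the high step level
($\alpha_L \cdot 1000 \gg a_{\max} - a_{\min}$), so the reference run sits
near $a_{\max}$ with a high $g_s$ and CO₂ supply barely limits assimilation.
The qualitative structure — impact ordering $SD > \alpha_L > k_i$ for both
the $A$ penalty and the $W_i$ gain, and the exact slope halving with density
— is robust to this; the absolute percentage responses of $A$ depend
strongly on how diffusion-limited the reference is, and should be read with
that caveat.

## Synthetic data

`gaussian_fluctuating_light()` emulates a programmed diurnal regime: a
Gaussian irradiance envelope (default 12-h photoperiod, 1000 µmol m⁻² s⁻¹
peak) multiplied by unit-mean log-normal AR(1) noise (default CV 0.3,
600-s correlation time), clipped at zero. Multiplicative noise keeps
fluctuations proportional to the envelope, as cloud-driven variation is.
`natural_like_light()` emulates the statistics of a recorded field series
instead: piecewise-constant light changing at exponentially distributed
intervals (default mean 480 s, the "change every 8 min" regime), with
segment levels drawn under the envelope. Both are pure functions of their
specification and seed. `synthetic_observations()` simulates a known
parameter set, samples every 120 s (the gas-analyser logging interval the
package emulates) and adds independent Gaussian noise — defaults
$\sigma_A = 0.6$ µmol m⁻² s⁻¹ and $\sigma_{g_s} = 0.014$ mol m⁻² s⁻¹, the
magnitudes of typical fit residuals for these instruments.

What the generators deliberately do not emulate: spectral quality (PPFD
only), humidity and temperature excursions, instrument drift, and the
autocorrelated component of real measurement error. Passing the recovery
tests therefore shows that the inference machinery is self-consistent under
the model's own assumptions — not that the model is correct for any
particular leaf.

**Recovery-test design.** The parameter-recovery checks generate
observations under a 6-h fluctuating envelope with 30-min dark margins on
both sides. The dark segments matter: the minimum pore area is identified by
dark conductance (exactly as it is in practice), and without them its
informative literature prior dominates. At the scaled-down setting used in
the tests (2 chains × 5 000 iterations, identifiable subset
$\{a_{\min}, \alpha_L, k_i, k_d, J_{\max}, \alpha\}$, noise fixed at the
defaults) the generating values fall inside their 95% credible intervals in
29 of 30 parameter-trials across five replicate fits.

## Problem sizes and runtimes

The test suite runs simulations of $10^3$–$6\times10^5$ s at 10–600 s output
resolution (milliseconds each; the right-hand side is compiled C under
`deSolve`), prior-only chains of 2 × 30 000 (seconds) and one full recovery
fit of 2 × 5 000 iterations on 226 observations (about two to three
minutes). The acceptance script runs the four deterministic step-change
simulations and two diurnal simulations in a few seconds.

## Known limitations

* No humidity, vapour-pressure-deficit, ABA or temperature response of
  stomata; no energy balance; no transpiration-based water-use efficiency.
* One representative stoma: spatial heterogeneity (patchiness) is outside
  the model by construction.
* $g_m$ constant; the efficiency feedback is a single first-order state and
  cannot represent, e.g., distinct starch/sucrose pools.
* The branch-switching aperture equation makes the vector field
  discontinuous; trajectories are fine, but derivative-based sensitivity
  methods would need care.
* Posterior geometry can be multi-modal when both outputs are fitted; the
  package surfaces between-chain disagreement instead of hiding it, and
  short chains should always be read alongside their diagnostics.
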