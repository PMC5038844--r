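# stomdyn

Dynamic modelling of stomatal conductance, photosynthesis and intrinsic
water-use efficiency under fluctuating light.

Leaves in the field almost never see constant light, and the stomatal
conductance response (*g<sub>s</sub>*, minutes) lags the photosynthetic
response (*A*, seconds) by an order of magnitude — so intrinsic water-use
efficiency, *W<sub>i</sub> = A / g<sub>s</sub>* (µmol CO₂ per mol H₂O),
swings continuously through the day. `stomdyn` is for plant ecophysiologists
who want to dissect those dynamics into measurable traits: stomatal density
and pore geometry, the speed and light sensitivity of pore opening,
photosynthetic capacity, and the slow sugar-accumulation feedback that
depresses both assimilation and conductance towards the end of a diurnal
period.

## The model

A "big stoma" approach: one representative pore, scaled to the leaf through
stomatal density. Four coupled ODEs are integrated over an arbitrary light
regime —

- pore area `a` relaxing towards a non-rectangular-hyperbola light target
  `a_s(PPFD) · L`, with separate opening/closing time constants
  (`da/dt = (a_s − a)/k_i` or `/k_d`);
- CO₂ in the intercellular airspaces,
  `dC_i/dt = [g_t(C_a − C_i) − g_m(C_i − C_c)] · R T_l/(d_a P_a)`;
- CO₂ at the carboxylation sites,
  `dC_c/dt = [g_m(C_i − C_c) + R_d − A_G·L] · R T_l/(d_p P_a)`, with `A_G`
  the Farquhar (min of Rubisco- and electron-transport-limited) gross rate;
- a feedback efficiency state `dL/dt = S_e(1 − L) − S_a·A_G·L` confined to
  [0, 1].

Leaf conductance follows from pore geometry,
`g_s = SD·D·a / (V·(l + (π/2)√(a/π)))`, and
`g_t = 1/(1.6/g_s + 1.37/g_b)` converts to CO₂. Reported net assimilation is
`A = A_G·L − R_d` (consistent with the mass balance; `A_G − R_d` is
available as an option) and `W_i = A/g_s`.

Around the forward model the package provides Bayesian calibration against
observed `A`/`g_s` time series (truncated-Gaussian priors, adaptive warm-up
+ fixed random-walk Metropolis, ESS/MCSE/acceptance diagnostics, credible
intervals), a ±50% one-at-a-time sensitivity scan, step-change light
experiments with initial-slope and 2-h mean-response statistics, and
generators for synthetic light regimes and noisy observations. See the
methods vignette (`vignettes/stomdyn-methods.Rmd`) for the full account.

## Worked example

Simulate the classic step-change protocol — 30 min at 100 µmol m⁻² s⁻¹,
then 2 h at 1000 — and ask how stomatal traits shape the response:

```r
library(stomdyn)

st <- step_change_experiment(
  params   = model_parameters(),          # calibrated posterior medians
  variants = list(SD = 0.5, k_i = 2, alpha_L = 0.5))
st
#> Step-change experiment: 100 -> 1000 umol m^-2 s^-1
#>   reference initial g_s slope: 1.39 mol m^-2 s^-1 h^-1
#>   SD x0.5: mean A -1.48%, mean W_i +96.95%, slope 0.694 /h
#>   k_i x2: mean A -0.07%, mean W_i +4.84%, slope 0.781 /h
#>   alpha_L x0.5: mean A -0.11%, mean W_i +7.88%, slope 2.36 /h
```

Reading this: halving stomatal density halves the initial conductance slope
exactly (0.694/1.39 — `g_s` is linear in `SD`), costs only 1.5% of the 2-h
mean assimilation, but nearly doubles mean water-use efficiency — stomatal
density is the dominant lever, followed by the aperture light-response slope
`alpha_L` and then the opening time constant `k_i`, for both statistics.
Slopes are reported per hour; at these parameter values the pore target is
nearly light-saturated at the upper step, so `A` is only weakly
diffusion-limited and its percentage penalties are small.

The steady state is available algebraically (it also serves as the
integrator's oracle in the tests):

```r
steady_state(1000)$record
#>   time ppfd        a      a_s      g_s       g_t      C_i      C_c         L
#> 1    0 1000 53.63846 53.63846 1.714193 0.9251943 386.9177 326.3996 0.5960152
#>        A_G        A      W_i
#> 1 20.54247 12.10362 7.060828
```

Calibration on (here synthetic) observations:

```r
env <- gaussian_fluctuating_light(seed = 1)            # 12-h fluctuating day
syn <- synthetic_observations(env, sigma_A = 0.6, sigma_gs = 0.014, seed = 1)
fit <- sample_posterior(syn$obs, iterations = 30000, chains = 2, seed = 1)
summarize_posterior(fit)    # 2.5/50/97.5% quantiles, ESS, MCSE% per parameter
```

A thin command-line wrapper covers the same ground
(`exec/stomdyn simulate|fit|sensitivity|step|synth`), reading YAML
configurations and CSV light/observation files and embedding the resolved
configuration in every output for provenance.

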