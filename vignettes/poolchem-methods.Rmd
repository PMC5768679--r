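---
title: "Methods: tide-pool carbonate chemistry, metabolism and feedbacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tide-pool carbonate chemistry, metabolism and feedbacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolchem)
```

## The scientific problem

Rocky-intertidal tide pools behave as nearly closed reactors during low
tide: the chemistry of the trapped water integrates everything the
resident community does. Photosynthesis and respiration move dissolved
inorganic carbon (DIC), calcification and CaCO3 dissolution move both
total alkalinity (TA) and DIC in a fixed 2:1 ratio, and CO2 exchanges
slowly with the atmosphere. Repeated bottle samples over a low-tide
period therefore allow the two key metabolic rates of the ecosystem to be
budgeted per pool and per hour:

* **Net ecosystem calcification** (NEC, mmol CaCO3 m^-2^ h^-1^), from the
  alkalinity-anomaly technique:
  $$NEC = \frac{\Delta TA \cdot \rho \cdot V}{2 \cdot SA \cdot t}$$
* **Net community production** (NCP, mmol C m^-2^ h^-1^), from the DIC
  budget after removing the calcification and air-sea flux terms:
  $$NCP = \frac{\Delta DIC \cdot \rho \cdot V}{SA \cdot t} - NEC - FCO_2$$
* **Air-sea CO2 flux**:
  $$FCO_2 = k \cdot s \cdot \rho \,(pCO_{2,water} - pCO_{2,air})$$

with $\rho$ the seawater density (1023 kg m^-3^ by default), $V$ the pool
volume, $SA$ its bottom surface area, $t$ the interval length, $k$ the
gas transfer velocity and $s$ the CO2 solubility. Differences are taken
as *start minus end*, so TA drawdown yields positive NEC (net
calcification) and DIC drawdown not otherwise explained yields positive
NCP (net photosynthesis). Both TA and DIC are normalised to a reference
salinity (36 by default) before differencing to remove evaporative
concentration, and TA is corrected for the small acid-base contributions
of dissolved inorganic nitrogen and phosphorus
(`TA* = TA + NO3 + PO4 - NH4`).

The downstream statistical layer asks what drives the pool-to-pool
differences in pH regime (community composition, ecosystem metabolism,
physical attributes, light, temperature) and quantifies the biophysical
feedback loop: production raises pH, and higher pH (via the aragonite
saturation state) promotes calcification.

## The carbonate-system solver

Bottle samples are measured as pH (total scale) plus titrated TA; all
remaining carbonate parameters are computed. `carb_from_ph_ta()` is
closed-form: at known [H^+^] every non-carbonate alkalinity term (borate,
water, free proton, fluoride, phosphate, silicate, ammonium) is explicit,
and carbonate alkalinity is linear in DIC. `carb_from_ta_dic()` inverts
the same expression by a bracketed root search for pH on [3, 12]
(Brent's bisection/secant hybrid; the simulator's inner loop uses a
warm-started Newton refinement of the same residual), converged to a TA
residual below 1e-4 umol/kg. `adjust_to_insitu()` moves a laboratory
measurement to in-situ temperature through the conservativity of TA and
DIC.

Constant formulations (all on the total pH scale, converted where the
source publishes on the seawater scale): K1/K2 from Lueker et al. (2000),
KB from Dickson (1990), KW / phosphoric / silicic constants from Millero
(1995), ammonium from Yao & Millero (1995), bisulfate from Dickson
(1990), fluoride from Perez & Fraga (1987), aragonite Ksp from Mucci
(1983), total borate from Uppstrom (1974) and total calcium from Riley &
Tongudai (1967). These are the de-facto community defaults for coastal
carbonate work; since field studies rarely state every option they used,
the choice is a package design decision and the constant set is exposed
as a first-class object (`equilibrium_constants()`) rather than buried.
Tide pools are sampled at the surface, so no pressure corrections are
implemented. Only the (pH, TA) and (TA, DIC) input pairs are supported,
and no uncertainty propagation is attempted.

The gas-exchange pieces follow the standard parameterisations: Weiss
(1974) solubility, the Wanninkhof (2014) Schmidt-number polynomial, and
the Ho et al. (2006) quadratic wind speed relation
k600 = 0.266 u^2 cm h^-1, rescaled by (Sc/600)^-1/2. Atmospheric pCO2
defaults to 400 uatm.

## Key tunable parameters

| Parameter | Default | Unit | Where |
|---|---|---|---|
| `rho` | 1023 | kg m^-3^ | `phys_config()` |
| `pco2_air` | 400 | uatm | `phys_config()` |
| `salinity_ref` | 36 | PSU | `phys_config()` |
| `nutrient_signs` | NO3 +1, PO4 +1, NH4 -1 | -- | `phys_config()` |
| PAR conversion | 0.0185 | umol m^-2^ s^-1^ per lux | `lumens_to_par()` |
| pH noise | 0.005 | total scale | `sim_config()` |
| TA noise | 3 | umol kg^-1^ | `sim_config()` |

The nutrient-correction sign convention is configurable because the
alkalinity-budget literature is not uniform about it; the default removes
the alkalinity signal of nitrate/phosphate uptake and ammonium release.
The lux-to-PAR coefficient is the customary daylight conversion (about
54 lux per umol m^-2^ s^-1^); pendant-logger calibrations are instrument-
specific, so the coefficient is an argument, not a constant. The default
per-taxon mobile-invertebrate footprint areas are likewise placeholders
to be replaced by local calibrations.

## The forward simulator

`simulate_pool_series()` integrates the closed-pool budget with forward
Euler steps (1 min by default, configurable; the step hides
discretisation error well below measurement noise):

* NCP(t) = PD-scaled P_max tanh(PAR/I_k) - R, with PAR a half-sine over
  the daytime low-tide window and zero at night. Producer dominance (PD,
  in [-100, 100]) scales the production amplitude linearly from 0 at
  PD = -100 to P_max at PD = +100. Gross production additionally carries
  a CO2-availability factor tanh(pCO2/20): exactly 1 at any ordinary
  pCO2, it shuts production down below ~60 uatm so that hours of strong
  fixation in a small, high-SA:V pool cannot push the chemistry into
  physically impossible drawdowns.
* NEC(t) = k_calc max(Omega - 1, 0) - k_diss max(1 - Omega, 0) when the
  Omega feedback is on; a configured constant otherwise. The tanh
  light-response and the linear Omega-dependence are simulator choices -
  convenient, monotone forms with the right signs - not claims about any
  particular field system.
* FCO2 uses the same flux formulation as the analysis; DIC and TA are
  updated conservatively (TA falls 2 per CaCO3 precipitated), evaporation
  (off by default) scales salinity, TA and DIC jointly; pH is re-solved
  from (TA, DIC) at every step; DO tracks cumulative NCP through a
  photosynthetic quotient.

Bottle samples are emitted hourly with Gaussian observation noise (pH
0.005, TA 3 umol/kg by default - loose emulations of glass-electrode
precision and titration accuracy), and the truth table records
*interval-averaged* instantaneous rates, which is exactly what the
interval estimator targets.

The campaign-level defaults mirror a realistic multi-site design: 4
sites whose ocean pH presets run 8.12, 8.04, 7.95, 7.87 (endpoints at
the observed extremes of a latitudinal gradient, interior values
interpolated), 14/13/15/15 pools per site, day and night events of 6
hourly samples, and an even producer-dominance gradient across pools.
The default simulator salinity equals the reference salinity (36), so
salinity normalisation is the identity unless evaporation is enabled;
this keeps recovery tests interpretable, because normalising a S = 34
series to S_ref = 36 rescales concentration differences by 36/34 by
construction.

What the simulator does *not* emulate: within-pool spatial
heterogeneity, high-tide flushing, hydrodynamics, temperature dynamics
within an event (pools get a constant per-event temperature offset from
the ocean), nutrient dynamics (baselines plus noise only), and any
covariance structure among geometry, community and forcing beyond the
imposed PD gradient. Passing recovery tests therefore demonstrates that
the estimators are correct for the budget model they assume - not that
the budget model captures every process in real pools.

## Statistical layer

Pool summaries comprise day/night mean pH, the pH range over the entire
sampling period (one range per pool, day and night pooled - the
alternative reading, one range per event, is narrower and less
comparable across pools sampled at different times), and the signed pH
divergence: the pool-minus-ocean difference of largest absolute value,
sign retained, since pools diverge both upwards (producer-dominated) and
downwards (consumer-dominated). The TA/DIC slope - OLS of
salinity-normalised TA on DIC across all time points - summarises the
calcification:production stoichiometry; pure calcification gives slope
2, pure production slope 0, and a mixed process with NEC:NCP molar ratio
r gives 2r/(1+r), a closed form the tests exploit.

Driver models are random-intercept linear mixed models fit by REML via
`nlme`: site intercepts in all models, pool-within-site intercepts plus
day/night interactions and optionally unequal day/night residual
variances (`varIdent`) in the pH-mean model. Response and predictors are
z-scored, so coefficients are standardized effect sizes; the
significance convention is a 95% CI (t-based, using nlme's degrees of
freedom) that excludes zero. Re-implementing REML would add nothing -
the models are entirely standard - so the package delegates the
optimisation to `nlme` and owns the model specification, effect
extraction and calibration. The feedback models (pH ~ NCP, NEC ~ pH,
NEC ~ NCP) are interval-level mixed models with pool random intercepts
and site-interaction slopes; per-site slopes and their CIs are recovered
as linear combinations of the fixed effects.

Calibration is checked by simulation at the summary level
(`simulate_pool_summaries()`, which isolates the inference machinery
from the biogeochemistry): under a zero-effect design of 57 pools in 4
sites the CI-excludes-zero rule shows an empirical type-I error within
the expected band around 5%, and an injected standardized
producer-dominance effect of 0.8 is recovered with the correct sign
essentially always.

## Numerical choices and degenerate inputs

* Root bracket [3, 12] pH; infeasible (TA, DIC) pairs - no sign change of
  the alkalinity residual - raise an explicit no-solution error, as do
  (pH, TA) pairs whose implied carbonate alkalinity is non-positive.
* The air-sea flux over an interval is evaluated at the interval
  midpoint state (endpoint means of pCO2, solubility and transfer
  velocity); the resulting approximation error is quadratic in the rate
  and in practice orders of magnitude below the 1% recovery tolerance.
* PCA is computed on the correlation matrix (mixed units), constant
  columns are dropped with a warning, and loadings are oriented so pool
  volume loads positively on PC1 ("pool size").
* Zero-variance columns abort standardisation with the column named;
  perfect collinearity yields an infinite VIF flag rather than an error.
* Mixed-model fits try `optim` then `nlminb` before raising a
  convergence error.

## Validation problem sizes

The shipped validation uses problem sizes chosen to exercise every code
path at desk scale: 100 random states for the solver-oracle comparison,
20 pools x 6 samples for rate recovery with 50-100 replicate noise
draws (on a fixed grid of moderate pool geometries, since a pool driven
at a strong constant rate for hours must hold enough water for the
implied DIC drawdown to remain chemically feasible), 2-3 sites x 3-6 pools for feedback-mechanism recovery with 50-100
replicates, and 200-500 replicates for the mixed-model calibration.
These sizes give Monte-Carlo standard errors comfortably inside the
tolerances being checked.

## Known limitations

* The solver supports only the (pH, TA) and (TA, DIC) input pairs, with
  no uncertainty propagation.
* DO is carried as an auxiliary variable (and used for the DO-pH
  coupling check); no oxygen-based metabolism estimates are produced.
* The statistical layer assumes linear relationships throughout.
* Real light-logger series are supported through `lumens_to_par()` /
  `integrate_par()`, but the simulator does not emit synthetic light
  series; in simulated campaigns the drivers analysis runs without the
  integrated-PAR predictor.
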