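---
title: "Models and methods behind lrcfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lrcfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrcfit)
```

This vignette records the models the package implements, the assumptions
behind them, and the numerical and design choices made where more than
one defensible option existed.

## The three model families

All three families describe a response $y$ (net CO₂ assimilation $P_n$,
electron transport rate $J$, or a derived efficiency channel) as a
function of irradiance $I$ (μmol photons m⁻² s⁻¹).

**Rectangular hyperbola (RH).**
$P_n = \alpha I P_m / (\alpha I + P_m) - R_d$. Two shape parameters plus
respiration; monotone, with asymptote $P_m - R_d$. Its initial slope and
asymptote are tightly coupled, which is why it tends to inflate both the
apparent quantum yield and the fitted maximum.

**Non-rectangular hyperbola (NRH).** The smaller root of
$\theta P^2 - (\alpha I + P_m)P + \alpha I P_m = 0$, minus $R_d$. The
convexity $\theta \in (0,1]$ interpolates between the RH limit
($\theta \to 0$) and the Blackman limit
($\theta = 1$: $\min(\alpha I, P_m) - R_d$). Still monotone: no finite
saturation irradiance exists, and the package signals that explicitly
(condition class `lrc_no_saturation`) rather than returning a number.

**Mechanistic family.**
$P_n = \alpha(1-\beta I)I/(1+\gamma I) - R_d$. The three coefficients
aggregate a microscopic description of light harvesting — light
absorption by a pigment pool, exciton transfer, and partitioning of
de-excitation between photochemistry, heat and fluorescence. The
micro-constants (energy-level degeneracies, rate constants, statistical
weights, excited-state lifetime, …) are jointly non-identifiable from a
single curve, so only the aggregates are ever fitted; the microscopic
interpretation matters because it gives $\beta$ (photoinhibition /
antenna down-regulation) and $\gamma$ (saturation) physical meaning and
links the leaf-level fit to pigment photophysics (below). With
$\beta > 0$ the family has closed forms for its interior maximum,
saturation irradiance, and derivative (quantum efficiency); these are
implemented exactly, and `invert_ye()` inverts maximum + saturation
irradiance back to $(\beta, \gamma)$ algebraically:
$\beta = (y_{max}+R_d)/(\alpha I_{sat}^2)$,
$\gamma = (1/\beta - 2 I_{sat})/I_{sat}^2$.

A rendering quirk in common typesettings of the quantum-efficiency
expression makes it ambiguous; the package uses the calculus-forced
form — the exact derivative of the response,
$\alpha(1 - 2\beta I - \beta\gamma I^2)/(1+\gamma I)^2$ — whose positive
root reproduces the closed-form saturation irradiance, and the test
suite checks it against central finite differences at $10^{-6}$
relative tolerance.

## Numerical choices

* The NRH quadratic root is evaluated through the quotient form
  $2\alpha I P_m / (A + \sqrt{A^2 - 4\theta\alpha I P_m})$,
  $A = \alpha I + P_m$, which avoids catastrophic cancellation as
  $\theta \to 0$ (verified to track the RH limit within $10^{-5}$ at
  $\theta = 10^{-8}$).
* Light compensation points: closed form for RH; bracketed root finding
  on $[0, I_{sat}]$ (or a generous upper bound for monotone families)
  to $10^{-8}$ absolute tolerance on irradiance otherwise. Absence of a
  crossing raises `lrc_no_compensation` instead of returning a guess.
* Nonlinear least squares uses the trust-region Levenberg–Marquardt
  implementation in `minpack.lm`, with deterministic data-driven starts:
  initial slope from an OLS line through the three lowest nonzero light
  steps, respiration from the dark observation, asymptote from the
  channel maximum, $\theta_0 = 0.5$, and $(\beta_0, \gamma_0)$ from the
  closed-form inversion applied to the observed maximum and its light
  step. No random restarts: a fit is a pure function of the data.
* Box bounds keep estimates physical and wide enough for all reference
  values: $\alpha \in (0,1]$, $\beta \in [0, 10^{-2}]$,
  $\gamma \in (0, 10^{-1}]$, $\theta \in (10^{-3}, 1]$,
  $R_d \in [0, 20]$.
* Tie-break: a fitted down-regulation coefficient below $10^{-8}$ (three
  orders below any observed value) is reported as $\beta = 0$, i.e. a
  monotone channel with no finite saturation, rather than an enormous
  pseudo-saturation irradiance.
* $R^2 = 1 - SSE/SST$ with centred SST; MAE is the mean absolute
  residual; AIC is the Gaussian-likelihood variant
  $n\ln(SSE/n) + 2(k+1)$. Since instruments and software differ in
  their AIC constant, only AIC *differences within one dataset* are
  interpreted, and the package asserts ranking, never absolute AIC
  values.
* Replicate aggregation defaults to per-replicate fits summarised as
  mean ± SE ($SE = SD/\sqrt{n}$), and *derived traits are computed per
  replicate and then averaged*. This mean-of-ratios convention is
  deliberate: nonlinear trait means (e.g. $I_c$, $n_a = J_{max}/P_{nmax}$)
  computed from averaged parameters do not equal averaged per-replicate
  traits, and replicate-level reporting is what field studies tabulate.
  A pooled mode is available.

## Fitted-vs-measured comparison

`empirical_traits()` estimates traits without a model: per-replicate
channel maximum, the protocol step at which it occurs, the dark value,
and the compensation point by linear interpolation between the adjacent
steps where the response crosses zero. `compare_models()` reports each
family's percent deviation from these, and
`anova_fitted_vs_measured()` runs a one-way ANOVA ($\alpha = 0.05$) with
Tukey-HSD compact letters. The post-hoc choice is ours; any method that
merges statistically indistinguishable groups gives the same letters in
the regimes the package targets.

## Efficiency channels

`derive_channels()` computes, row-wise: LUE $= P_n/I$ (mol mol⁻¹,
undefined in darkness), CE $= P_n/C_i$ (mol m⁻² s⁻¹), WUE$_i$
$= P_n/g_s$ (μmol mol⁻¹), WUE$_{inst}$ $= P_n/T_r$ (μmol CO₂ per mmol
H₂O — note the per-mmol convention). Their light responses are fitted
with members of the same rational-function kernel:

* rising–saturating $a(1-\beta I)I/(1+\gamma I) - c$ for NPQ (with
  $c = 0$: quenching is zero in darkness) and for CE/WUE channels (free
  intercept, because net assimilation is negative at low light);
* monotone decreasing $\phi_{max}(1-\beta I)/(1+\gamma I)$ for
  Φ_PSII, whose maximum is the dark value;
* LUE is *not* refitted: it is the fitted $P_n$ curve divided by $I$,
  with the peak location from the closed form
  $1/I^\ast = \sqrt{\alpha(\beta+\gamma)/R_d} - \gamma$ (LUE peaks at
  low light only because respiration penalises low irradiance;
  $R_d = 0$ pushes the optimum to the dark limit).

These derivative forms are reconstructions: the originating efficiency
models are not re-derived here, and the forms were chosen to reproduce
the trait structure practitioners report (finite maximum plus
saturation irradiance; nonzero dark PSII efficiency). They are validated
against trait tables and numeric argmax checks, not against any
particular published curve shape.

## Pigment photophysics

* `n0_from_chlorophyll()`: $N_0 = \text{Chl}\cdot 10^{-3}/M \cdot N_A
  \cdot S$ with molar mass $M = 900.5$ g mol⁻¹ (mean of chlorophyll a,
  893.5, and b, 907.5) and chamber area $S = 2$ cm² by default — the
  standard constants that make the reference chlorophyll content
  (707.34 mg m⁻²) correspond to the reference pool size
  ($9.46\times10^{16}$). Both are configurable; the pool is interpreted
  as a molecule count for the measured area.
* `sigma_ik_from_alpha_e()`: the $J$–$I$ initial slope aggregates
  $\alpha_e = (\alpha'\beta'\varphi)\,\sigma_{ik}\,N_0/S$; the bundled
  optical product defaults to a calibration constant $k = 0.379$, which
  maps the reference slope onto the reference cross-section and implies
  a plausible leaf absorption optical depth
  ($\sigma_{ik} N_0/S \approx 0.90$). It is a calibration, not a
  derivation, and is exposed as an argument.
* `effective_cross_section()`: $\sigma'_{ik}(I) = \sigma_{ik}
  (1-\beta_e I)/(1+\gamma_e I)$ — the same down-regulation kernel as the
  electron-transport response, equal to $\sigma_{ik}$ in darkness and
  strictly decreasing (73.8% down at $I = 2000$ for the reference
  coefficients). Beyond $1/\beta_e$ the antenna is reported as fully
  down-regulated (0, with a warning).
* `excited_state_pool()`: steady-state two-level pumping with
  ground-state depletion, $x = \sigma_{ik}\Phi(I)\tau$,
  $N_k = N_0\, x/(1+x)$, with photon flux
  $\Phi(I) = I\cdot10^{-6}N_A$. This is the simplest kinetics
  consistent with a monotone, saturating excited-state pool; it ignores
  annihilation and multi-level structure.
* The excited-state lifetime $\tau$ is an *input* (default 11.53 ms,
  the reference minimum): extracting it requires fluorescence kinetics
  outside a light-curve experiment's reach.

## The synthetic-data generator

`simulation_config()`/`simulate_dataset()` emulate a replicate-structured
light-curve experiment: the 16-step descending protocol, 4 replicates,
channel means from the forward models, additive Gaussian noise per
channel, and lognormal replicate-level parameter jitter (CV 5% by
default) — replicate heterogeneity is real in field data, which is why
mean-of-ratios and ratio-of-means trait summaries disagree.

Generator defaults are the reference study conditions: $P_n$ and $J$
coefficients from closed-form inversion of the reference fitted traits;
NPQ from the rising–saturating family anchored at the reference maximum
(1.366) and saturation irradiance (2278.76), with initial slope 0.0015
chosen to give a realistic dark-adjacent rise; noise SDs
(P$_n$ 0.3, $J$ 2, Φ_PSII 0.01, NPQ 0.03, $g_s$ 0.02, $T_r$ 0.3, $C_i$
5, channel units) set so fitted-trait SEs land in the range reference
tables report.

Coupled channels are derived, not independently drawn: Φ_PSII from the
fluorometer identity $J = \Phi_{PSII}\, I \cdot 0.5 \cdot a$ with leaf
absorptance $a = 0.84$ (the common instrument default; the factor is a
convention, not a measurement); stomatal conductance rises with a
Michaelis form $g_s = g_{min} + (g_{max}-g_{min})\,I/(I+K)$
($0.15$–$0.55$ mol m⁻² s⁻¹, $K = 300$); transpiration proportional to
conductance (23.4 mmol mol⁻¹, bundling the vapour-pressure gradient);
and $C_i = C_a - P_n/(g_s/1.6)$ at chamber CO₂ 390 μmol mol⁻¹. One
consequence worth knowing: the generator enforces the fluorometer
identity exactly, so its dark-extrapolated Φ_PSII equals
$\alpha_e/(0.5a) \approx 0.82$ rather than a typical measured dark
value near 0.76–0.79 — published Φ_PSII and $J$ columns are not exactly
consistent with a single absorptance constant, and the generator
resolves that tension in favour of the identity.

What the generator does **not** emulate: autocorrelated drift within a
curve, heteroscedastic noise (variance growing with signal),
temperature/VPD fluctuation, stomatal patchiness, or induction effects
at the first light steps. Passing recovery tests on this generator
therefore demonstrates estimator correctness under the stated error
model, not robustness to every instrument pathology.

## Simulation-study sizes and a known identifiability limit

The packaged studies use 200 simulated experiments for parameter
recovery and 100 for model selection — enough for stable medians and
selection frequencies while keeping the whole suite fast on one CPU.

A genuine limitation surfaces there: with the reference $P_n$
coefficients, the saturation irradiance (≈2520) lies *above* the top of
the 16-step protocol (2400), so the downturn that identifies $\beta$ is
never observed. Under the default noise level, the median relative
error of $\hat\beta$ across 200 experiments is ≈5%, several times the
error of $\hat\alpha$ (≈1.4%), while derived traits remain accurate
(maximum ≈0.4%, saturation irradiance ≈2.3%) because their closed forms
are dominated by the better-identified aggregates. Anyone designing a
light-curve protocol for photoinhibition inference should extend the
gradient beyond the expected saturation irradiance; the electron
transport channel (saturating near 1700) does not suffer from this.

## Reference values and scope

`reference_traits()` ships the published water-hyacinth trait set used
for defaults and worked examples; `cross_species_reference()` is a
static context table of photosynthetic capacity across aquatic and crop
species. The package deliberately does not model: FvCB biochemical
coupling, temperature or CO₂ response surfaces, mechanistic stomatal
models, respiration-in-the-light estimation (no closed form exists in
this framework), weighted or heteroscedastic regression, or bootstrap
confidence intervals.
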