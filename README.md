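# lrcfit

Fitting and comparison of photosynthetic light-response curves, with a
mechanistic model family that represents photoinhibition explicitly.

## The problem

A light-response experiment steps a leaf through an irradiance gradient
(here the common 16-step protocol, 2400 down to 0 μmol photons m⁻² s⁻¹)
while a gas-exchange system with a chamber fluorometer records net CO₂
assimilation (*P*ₙ), electron transport rate (*J*), PSII operating
efficiency (Φ_PSII), non-photochemical quenching (*NPQ*), stomatal
conductance, transpiration and intercellular CO₂. Ecophysiologists
summarise such curves by a handful of traits — maximum net rate
*P*ₙₘₐₓ, saturation irradiance *I*_sat, light compensation point *I*_c,
dark respiration *R*_d, maximum electron transport *J*ₘₐₓ — and those
traits depend strongly on which model produced them.

`lrcfit` implements the three families in routine use and everything
needed to compare them honestly:

* **Rectangular hyperbola (RH)**
  *P*ₙ = α *I* *P*ₘ / (α *I* + *P*ₘ) − *R*_d
* **Non-rectangular hyperbola (NRH)** — the smaller root of
  θ *P*² − (α *I* + *P*ₘ) *P* + α *I* *P*ₘ = 0, minus *R*_d, with
  convexity θ ∈ (0, 1]
* **Mechanistic family with photoinhibition**
  *P*ₙ = α (1 − β *I*) *I* / (1 + γ *I*) − *R*_d, where β is the
  photoinhibition/down-regulation coefficient and γ the saturation
  coefficient. Unlike the hyperbolas this family has a finite interior
  maximum with closed forms for the maximum, the saturation irradiance
  *I*_sat = (√((β+γ)/β) − 1)/γ, and the quantum efficiency
  d*P*ₙ/d*I* = α (1 − 2β*I* − βγ*I*²)/(1 + γ*I*)².

The same rational-function kernel links the leaf-level curve to pigment
photophysics: the pigment pool size *N*₀ from chlorophyll content, the
eigen absorption cross-section σ_ik from the *J–I* initial slope, the
light-dependent effective cross-section σ′_ik(I), and the excited-state
pigment pool *N*_k(I) from steady-state two-level pumping. Derived
efficiency channels (light-use, carboxylation, intrinsic and
instantaneous water-use efficiency, *NPQ*, Φ_PSII) are computed and
fitted with the matching family members.

The package ships a published reference trait set for water hyacinth
(*Pontederia crassipes*), used as generator defaults and in the worked
examples, plus a replicate-structured synthetic-data generator so every
stage is testable without instrument data.

## Worked example

Recover the mechanistic coefficients from published traits (initial
slope 0.0528, *P*ₙₘₐₓ 24.64 μmol m⁻² s⁻¹ at *I*_sat 2520.41 μmol
photons m⁻² s⁻¹, *R*_d 3.46) by exact closed-form inversion:

```r
library(lrcfit)
tr <- reference_traits()
pn <- invert_ye(tr$pn$alpha, tr$pn$pn_max, tr$pn$i_sat, offset = tr$pn$rd)
pn
#> Light-response parameters: mechanistic (photoinhibition) family
#>   alpha = 0.0528
#>   beta = 8.3778e-05
#>   gamma = 0.00108548
#>   offset = 3.46
light_compensation(pn)
#> [1] 71.00327
```

Simulate a 4-replicate experiment under the reference conditions and
compare all three families:

```r
d <- simulate_dataset(simulation_config(seed = 42))
compare_models(d, "pn")
#> Model comparison on channel `pn` (ranked by AIC):
#>  model r_squared     mae     aic max_fitted pct_dev_max
#>     ye   0.99911 0.24195 -29.993     25.526    0.061919
#>    nrh   0.99871 0.29919 -22.964     33.637   31.857000
#>     rh   0.99767 0.40296 -15.528     37.394   46.582000
```

The mechanistic family ranks first by AIC and tracks the observed
maximum (+0.06%), while the hyperbolic families overestimate it by
32–47% — they can only approach a plateau from below, so their
asymptote must exceed any observed maximum of a photoinhibited curve.

Pigment photophysics from the electron-transport fit and chlorophyll
content:

```r
jp <- invert_ye(tr$j$alpha, tr$j$j_max, tr$j$i_sat)
pigment_traits(jp, chl = 707.34)
#> Light-harvesting pigment traits:
#>   N_0      = 9.46e+16 molecules (707.3 mg m^-2 chlorophyll over 0.0002 m^2)
#>   sigma_ik = 1.91e-21 m^2
#>   tau      = 0.0115 s
#>   at I = 2400: sigma_eff = 4e-22 m^2 (21.0% of sigma_ik), N_k = 2.92e+15
```

So a leaf holding ~9.5 × 10¹⁶ pigment molecules in the 2 cm² chamber
window cuts its effective absorption cross-section to about a fifth of
the dark value at the top of the light gradient while the excited-state
pool keeps rising — photoprotection by antenna down-regulation rather
than absorption collapse.

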