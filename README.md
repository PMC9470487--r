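# elytherm

Radiative heating and spectral optics of beetle elytra.

Beetle elytra are the main sun-exposed surface of the animal, and their
optical properties — how much visible (VIS, 400–700 nm) and near-infrared
(NIR, 700–1700 nm) light they reflect, transmit and absorb — control how
fast the beetle gains radiative heat. `elytherm` is for researchers running
(or re-analysing) solar-simulator heating experiments on insect cuticle:
it turns per-specimen reflectance/transmittance spectra and thermocouple
traces into band-weighted optical scalars, heating-curve features, and the
statistical models that connect them while controlling for body size.

## What it computes

**Band-weighted optics.** For each band, the fraction of incident source
energy reflected (reflectivity *R*) or transmitted (transmissivity *T*):

    R = ∫ I(λ) F(λ) E(λ) dλ / ∫ I(λ) F(λ) dλ        A = 100 − (T + R)

with *I* the source irradiance, *F* the illumination filter, *E*/*S* the
measured reflectance/transmittance spectra, and absorptivity *A* closing
the energy budget. Integrals are evaluated exactly on the piecewise-linear
interpolants over a common 1-nm grid.

**Heating metrics.** Thermocouple traces are segmented into the
illumination/cooling cycle (initial cooling, TOTAL, cooling, NIR, cooling,
VIS, cooling) and each illumination phase yields ΔT₅ (temperature change
over 5 min from onset) and maxHR (maximum slope between adjacent 20-s
samples, °C/s).

**Statistics.** OLS heating models `ΔT₅ (or maxHR) ~ absorptivity + size
+ side` with extra-sum-of-squares partial R²; Pearson correlations with
Fisher-z intervals; Gaussian repeatability (intraclass correlation) with
parametric-bootstrap CIs and a boundary-corrected likelihood-ratio test;
and a paired percentile bootstrap for the elytra-open vs elytra-closed
body-heating difference D_ΔT.

**Synthetic data.** A generator produces realistic spectra (four optical
archetypes of scarab elytra), lumped-capacitance heating traces
(T(t) = T_air + ΔT∞(1 − e^(−t/τ)), ΔT∞ = (A/100)·I·S/h), full 56-specimen
cohorts and paired body datasets — all seeded, with ground truth recorded,
so every stage runs and is testable without instrument data.

## Worked example

```r
library(elytherm)

# a gold-metallic elytron: broadband reflectance rising into the NIR
es <- gen_spectrum_family("broadband_metallic", seed = 42)
ir <- solar_simulator_irradiance()   # smooth 0.5-Sun-class stand-in
summarize_optics(list(list(id = "metallic_gold", E = es$E, S = es$S)), ir)
#>     specimen_id  band reflectivity_R transmissivity_T absorptivity_A qc_flags
#> 1 metallic_gold   VIS           33.7             1.82           64.4
#> 2 metallic_gold   NIR           72.9             4.13           23.0
#> 3 metallic_gold TOTAL           54.6             3.05           42.4

# heat it for 5 minutes under 450 W/m^2 reaching a 2.4-cm elytron
p <- heat_sim_params(absorptivity_A = 42.4, area_m2 = elytron_area(2.4),
                     irradiance_W_m2 = 450)
tr <- simulate_heating_trace(p, duration_s = 300, seed = 42)
delta_t5(tr); max_heating_rate(tr)
#> dT5 = 1.83 degC, maxHR = 0.0193 degC/s  (steady state dT_inf = 1.90 degC)
```

The optics rows say this specimen reflects 73 % of NIR but only 34 % of
VIS source energy, so it absorbs far more in VIS (64 %) than NIR (23 %) —
the typical metallic-scarab pattern. Driving the heat balance with the
TOTAL-band absorptivity, the elytron warms 1.8 °C in 5 min and is already
near its steady state, as the heating curve's saturation implies.

The full pipeline (optics table, heating table, six heating models,
correlation table, repeatability, paired test) runs from one call:

```r
gen_cohort(n_species = 28, seed = 42, dir = "cohort")
res <- run_full_analysis(run_config("cohort", "results", seed = 42))
res$models   # Table of coefficients with partial R^2 per response x band
```

or from the shell via `Rscript inst/cli/elytherm.R all --in cohort
--out results --seed 42`.

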