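---
title: "Band-weighted optics and radiative heating of beetle elytra: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-weighted optics and radiative heating of beetle elytra: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elytherm)
```

## The scientific problem

Beetle elytra are the largest sun-exposed surface of most beetles, and
their interaction with sunlight — how much they reflect, transmit and
absorb across the visible (VIS, 400–700 nm) and near-infrared (NIR,
700–1700 nm) bands — sets how much radiative heat the animal gains.
`elytherm` implements the full analysis chain for experiments that
illuminate elytra (or whole bodies) with a solar simulator inside a
convection-controlled chamber and log their temperature with
thermocouples: band-weighted scalar optics from measured spectra,
heating-curve feature extraction, and the statistical models linking the
two while controlling for body size.

## Band-weighted optical properties

A reflectance spectrum $E(\lambda)$ (percent against a white standard)
or transmittance spectrum $S(\lambda)$ is reduced to a scalar per band
by weighting with the source irradiance $I(\lambda)$ and the filter
transmittance $F(\lambda)$ of the illumination condition:

$$R = \frac{\int I(\lambda)\,F(\lambda)\,E(\lambda)\,d\lambda}
           {\int I(\lambda)\,F(\lambda)\,d\lambda},\qquad
  T = \frac{\int I(\lambda)\,F(\lambda)\,S(\lambda)\,d\lambda}
           {\int I(\lambda)\,F(\lambda)\,d\lambda},\qquad
  A = 100 - (T + R).$$

$R$ (reflectivity) and $T$ (transmissivity) are therefore the fractions
of the *incident source energy* reflected/transmitted in the band, and
$A$ (absorptivity) closes the energy budget. Three bands are built in:
VIS 400–700, NIR 700–1700 and TOTAL 400–1700 nm; TOTAL uses a flat
100 % "filter" (the uncovered chamber portal), VIS and NIR use band-pass
filter curves, which are ordinary spectra and can be replaced by
measured ones.

### Numerical choices

* **Quadrature.** All spectra are linearly interpolated onto a common
  1-nm grid across the band, and the integrals of the resulting
  piecewise-linear representation are evaluated *exactly*: within each
  grid interval the product of up to three linear factors is a cubic,
  which a per-interval Simpson rule integrates without error. This
  removes the $O(h^2)$ bias that trapezoid-of-the-product quadrature
  would leave, so results agree with brute-force fine-grid Riemann sums
  to well below $10^{-6}$ percentage points, and band values are exactly
  additive across a band partition (TOTAL is exactly the
  incident-energy-weighted mean of VIS and NIR under a common filter).
* **Filter edges** are represented as data points (e.g. 100 % at 700 nm,
  0 % at 701 nm) and receive no special treatment beyond interpolation.
* **No extrapolation.** Resampling outside a spectrum's support is an
  error; UV below 400 nm is excluded by construction.
* **Out-of-range values.** Raw instrument spectra can stray outside
  [0, 100] %; such values (and any resulting $A \notin [0,100]$) are
  kept and flagged (`value_outside_0_100`, `out_of_physical_range`),
  never silently clamped, so instrument artifacts stay visible in QC.
* **Duplicate wavelengths** in input files are collapsed to their mean
  with a warning.
* **Irradiance.** The shipped `solar_simulator_irradiance()` is a
  smooth synthetic stand-in (a 5800-K Planck curve scaled to
  450 W m⁻² over 400–1700 nm, i.e. the in-band share of a 0.5-Sun
  source); substitute the manufacturer's lamp table via
  `read_spectrum(..., kind = "I")` for real instruments. Because the
  "share of solar energy in a band" depends on both the spectrum and
  the denominator range, `band_energy_fraction()` exposes both as
  explicit arguments rather than hard-coding a convention.

## Heating metrics

Trials follow an alternating cycle — initial cooling, TOTAL, cooling,
NIR, cooling, VIS, cooling — of nominally 5-min phases, logged every
20 s. Two features are extracted per illumination phase:

* $\Delta T_5$: temperature change from phase onset to onset + 300 s.
  The onset is the phase's first sample (default); if no sample falls
  within 1 s of the 300-s mark the value there is linearly interpolated
  (robustness to logger jitter). An alternative baseline — the mean of
  the last 60 s of the preceding cooling plateau — is available as
  `baseline = "precool"`, since published analyses rarely state which
  reference they used; the onset rule is the default because it needs
  no assumption about how completely the sample re-cooled.
* maxHR: the maximum slope between *adjacent raw samples*,
  $(T_{i+1}-T_i)/(t_{i+1}-t_i)$, using actual timestamp gaps. No
  smoothing is applied — deliberately, because the low repeatability of
  maxHR is itself a finding about fine-scale derivatives of noisy
  traces, and smoothing would hide it. For a monotone cooling slice the
  (negative) maximum slope is still returned.

A sample lying exactly on a phase boundary belongs to the later phase
(it is that phase's onset) while also closing the earlier slice, so
every illumination slice spans its full 300 s. Chamber and water-jacket
channels can be screened with `check_reference_channel()` (flagging
peak-to-peak drift > 0.5 °C).

Because $\Delta T_5 / 300$ is the mean of the adjacent-sample slopes
over a 300-s phase, maxHR ≥ $\Delta T_5/300$ holds for every slice —
a useful invariant that the tests exercise on thousands of simulated
traces.

## Statistics

* **Heating models.** `fit_heating_model()` fits the additive OLS model
  `response ~ absorptivity + size + side` (no interactions: under even
  illumination, absorbed power is additive in absorptivity and exposed
  area). Partial $R^2$ of each term is the extra sum of squares when the
  term is dropped from the full model, over the total sum of squares;
  these add up to the overall $R^2$ only under orthogonal predictors,
  which is documented rather than forced. Side is a two-level fixed
  effect (reference `left`). Residual normality is summarised via
  Shapiro–Wilk. Rank-deficient designs fail loudly, naming the
  collinear terms.
* **Pearson correlations** use the product-moment estimate with a
  Fisher-z 95 % interval and a t-based two-sided p-value; perfectly
  collinear input returns a degenerate flagged interval.
* **Repeatability** is the intraclass correlation of a Gaussian
  random-intercept model, $R = \sigma^2_{group} / (\sigma^2_{group} +
  \sigma^2_{res})$. The point estimate comes from a REML fit (lme4) with
  tight optimizer tolerances — on balanced data this coincides with the
  closed-form ANOVA estimator to ~10⁻⁸, which the tests verify. The
  95 % CI is a percentile parametric bootstrap (simulate from the
  fitted model, refit; default 1000 draws). The LRT p-value for
  $\sigma^2_{group}=0$ uses ML fits and the boundary-corrected null
  $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$; note that under this null the
  p-value is *sub*-uniform with an atom above 0.5, so its validity is
  checked through its type-I error rate, not a uniformity test.
  Singleton groups are dropped with a warning.
* **Paired bootstrap.** For individuals measured with elytra closed and
  open, $D_i = \Delta T_5^{closed} - \Delta T_5^{open}$; the individuals
  are resampled with replacement (default 10 000 times) and the
  2.5/97.5 percentile interval of the mean reported. Negative intervals
  excluding zero mean the body heats more when the elytra are *not*
  covering it. A caveat the package states rather than hides: at
  n = 11 the plain percentile interval's true coverage is ≈ 0.91, not
  0.95 — the classic small-sample undercoverage of percentile
  bootstraps — which matters when interpreting borderline intervals.
* No multiple-testing correction and no phylogenetic correction are
  applied, matching the experimental logic the pipeline supports
  (physical, not comparative-evolutionary, inference); both choices are
  deliberate and documented here.

## The synthetic-data generator

The generator exists so every stage runs and is testable without
instrument data; it emulates the *structure* the analysis assumes, not
any particular beetle.

* **Spectra.** Four archetypes at 1-nm resolution (broadband metallic,
  narrowband green, melanin brown, high-NIR transmitter) span VIS
  reflectivities of roughly 5–30 % and NIR reflectivities of 25–90 %,
  with NIR transmissivities up to ~60 % — the ranges seen across
  optically diverse scarabs. Pointwise $E + S \le 100$ is enforced
  (impossible parameter sets are refused before generation), Gaussian
  measurement noise (default 1 %) is added afterwards. Species share an
  archetype with species-level amplitude jitter; conspecific specimens
  add smaller individual jitter.
* **Traces.** Single-compartment (lumped-capacitance) heat balance:
  $T(t) = T_{air} + \Delta T_\infty (1 - e^{-t/\tau})$ with
  $\Delta T_\infty = (A/100)\,I\,S/h$, sampled analytically (no
  integrator error) every 20 s with thermocouple noise (default
  0.05 °C, which realistically degrades maxHR repeatability more than
  $\Delta T_5$). Defaults $h = 0.025$ W/°C and $\tau = 75$ s are
  calibrated so that a 0.5-Sun source on 1.6–3 cm elytra plateaus
  within 5 min with $\Delta T_5$ spanning roughly 0.7–5.3 °C. The
  exposed area comes from length through a fixed elliptical shape
  factor (aspect 0.55), reflecting the conserved shape of these
  beetles. Per-band incident power is the integral of the (filtered)
  irradiance over the band, so TOTAL, NIR and VIS phases each drive the
  trace with their own $\Delta T_\infty$ through the 7-phase cycle.
* **Cohort.** Default 28 species × 2 specimens (56), lengths
  species-structured within 1.6–3 cm, platform side alternating. A
  `ground_truth.json` records every generating parameter so tests can
  check end-to-end recovery: the pipeline's absorptivity estimates
  reproduce the generator's (both use the same band integrals — an
  internal consistency check), $\Delta T_5$ always falls short of
  $\Delta T_\infty$ (finite exposure), and the fitted
  absorptivity-slope of the $\Delta T_5$ model matches
  $(I\,\bar S/100h)(1-e^{-300/\tau})$.
* **What it does not emulate:** iridescence/BRDF structure, spectral
  autocorrelation of real instrument noise, chamber convection
  transients, conduction through the mount, mid/long-wave emissivity.
  Passing tests on synthetic data therefore validate the *pipeline's
  arithmetic and statistics*, not any biological claim about real
  specimens.

## Problem sizes and determinism

Every stochastic routine takes an explicit integer seed and is
bit-for-bit reproducible under it; pipeline reruns with the same config
and seed produce byte-identical CSVs. The validation suite runs the
quadrature oracle on 10 random fixtures, the heating contracts on 1000
simulated traces, ICC recovery on 3 × 200 Monte-Carlo datasets of 30
groups × 10 observations, and bootstrap coverage on 1000 paired
datasets of 11 individuals — sizes chosen to pin each property with
comfortable statistical margin on a single CPU.

## Known limitations

* The additive heating model is a first-order description of a
  response that physically scales with the absorptivity × area product;
  its absorptivity coefficient equals the analytic slope only to within
  the chance absorptivity–size correlation of a finite cohort.
* Percentile bootstrap intervals undercover at very small n (see
  above); with n ≈ 11 a reported "95 %" interval is closer to 91 %.
* Hemispherical-vs-directional reflectance geometry, UV (< 400 nm) and
  heat dissipation in the thermal infrared are out of scope.
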