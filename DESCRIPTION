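Package: elytherm
Title: Radiative Heating and Spectral Optics of Beetle Elytra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how the optical properties of beetle elytra
    (band-weighted reflectivity, transmissivity and absorptivity over the
    visible and near-infrared solar spectrum) together with body size predict
    radiative heating. Implements irradiance-and-filter-weighted spectral band
    integration, segmentation of thermocouple traces into illumination and
    cooling phases with extraction of the 5-minute temperature change and the
    maximum heating rate, linear heating models with extra-sum-of-squares
    partial R-squared, Pearson correlations with Fisher-z intervals, Gaussian
    repeatability (intraclass correlation) with parametric-bootstrap
    confidence intervals and a boundary-corrected likelihood-ratio test, and a
    paired-bootstrap test for the insulating effect of elytra on body heating.
    A synthetic-data module generates reflectance and transmittance spectra
    and lumped-capacitance heating traces with known ground truth so the whole
    pipeline can be exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
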