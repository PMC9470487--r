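#' Synthetic reflectance/transmittance spectrum families
#'
#' Generates paired reflectance (E) and transmittance (S) spectra at 1-nm
#' resolution over 400-1700 nm, emulating the optical archetypes seen in
#' Christmas beetle elytra: `broadband_metallic` (gold/silver sheen: high,
#' broadband reflectance rising into the NIR), `narrowband_green` (a
#' structural-colour peak near 550 nm over a dark base, moderate NIR),
#' `melanin_brown` (reflectance rising monotonically with wavelength, as
#' for melanised cuticle) and `high_NIR_transmitter` (dark, thin elytra
#' passing much of the NIR). Smooth shapes are checked to satisfy
#' E + S <= 100 pointwise before any noise is added; measurement noise is
#' then applied and the pointwise constraint re-imposed.
#'
#' @param family one of `"broadband_metallic"`, `"narrowband_green"`,
#'   `"melanin_brown"`, `"high_NIR_transmitter"`.
#' @param amplitude main reflectance amplitude in percent (family default
#'   if `NULL`).
#' @param baseline baseline reflectance in percent.
#' @param edge_nm edge/centre wavelength of the main feature in nm.
#' @param trans_amplitude transmittance amplitude in percent.
#' @param noise_sd Gaussian measurement noise sd in percent (default 1).
#' @param seed integer seed for the noise realisation.
#' @param label label prefix for the spectra.
#' @return A list with `E` and `S`, both `elytherm_spectrum` on 400-1700 nm.
#' @export
gen_spectrum_family <- function(family = c("broadband_metallic",
                                           "narrowband_green",
                                           "melanin_brown",
                                           "high_NIR_transmitter"),
                                amplitude = NULL, baseline = NULL,
                                edge_nm = NULL, trans_amplitude = NULL,
                                noise_sd = 1, seed = 1L, label = family) {
  family <- match.arg(family)
  wl <- 400:1700
  logistic <- function(x) 1 / (1 + exp(-x))
  defaults <- switch(family,
    broadband_metallic = list(amplitude = 65, baseline = 12, edge_nm = 620,
                              trans_amplitude = 6),
    narrowband_green = list(amplitude = 22, baseline = 5, edge_nm = 550,
                            trans_amplitude = 12),
    melanin_brown = list(amplitude = 45, baseline = 6, edge_nm = 700,
                         trans_amplitude = 22),
    high_NIR_transmitter = list(amplitude = 14, baseline = 8, edge_nm = 800,
                                trans_amplitude = 52))
  amplitude <- amplitude %||% defaults$amplitude
  baseline <- baseline %||% defaults$baseline
  edge_nm <- edge_nm %||% defaults$edge_nm
  trans_amplitude <- trans_amplitude %||% defaults$trans_amplitude

  E <- switch(family,
    broadband_metallic = baseline + amplitude * logistic((wl - edge_nm) / 90),
    narrowband_green = baseline +
      amplitude * exp(-((wl - edge_nm) / 45)^2) +
      0.45 * amplitude * logistic((wl - 780) / 120),
    melanin_brown = baseline + amplitude * (1 - exp(-(wl - 400) / 650)),
    high_NIR_transmitter = baseline + amplitude * logistic((wl - edge_nm) / 200))
  S <- switch(family,
    broadband_metallic = 1 + trans_amplitude * logistic((wl - 1000) / 250),
    narrowband_green = 1 + trans_amplitude * logistic((wl - 900) / 220),
    melanin_brown = 1 + trans_amplitude * logistic((wl - 850) / 250),
    high_NIR_transmitter = 2 + trans_amplitude * logistic((wl - 800) / 180))
  if (max(E + S) > 100) {
    stop(sprintf(
      "family parameters imply E + S > 100 (max %.1f); reduce amplitudes",
      max(E + S)), call. = FALSE)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    E <- E + stats::rnorm(length(wl), 0, noise_sd)
    S <- S + stats::rnorm(length(wl), 0, noise_sd)
  }
  E <- pmax(E, 0); S <- pmax(S, 0)
  over <- (E + S) > 100
  if (any(over)) {  # noise can nudge the sum past 100; rescale those points
    sc <- 100 / (E[over] + S[over])
    E[over] <- E[over] * sc
    S[over] <- S[over] * sc
  }
  list(E = spectrum_data(wl, E, kind = "E", label = paste0(label, " E")),
       S = spectrum_data(wl, S, kind = "S", label = paste0(label, " S")))
}

#' Exposed elytron area from body length
#'
#' Elytra in this group are conserved in shape, so length is a good proxy
#' for exposed area; the projected area is modelled as an ellipse with a
#' fixed width:length aspect ratio.
#'
#' @param length_cm body/elytron length in cm.
#' @param aspect width-to-length aspect ratio (default 0.55).
#' @return Projected area in m^2.
#' @export
elytron_area <- function(length_cm, aspect = 0.55) {
  L <- length_cm / 100
  pi * (L / 2) * (aspect * L / 2)
}

#' Default lumped-capacitance heating parameters
#'
#' One-compartment heat balance: an object with heat capacity `C` (J/degC)
#' absorbing `(A/100) * I * S` watts and losing `h * (T - T_air)` watts
#' gives `T(t) = T_air + dT_inf * (1 - exp(-t / tau))` with
#' `dT_inf = (A/100) * I * S / h` and `tau = C / h`. Defaults are chosen so
#' synthetic elytra plateau within 5 minutes and span the 0.7-5.3 degC
#' 5-min temperature changes typical of half-Sun illumination of elytra of
#' 1.6-3 cm beetles: `h = 0.025` W/degC and `tau = 75` s.
#'
#' @param absorptivity_A band absorptivity in percent.
#' @param irradiance_W_m2 incident energy density in W/m^2 reaching the
#'   sample in the active band (500 = 0.5 Sun full spectrum).
#' @param area_m2 exposed area in m^2 (see [elytron_area()]).
#' @param conductance_h total heat-loss conductance in W/degC.
#' @param heat_capacity_C lumped heat capacity in J/degC.
#' @param air_temp_C chamber air temperature in degC.
#' @param dt_sample_s sampling interval in s (default 20, the logger rate).
#' @param noise_sd_C thermocouple noise sd in degC (default 0.05).
#' @return A list of class `heat_sim_params`.
#' @export
heat_sim_params <- function(absorptivity_A, irradiance_W_m2 = 500,
                            area_m2 = elytron_area(2.3),
                            conductance_h = 0.025,
                            heat_capacity_C = 0.025 * 75,
                            air_temp_C = 20, dt_sample_s = 20,
                            noise_sd_C = 0.05) {
  if (conductance_h <= 0 || heat_capacity_C <= 0) {
    stop("conductance and heat capacity must be positive", call. = FALSE)
  }
  if (irradiance_W_m2 < 0 || area_m2 <= 0) {
    stop("irradiance must be >= 0 and area > 0", call. = FALSE)
  }
  structure(list(absorptivity_A = absorptivity_A,
                 irradiance_W_m2 = irradiance_W_m2, area_m2 = area_m2,
                 conductance_h = conductance_h,
                 heat_capacity_C = heat_capacity_C,
                 air_temp_C = air_temp_C, dt_sample_s = dt_sample_s,
                 noise_sd_C = noise_sd_C),
            class = "heat_sim_params")
}

#' @rdname heat_sim_params
#' @param params a `heat_sim_params`.
#' @export
steady_state_excess <- function(params) {
  with(params, (absorptivity_A / 100) * irradiance_W_m2 * area_m2 /
                 conductance_h)
}

#' Simulate a single-phase heating trace
#'
#' Samples the analytic lumped-capacitance solution
#' `T(t) = T_air + dT_inf * (1 - exp(-t / tau))` every `dt_sample_s`
#' seconds (no integrator error) and adds Gaussian thermocouple noise.
#'
#' @param params a [heat_sim_params()] object.
#' @param duration_s trace duration in seconds (>= 2 sampling intervals).
#' @param seed integer seed for the noise.
#' @param channel channel label.
#' @return An `elytherm_trace`.
#' @export
simulate_heating_trace <- function(params, duration_s = 300, seed = 1L,
                                   channel = "T1") {
  stopifnot(inherits(params, "heat_sim_params"))
  if (duration_s < 2 * params$dt_sample_s) {
    stop("duration must cover at least 2 sampling intervals", call. = FALSE)
  }
  t <- seq(0, duration_s, by = params$dt_sample_s)
  tau <- params$heat_capacity_C / params$conductance_h
  temp <- params$air_temp_C + steady_state_excess(params) * (1 - exp(-t / tau))
  if (params$noise_sd_C > 0) {
    set.seed(seed)
    temp <- temp + stats::rnorm(length(t), 0, params$noise_sd_C)
  }
  thermal_trace(t, temp, channel = channel)
}

#' Simulate a full 7-phase trial trace
#'
#' Piecewise lumped-capacitance dynamics through the canonical cycle
#' (initial cooling, TOTAL, cooling, NIR, cooling, VIS, cooling): during an
#' illumination phase the temperature relaxes towards
#' `T_air + dT_inf(band)`, during cooling towards `T_air`, each from the
#' temperature reached at the previous phase boundary.
#'
#' @param dT_inf_by_band named numeric: steady-state excess (degC) for
#'   `TOTAL`, `NIR`, `VIS`.
#' @param plan an `elytherm_plan` (default [canonical_trial_plan()]).
#' @param tau_s thermal time constant in s.
#' @param air_temp_C chamber temperature.
#' @param dt_sample_s sampling interval.
#' @param noise_sd_C thermocouple noise sd.
#' @param seed integer seed.
#' @param channel channel label.
#' @return An `elytherm_trace` spanning the plan.
#' @export
simulate_trial_trace <- function(dT_inf_by_band, plan = canonical_trial_plan(),
                                 tau_s = 75, air_temp_C = 20,
                                 dt_sample_s = 20, noise_sd_C = 0.05,
                                 seed = 1L, channel = "T1") {
  t <- seq(min(plan$start_s), max(plan$end_s), by = dt_sample_s)
  temp <- numeric(length(t))
  T_now <- air_temp_C
  for (i in seq_len(nrow(plan))) {
    tgt <- if (plan$label[[i]] == "COOL") air_temp_C
           else air_temp_C + dT_inf_by_band[[plan$label[[i]]]]
    sel <- t >= plan$start_s[[i]] - 1e-9 & t <= plan$end_s[[i]] + 1e-9
    temp[sel] <- tgt + (T_now - tgt) * exp(-(t[sel] - plan$start_s[[i]]) / tau_s)
    T_now <- tgt + (T_now - tgt) * exp(-(plan$end_s[[i]] - plan$start_s[[i]]) / tau_s)
  }
  if (noise_sd_C > 0) {
    set.seed(seed)
    temp <- temp + stats::rnorm(length(t), 0, noise_sd_C)
  }
  thermal_trace(t, temp, channel = channel)
}

#' Generate a synthetic specimen cohort with ground truth
#'
#' Builds a museum-style cohort (default 28 species x 2 specimens = 56):
#' per specimen a reflectance and a transmittance spectrum (families cycled
#' across species, with species-level and specimen-level parameter
#' jitter so that conspecifics resemble each other), a body length in
#' 1.6-3 cm (a species-level mean with small individual jitter, since
#' conspecifics share size), a platform side assigned alternately, and a
#' 7-phase trial trace driven by the specimen's band absorptivities
#' through the lumped-capacitance model. When `dir` is given, everything
#' is written in the file formats the pipeline consumes (per-specimen
#' spectra CSVs, trace CSVs, a trial-plan YAML, metadata CSV, irradiance
#' CSV) plus `ground_truth.json` with every generating parameter.
#'
#' @param n_species number of species (>= 2).
#' @param n_per_species specimens per species (default 2).
#' @param seed integer seed controlling every random draw.
#' @param dir optional output directory; created if missing.
#' @param noise_sd_C thermocouple noise sd (default 0.05 degC; use 0 for
#'   exact analytic checks).
#' @param spectral_noise_sd spectral noise sd in percent (default 1).
#' @param conductance_h,tau_s thermal parameters (see [heat_sim_params()]).
#' @param irradiance irradiance spectrum (default
#'   [solar_simulator_irradiance()]).
#' @return A list: `metadata` (data.frame), `specimens` (list of
#'   id/E/S), `traces` (named list of `elytherm_trace`), `plan`,
#'   `irradiance`, `ground_truth` (data.frame with per-specimen, per-band
#'   true absorptivity and steady-state excess), `params`.
#' @export
gen_cohort <- function(n_species = 28, n_per_species = 2, seed = 1L,
                       dir = NULL, noise_sd_C = 0.05, spectral_noise_sd = 1,
                       conductance_h = 0.025, tau_s = 75,
                       irradiance = solar_simulator_irradiance()) {
  if (n_species < 2L) stop("need at least 2 species", call. = FALSE)
  set.seed(seed)
  families <- c("broadband_metallic", "narrowband_green", "melanin_brown",
                "high_NIR_transmitter")
  bands <- default_bands()
  filters <- lapply(stats::setNames(names(bands), names(bands)), band_filter)
  # incident power reaching the sample in each illumination condition
  I_band <- vapply(names(bands), function(bn) {
    grid <- band_grid(bands[[bn]])
    iv <- spectrum_values(resample_spectrum(irradiance, grid))
    fv <- spectrum_values(resample_spectrum(filters[[bn]], grid)) / 100
    product_integral(grid, iv, fv)
  }, numeric(1))

  plan <- canonical_trial_plan()
  meta <- list(); specimens <- list(); traces <- list(); truth <- list()
  spec_i <- 0L
  for (sp in seq_len(n_species)) {
    family <- families[[(sp - 1L) %% length(families) + 1L]]
    # species-level jitter of the family archetype
    sp_amp <- stats::rnorm(1, 0, 4)
    sp_trans <- stats::rnorm(1, 0, 2)
    # conspecifics share body size: species mean with small individual jitter
    sp_length <- stats::runif(1, 1.7, 2.9)
    species_id <- sprintf("sp%02d", sp)
    for (k in seq_len(n_per_species)) {
      spec_i <- spec_i + 1L
      id <- sprintf("%s_ind%d", species_id, k)
      d <- switch(family,
        broadband_metallic = list(amplitude = 65, trans_amplitude = 6),
        narrowband_green = list(amplitude = 22, trans_amplitude = 12),
        melanin_brown = list(amplitude = 45, trans_amplitude = 22),
        high_NIR_transmitter = list(amplitude = 14, trans_amplitude = 52))
      amp <- max(3, d$amplitude + sp_amp + stats::rnorm(1, 0, 1.5))
      tra <- max(1, d$trans_amplitude + sp_trans + stats::rnorm(1, 0, 1))
      es <- gen_spectrum_family(family, amplitude = amp,
                                trans_amplitude = tra,
                                noise_sd = spectral_noise_sd,
                                seed = sample.int(2^30, 1), label = id)
      length_cm <- min(3.0, max(1.6, sp_length + stats::runif(1, -0.1, 0.1)))
      side <- if (spec_i %% 2L == 1L) "left" else "right"
      opt <- summarize_optics(list(list(id = id, E = es$E, S = es$S)),
                              irradiance, filters, bands)
      A_band <- stats::setNames(opt$absorptivity_A, opt$band)
      area <- elytron_area(length_cm)
      dT_inf <- (A_band / 100) * I_band[names(A_band)] * area / conductance_h
      tr <- simulate_trial_trace(dT_inf, plan, tau_s = tau_s,
                                 dt_sample_s = 20, noise_sd_C = noise_sd_C,
                                 seed = sample.int(2^30, 1), channel = "T1")
      meta[[spec_i]] <- data.frame(
        specimen_id = id, species = species_id, family = family,
        length_cm = length_cm, side = side, stringsAsFactors = FALSE)
      specimens[[spec_i]] <- list(id = id, E = es$E, S = es$S)
      traces[[id]] <- tr
      truth[[spec_i]] <- data.frame(
        specimen_id = id, band = names(dT_inf),
        true_absorptivity_A = unname(A_band[names(dT_inf)]),
        incident_W_m2 = unname(I_band[names(dT_inf)]),
        dT_inf_C = unname(dT_inf), area_m2 = area,
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  metadata <- do.call(rbind, meta)
  ground_truth <- do.call(rbind, truth)
  out <- list(metadata = metadata, specimens = specimens, traces = traces,
              plan = plan, irradiance = irradiance, filters = filters,
              ground_truth = ground_truth,
              params = list(seed = seed, conductance_h = conductance_h,
                            tau_s = tau_s, noise_sd_C = noise_sd_C,
                            spectral_noise_sd = spectral_noise_sd,
                            air_temp_C = 20, dt_sample_s = 20))
  if (!is.null(dir)) write_cohort(out, dir)
  invisible(out)
}

write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "spectra"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "traces"), showWarnings = FALSE)
  for (sp in cohort$specimens) {
    write_spectrum(sp$E, file.path(dir, "spectra", paste0(sp$id, "_E.csv")))
    write_spectrum(sp$S, file.path(dir, "spectra", paste0(sp$id, "_S.csv")))
  }
  for (id in names(cohort$traces)) {
    tr <- cohort$traces[[id]]
    utils::write.csv(data.frame(time_s = tr$time_s, temp_C = tr$temp_C,
                                channel = tr$channel),
                     file.path(dir, "traces", paste0(id, ".csv")),
                     row.names = FALSE)
  }
  write_trial_plan(cohort$plan, file.path(dir, "trial_plan.yml"))
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  write_spectrum(cohort$irradiance, file.path(dir, "irradiance.csv"))
  jsonlite::write_json(
    list(params = cohort$params, specimens = cohort$ground_truth),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Generate a paired elytra-open/closed body heating dataset
#'
#' Emulates the body experiment: per individual and band, a 5-min body
#' temperature change with the elytra closed, and one with the elytra
#' open, whose paired difference `D = closed - open` is drawn from
#' `Normal(true_mean_D, sd_D)`. Band defaults follow the pattern of a real
#' insulating elytron: clearly negative D in TOTAL and NIR, near zero in
#' VIS.
#'
#' @param n_individuals number of paired individuals (default 11).
#' @param true_mean_D named or scalar mean difference in degC; default
#'   `c(TOTAL = -0.30, NIR = -0.23, VIS = 0.05)`.
#' @param sd_D sd of the individual differences (default 0.15 degC).
#' @param baseline_mean,baseline_sd distribution of the closed-elytra
#'   body temperature change.
#' @param seed integer seed.
#' @param bands band labels to generate.
#' @return A data.frame `individual`, `band`, `closed_dt5`, `open_dt5`
#'   with the generating parameters attached as attribute
#'   `"ground_truth"`.
#' @export
gen_paired_body_dataset <- function(n_individuals = 11,
                                    true_mean_D = c(TOTAL = -0.30,
                                                    NIR = -0.23,
                                                    VIS = 0.05),
                                    sd_D = 0.15, baseline_mean = 1.5,
                                    baseline_sd = 0.3, seed = 1L,
                                    bands = c("TOTAL", "NIR", "VIS")) {
  if (n_individuals < 3L) stop("need at least 3 individuals", call. = FALSE)
  if (length(true_mean_D) == 1L && is.null(names(true_mean_D))) {
    true_mean_D <- stats::setNames(rep(true_mean_D, length(bands)), bands)
  }
  set.seed(seed)
  rows <- list()
  for (b in bands) {
    closed <- stats::rnorm(n_individuals, baseline_mean, baseline_sd)
    D <- stats::rnorm(n_individuals, true_mean_D[[b]], sd_D)
    rows[[b]] <- data.frame(individual = sprintf("ind%02d", seq_len(n_individuals)),
                            band = b, closed_dt5 = closed,
                            open_dt5 = closed - D,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ground_truth") <- list(true_mean_D = true_mean_D, sd_D = sd_D,
                                    seed = seed)
  out
}
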