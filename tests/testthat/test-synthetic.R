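test_that("every spectrum family respects E + S <= 100 pointwise and is seed-deterministic", {
  fams <- c("broadband_metallic", "narrowband_green", "melanin_brown",
            "high_NIR_transmitter")
  for (fam in fams) {
    for (seed in c(1, 99)) {
      es <- gen_spectrum_family(fam, seed = seed)
      expect_true(all(spectrum_values(es$E) + spectrum_values(es$S) <= 100))
      expect_true(all(spectrum_values(es$E) >= 0))
      expect_true(all(spectrum_values(es$S) >= 0))
      es2 <- gen_spectrum_family(fam, seed = seed)
      expect_identical(spectrum_values(es$E), spectrum_values(es2$E))
      expect_identical(spectrum_values(es$S), spectrum_values(es2$S))
    }
    # distinct seeds give distinct noise realisations
    a <- gen_spectrum_family(fam, seed = 1)
    b <- gen_spectrum_family(fam, seed = 2)
    expect_false(identical(spectrum_values(a$E), spectrum_values(b$E)))
  }
})

test_that("impossible family parameters are refused before generation", {
  expect_error(
    gen_spectrum_family("broadband_metallic", amplitude = 80, baseline = 20,
                        trans_amplitude = 30, noise_sd = 0),
    "E \\+ S > 100")
})

test_that("noise-free families are smooth and the metallic family is NIR-bright", {
  es <- gen_spectrum_family("broadband_metallic", amplitude = 70,
                            baseline = 10, noise_sd = 0)
  ir <- solar_simulator_irradiance()
  filt <- band_filter("TOTAL")
  r_vis <- band_weighted_fraction(ir, filt, es$E, band_definition("VIS"))
  r_nir <- band_weighted_fraction(ir, filt, es$E, band_definition("NIR"))
  r_tot <- band_weighted_fraction(ir, filt, es$E, band_definition("TOTAL"))
  expect_gte(r_nir, 50)
  expect_gte(r_tot, r_vis)
  # zero noise: repeated generation identical without a seed effect
  es2 <- gen_spectrum_family("broadband_metallic", amplitude = 70,
                             baseline = 10, noise_sd = 0, seed = 77)
  expect_identical(spectrum_values(es$E), spectrum_values(es2$E))
})

test_that("the analytic heating trace obeys its closed-form limits", {
  # zero absorptivity: flat at air temperature
  p0 <- heat_sim_params(absorptivity_A = 0, noise_sd_C = 0)
  tr0 <- simulate_heating_trace(p0, duration_s = 300)
  expect_true(all(tr0$temp_C == 20))
  # long-run steady state
  p <- heat_sim_params(absorptivity_A = 60, noise_sd_C = 0)
  tr <- simulate_heating_trace(p, duration_s = 30 * 75)
  expect_equal(tail(tr$temp_C, 1), 20 + steady_state_excess(p),
               tolerance = 1e-8)
  # doubling A exactly doubles dT5 and maxHR in the noise-free case
  p1 <- heat_sim_params(absorptivity_A = 30, noise_sd_C = 0)
  p2 <- heat_sim_params(absorptivity_A = 60, noise_sd_C = 0)
  t1 <- simulate_heating_trace(p1, duration_s = 300)
  t2 <- simulate_heating_trace(p2, duration_s = 300)
  expect_equal(delta_t5(t2), 2 * delta_t5(t1), tolerance = 1e-12)
  expect_equal(as.numeric(max_heating_rate(t2)),
               2 * as.numeric(max_heating_rate(t1)), tolerance = 1e-12)
  expect_error(heat_sim_params(50, conductance_h = 0), "positive")
  expect_error(simulate_heating_trace(p, duration_s = 30), "2 sampling")
})

test_that("gen_cohort builds the 28-species x 2-specimen museum design", {
  co <- gen_cohort(n_species = 28, n_per_species = 2, seed = 10,
                   noise_sd_C = 0)
  expect_equal(nrow(co$metadata), 56)
  expect_equal(length(unique(co$metadata$species)), 28)
  expect_true(all(co$metadata$length_cm >= 1.6 & co$metadata$length_cm <= 3))
  expect_setequal(unique(co$metadata$side), c("left", "right"))
  # finite exposure: recovered dT5 always below the steady-state excess
  plan <- co$plan
  for (id in co$metadata$specimen_id[1:10]) {
    hm <- heating_metrics(co$traces[[id]], plan)
    truth <- co$ground_truth[co$ground_truth$specimen_id == id, ]
    for (bn in hm$phase) {
      expect_lt(hm$delta_t5_C[hm$phase == bn],
                truth$dT_inf_C[truth$band == bn])
    }
  }
})

test_that("gen_cohort is deterministic under seed and distinct across seeds", {
  a <- gen_cohort(n_species = 4, seed = 5)
  b <- gen_cohort(n_species = 4, seed = 5)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$traces[[1]]$temp_C, b$traces[[1]]$temp_C)
  c_ <- gen_cohort(n_species = 4, seed = 6)
  expect_false(identical(a$ground_truth$dT_inf_C, c_$ground_truth$dT_inf_C))
})

test_that("the pipeline recovers the generator's absorptivity scaling", {
  # dT5 scales with the product A x area, so the additive absorptivity
  # coefficient equals (I mean(area) / 100 h)(1 - exp(-300/tau)) only up
  # to the chance A-size correlation of a 28-species draw (~+/-10% per
  # cohort); the analytic expectation is asserted on the mean over cohorts
  ratios <- vapply(c(21, 5, 99, 303), function(sd) {
    co <- gen_cohort(n_species = 28, n_per_species = 2, seed = sd,
                     noise_sd_C = 0.05)
    hm <- do.call(rbind, lapply(co$metadata$specimen_id, function(id) {
      h <- heating_metrics(co$traces[[id]], co$plan)
      h$specimen_id <- id
      h
    }))
    truth <- co$ground_truth[co$ground_truth$band == "TOTAL", ]
    d <- merge(hm[hm$phase == "TOTAL", ], truth, by = "specimen_id")
    fit <- lm(delta_t5_C ~ true_absorptivity_A + area_m2, data = d)
    expected <- (d$incident_W_m2[[1]] * mean(truth$area_m2) /
                   (100 * co$params$conductance_h)) *
      (1 - exp(-300 / co$params$tau_s))
    coef(fit)[["true_absorptivity_A"]] / expected
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("cohort dT5 values sit in the ecologically calibrated range", {
  co <- gen_cohort(n_species = 28, n_per_species = 2, seed = 31)
  dt5 <- vapply(co$metadata$specimen_id, function(id) {
    hm <- heating_metrics(co$traces[[id]], co$plan)
    hm$delta_t5_C[hm$phase == "TOTAL"]
  }, numeric(1))
  expect_true(all(dt5 > 0.2 & dt5 < 6))
  expect_true(stats::quantile(dt5, 0.25) > 0.7)
  expect_true(stats::quantile(dt5, 0.75) < 5.3)
})

test_that("paired body datasets honour their generating parameters", {
  d <- gen_paired_body_dataset(n_individuals = 11, seed = 8)
  expect_equal(nrow(d), 33)
  expect_setequal(unique(d$band), c("TOTAL", "NIR", "VIS"))
  gt <- attr(d, "ground_truth")
  expect_equal(gt$true_mean_D[["TOTAL"]], -0.30)
  # sd_D = 0: all individual differences identical
  d0 <- gen_paired_body_dataset(5, true_mean_D = -0.2, sd_D = 0, seed = 2,
                                bands = "TOTAL")
  expect_equal(unique(round(d0$closed_dt5 - d0$open_dt5, 12)), -0.2)
  # determinism
  expect_identical(gen_paired_body_dataset(11, seed = 8),
                   gen_paired_body_dataset(11, seed = 8))
})
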