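#' Run configuration for the full analysis
#'
#' Validates and freezes every knob of an end-to-end run; the returned
#' object is serialized into the results bundle so any output can be
#' traced back to its settings.
#'
#' @param input_dir directory holding a cohort (as written by
#'   [gen_cohort()] or laid out the same way): `metadata.csv`,
#'   `spectra/<id>_E.csv` and `_S.csv`, `traces/<id>.csv`,
#'   `trial_plan.yml`, `irradiance.csv`, optionally `paired.csv`.
#' @param output_dir directory for result tables (created if missing).
#' @param step_nm quadrature grid spacing in nm (default 1).
#' @param baseline dT5 baseline rule, `"onset"` or `"precool"`.
#' @param n_boot_repeatability parametric-bootstrap draws for
#'   repeatability intervals (default 1000).
#' @param n_boot_paired resamples for the paired bootstrap (default 10000).
#' @param seed integer seed used for every stochastic step.
#' @return A list of class `elytherm_config`.
#' @export
run_config <- function(input_dir, output_dir,
                       step_nm = 1, baseline = c("onset", "precool"),
                       n_boot_repeatability = 1000, n_boot_paired = 10000,
                       seed = 1L) {
  baseline <- match.arg(baseline)
  if (!dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir, call. = FALSE)
  }
  stopifnot(step_nm > 0, n_boot_repeatability >= 0, n_boot_paired > 0)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 step_nm = step_nm, baseline = baseline,
                 n_boot_repeatability = n_boot_repeatability,
                 n_boot_paired = n_boot_paired,
                 seed = as.integer(seed)),
            class = "elytherm_config")
}

#' Read a cohort directory
#'
#' Loads the file layout written by [gen_cohort()] back into memory.
#'
#' @param dir cohort directory.
#' @return A list with `metadata`, `specimens`, `traces`, `plan`,
#'   `irradiance`, and `paired` (NULL when absent).
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stop("no metadata.csv in ", dir, call. = FALSE)
  metadata <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  specimens <- lapply(metadata$specimen_id, function(id) {
    e_path <- file.path(dir, "spectra", paste0(id, "_E.csv"))
    s_path <- file.path(dir, "spectra", paste0(id, "_S.csv"))
    if (!file.exists(e_path) || !file.exists(s_path)) {
      return(list(id = id, E = NULL, S = NULL))  # caller logs and skips
    }
    list(id = id,
         E = read_spectrum(e_path, kind = "E", label = id),
         S = read_spectrum(s_path, kind = "S", label = id))
  })
  traces <- lapply(stats::setNames(metadata$specimen_id,
                                   metadata$specimen_id), function(id) {
    path <- file.path(dir, "traces", paste0(id, ".csv"))
    if (!file.exists(path)) return(NULL)  # caller logs and skips
    read_traces(path)[[1]]
  })
  plan <- read_trial_plan(file.path(dir, "trial_plan.yml"))
  irradiance <- read_spectrum(file.path(dir, "irradiance.csv"), kind = "I",
                              label = "irradiance")
  paired_path <- file.path(dir, "paired.csv")
  paired <- if (file.exists(paired_path)) {
    utils::read.csv(paired_path, stringsAsFactors = FALSE)
  } else NULL
  list(metadata = metadata, specimens = specimens, traces = traces,
       plan = plan, irradiance = irradiance, paired = paired)
}

#' Run the full analysis end to end
#'
#' Orchestrates every stage on a cohort directory: band-weighted optics
#' per specimen, heating metrics per illumination phase, the six linear
#' heating models (dT5 and maxHR x TOTAL/NIR/VIS) with partial R-squared,
#' the correlation table (transmissivity x reflectivity per band, NIR-VIS
#' cross-band correlations, size x each optical property), species
#' repeatability of both heating metrics per band, and — when a
#' `paired.csv` with columns `individual`, `band`, `closed_dt5`,
#' `open_dt5` is present — the paired bootstrap test per band. Specimens
#' with missing files are skipped with a logged reason; a run in which
#' every specimen fails is an error. All tables are written as CSV under
#' `output_dir`, together with a `results.json` bundle (settings, seeds,
#' QC flags) and a `run.log`.
#'
#' @param config an [run_config()] object.
#' @return Invisibly, a list with every result table (`optics`,
#'   `heating`, `models`, `correlations`, `repeatability`, `paired`) and
#'   `qc` (character vector of warnings).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "elytherm_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  cat("", file = log_path)
  logmsg <- function(level, ...) {
    line <- sprintf("[%s] %s %s", level,
                    format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    paste0(...))
    cat(line, "\n", file = log_path, append = TRUE)
    message(line)
  }
  logmsg("INFO", "reading cohort from ", config$input_dir)
  cohort <- read_cohort(config$input_dir)
  bands <- default_bands()
  filters <- lapply(stats::setNames(names(bands), names(bands)), band_filter)
  qc_all <- character(0)

  usable <- vapply(cohort$specimens, function(sp) {
    if (is.null(sp$E) || is.null(sp$S)) {
      logmsg("WARN", "specimen ", sp$id, " skipped: missing spectra")
      return(FALSE)
    }
    if (is.null(cohort$traces[[sp$id]])) {
      logmsg("WARN", "specimen ", sp$id, " skipped: no trace")
      return(FALSE)
    }
    TRUE
  }, logical(1))
  if (!any(usable)) stop("no usable specimens", call. = FALSE)
  specimens <- cohort$specimens[usable]

  logmsg("INFO", "computing band-weighted optics for ",
         length(specimens), " specimens")
  optics <- summarize_optics(specimens, cohort$irradiance, filters, bands,
                             step_nm = config$step_nm)
  flagged <- optics$qc_flags != ""
  if (any(flagged)) {
    logmsg("WARN", sum(flagged), " optics rows carry QC flags")
    qc_all <- c(qc_all, paste0("optics:", optics$specimen_id[flagged], ":",
                               optics$qc_flags[flagged]))
  }

  logmsg("INFO", "extracting heating metrics (baseline rule: ",
         config$baseline, ")")
  heating <- do.call(rbind, lapply(specimens, function(sp) {
    hm <- heating_metrics(cohort$traces[[sp$id]], cohort$plan,
                          baseline = config$baseline)
    hm$specimen_id <- sp$id
    hm[, c("specimen_id", setdiff(names(hm), "specimen_id"))]
  }))

  model_rows <- function(response_col, response_name) {
    do.call(rbind, lapply(names(bands), function(bn) {
      dat <- merge(
        merge(heating[heating$phase == bn,
                      c("specimen_id", response_col)],
              optics[optics$band == bn,
                     c("specimen_id", "absorptivity_A")],
              by = "specimen_id"),
        cohort$metadata[, c("specimen_id", "length_cm", "side")],
        by = "specimen_id")
      names(dat)[names(dat) == response_col] <- "response"
      names(dat)[names(dat) == "absorptivity_A"] <- "absorptivity"
      names(dat)[names(dat) == "length_cm"] <- "size"
      fit <- fit_heating_model(dat, response_name, bn)
      co <- fit$coefficients
      co$partial_R2 <- NA_real_
      for (tm in names(fit$partial_R2)) {
        co$partial_R2[grepl(paste0("^", tm), co$term)] <- fit$partial_R2[[tm]]
      }
      data.frame(response = response_name, band = bn,
                 overall_R2 = fit$overall_R2, term = co$term,
                 partial_R2 = co$partial_R2, estimate = co$estimate,
                 std_error = co$std_error, p_value = co$p_value, n = fit$n,
                 shapiro_p = fit$residual_diagnostics$shapiro_p,
                 stringsAsFactors = FALSE)
    }))
  }
  logmsg("INFO", "fitting 6 heating models (2 responses x 3 bands)")
  models <- rbind(model_rows("delta_t5_C", "delta_t5"),
                  model_rows("max_hr_C_per_s", "max_hr"))

  logmsg("INFO", "computing correlation table")
  wide <- stats::reshape(
    optics[, c("specimen_id", "band", "reflectivity_R", "transmissivity_T",
               "absorptivity_A")],
    direction = "wide", idvar = "specimen_id", timevar = "band", sep = "_")
  wide <- merge(wide, cohort$metadata[, c("specimen_id", "length_cm")],
                by = "specimen_id")
  corr_row <- function(label, parameters, range, x, y) {
    pr <- pearson_with_ci(x, y)
    data.frame(correlation = label, parameters = parameters,
               spectral_range = range, pearson_r = pr$r,
               ci_lo = pr$ci_95[[1]], ci_hi = pr$ci_95[[2]],
               p_value = pr$p_value, n = pr$n, stringsAsFactors = FALSE)
  }
  correlations <- rbind(
    do.call(rbind, lapply(names(bands), function(bn) {
      corr_row("optical properties", "Transmissivity x Reflectivity", bn,
               wide[[paste0("transmissivity_T_", bn)]],
               wide[[paste0("reflectivity_R_", bn)]])
    })),
    corr_row("spectral bands NIR-VIS", "NIR-VIS Transmissivity", "-",
             wide$transmissivity_T_NIR, wide$transmissivity_T_VIS),
    corr_row("spectral bands NIR-VIS", "NIR-VIS Reflectivity", "-",
             wide$reflectivity_R_NIR, wide$reflectivity_R_VIS),
    corr_row("spectral bands NIR-VIS", "NIR-VIS Absorptivity", "-",
             wide$absorptivity_A_NIR, wide$absorptivity_A_VIS),
    do.call(rbind, lapply(names(bands), function(bn) {
      rbind(
        corr_row("size and optical properties", "Size x Reflectivity", bn,
                 wide$length_cm, wide[[paste0("reflectivity_R_", bn)]]),
        corr_row("size and optical properties", "Size x Transmissivity", bn,
                 wide$length_cm, wide[[paste0("transmissivity_T_", bn)]]),
        corr_row("size and optical properties", "Size x Absorptivity", bn,
                 wide$length_cm, wide[[paste0("absorptivity_A_", bn)]]))
    })))

  logmsg("INFO", "repeatability across species (",
         config$n_boot_repeatability, " bootstrap draws)")
  heat_meta <- merge(heating, cohort$metadata[, c("specimen_id", "species")],
                     by = "specimen_id")
  rep_rows <- list()
  responses <- c(delta_t5 = "delta_t5_C", max_hr = "max_hr_C_per_s")
  for (resp_name in names(responses)) {
    resp <- responses[[resp_name]]
    for (bn in names(bands)) {
      d <- heat_meta[heat_meta$phase == bn, ]
      rp <- gaussian_repeatability(d[[resp]], d$species,
                                   n_boot = config$n_boot_repeatability,
                                   seed = config$seed)
      rep_rows[[paste(resp_name, bn)]] <- data.frame(
        response = resp_name, band = bn, R = rp$R_point,
        ci_lo = rp$ci_95[[1]], ci_hi = rp$ci_95[[2]], p_lrt = rp$p_lrt,
        n_groups = rp$n_groups, n_obs = rp$n_obs, stringsAsFactors = FALSE)
    }
  }
  repeatability <- do.call(rbind, rep_rows)
  rownames(repeatability) <- NULL

  paired <- NULL
  if (!is.null(cohort$paired)) {
    logmsg("INFO", "paired elytra-open/closed bootstrap (",
           config$n_boot_paired, " resamples)")
    paired <- do.call(rbind, lapply(unique(cohort$paired$band), function(bn) {
      d <- cohort$paired[cohort$paired$band == bn, ]
      pb <- paired_bootstrap_dt(d$open_dt5, d$closed_dt5,
                                n_boot = config$n_boot_paired,
                                seed = config$seed, band = bn)
      data.frame(band = bn, mean_D = pb$mean_D, ci_lo = pb$ci_95[[1]],
                 ci_hi = pb$ci_95[[2]], n_individuals = pb$n_individuals,
                 n_boot = pb$n_boot, stringsAsFactors = FALSE)
    }))
  } else {
    logmsg("INFO", "no paired.csv found; paired test skipped")
  }

  tables <- list(optics = optics, heating = heating, models = models,
                 correlations = correlations, repeatability = repeatability)
  if (!is.null(paired)) tables$paired <- paired
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]],
                     file.path(config$output_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(config = unclass(config), qc = qc_all,
         n_specimens = length(specimens),
         tables = names(tables)),
    file.path(config$output_dir, "results.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logmsg("INFO", "wrote ", length(tables), " tables to ", config$output_dir)
  invisible(c(tables, list(qc = qc_all)))
}
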