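#' @keywords internal
trapezoid_integral <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Exact integral of a product of piecewise-linear factors sharing knots x.
# On each interval the product of k linear pieces is a degree-k polynomial;
# per-interval Simpson is exact through degree 3, which covers the two- and
# three-factor products used here. Midpoint values of each factor are the
# endpoint means because the factors are linear within the interval.
product_integral <- function(x, ...) {
  factors <- list(...)
  n <- length(x)
  h <- x[-1] - x[-n]
  f_lo <- rep(1, n - 1); f_mid <- rep(1, n - 1); f_hi <- rep(1, n - 1)
  for (f in factors) {
    f_lo <- f_lo * f[-n]
    f_hi <- f_hi * f[-1]
    f_mid <- f_mid * (f[-n] + f[-1]) / 2
  }
  sum(h / 6 * (f_lo + 4 * f_mid + f_hi))
}

#' Irradiance-and-filter-weighted band fraction
#'
#' Computes the band-weighted scalar optical property
#' \deqn{\frac{\int I(\lambda) F(\lambda) X(\lambda)\, d\lambda}
#'            {\int I(\lambda) F(\lambda)\, d\lambda}}
#' over a wavelength band, where `I` is the source irradiance, `F` the
#' filter transmittance and `X` either a reflectance spectrum (giving
#' reflectivity R) or a transmittance spectrum (giving transmissivity T),
#' both in percent. All three spectra are linearly interpolated onto a
#' common grid over the band (default 1-nm spacing) and the integrals of
#' the piecewise-linear representations are evaluated exactly.
#'
#' @param irradiance `elytherm_spectrum` of kind `"I"`.
#' @param filter `elytherm_spectrum` of kind `"F"`.
#' @param x `elytherm_spectrum` of kind `"E"` or `"S"` (percent).
#' @param band an `elytherm_band` (see [band_definition()]).
#' @param step_nm grid spacing in nm (default 1).
#' @return Band-weighted value of `x` in percent (scalar).
#' @export
band_weighted_fraction <- function(irradiance, filter, x, band, step_nm = 1) {
  stopifnot(is_spectrum(irradiance), is_spectrum(filter), is_spectrum(x),
            inherits(band, "elytherm_band"))
  grid <- band_grid(band, step_nm)
  iv <- spectrum_values(resample_spectrum(irradiance, grid))
  fv <- spectrum_values(resample_spectrum(filter, grid))
  xv <- spectrum_values(resample_spectrum(x, grid))
  denom <- product_integral(grid, iv, fv)
  if (!is.finite(denom) || denom <= 0) {
    stop("no incident energy in band ", band$name, call. = FALSE)
  }
  product_integral(grid, iv, fv, xv) / denom
}

band_grid <- function(band, step_nm = 1) {
  g <- seq(band$lo_nm, band$hi_nm, by = step_nm)
  if (g[length(g)] < band$hi_nm) g <- c(g, band$hi_nm)
  g
}

#' Absorptivity from reflectivity and transmissivity
#'
#' Energy bookkeeping: the fraction absorbed is whatever is neither
#' reflected nor transmitted, `A = 100 - (T + R)`. Values outside
#' \[0, 100\] (possible when raw instrument spectra exceed the physical
#' range) are returned unmodified with an `"out_of_physical_range"` QC
#' flag — never silently clamped.
#'
#' @param R reflectivity in percent.
#' @param T_ transmissivity in percent.
#' @return A list with `A` (percent) and `qc_flags` (character vector).
#' @export
absorptivity_from_RT <- function(R, T_) {
  if (!is.finite(R) || !is.finite(T_)) {
    stop("R and T must be finite", call. = FALSE)
  }
  A <- 100 - (T_ + R)
  qc <- if (A < 0 || A > 100) "out_of_physical_range" else character(0)
  list(A = A, qc_flags = qc)
}

#' Band-weighted optical summary for a cohort of specimens
#'
#' For every specimen and every band, computes reflectivity R and
#' transmissivity T as irradiance-and-filter-weighted means of the
#' specimen's reflectance and transmittance spectra, and absorptivity
#' A = 100 - (T + R).
#'
#' @param specimens a list; each element a list with `id` (character),
#'   `E` (reflectance `elytherm_spectrum`) and `S` (transmittance
#'   `elytherm_spectrum`).
#' @param irradiance source irradiance spectrum (kind `"I"`).
#' @param filters named list of filter spectra, one per band name; defaults
#'   to the ideal [band_filter()] curves.
#' @param bands named list of `elytherm_band` (default [default_bands()]).
#' @param step_nm quadrature grid spacing (default 1 nm).
#' @return A data.frame with columns `specimen_id`, `band`,
#'   `reflectivity_R`, `transmissivity_T`, `absorptivity_A`, `qc_flags`
#'   (comma-separated string, empty if clean).
#' @export
summarize_optics <- function(specimens, irradiance,
                             filters = NULL, bands = default_bands(),
                             step_nm = 1) {
  filters <- filters %||% lapply(stats::setNames(names(bands), names(bands)),
                                 function(b) band_filter(b))
  rows <- list()
  for (sp in specimens) {
    stopifnot(is.character(sp$id), is_spectrum(sp$E), is_spectrum(sp$S))
    for (bn in names(bands)) {
      band <- bands[[bn]]
      filt <- filters[[bn]]
      if (is.null(filt)) stop("no filter supplied for band ", bn, call. = FALSE)
      R <- band_weighted_fraction(irradiance, filt, sp$E, band, step_nm)
      T_ <- band_weighted_fraction(irradiance, filt, sp$S, band, step_nm)
      ab <- absorptivity_from_RT(R, T_)
      qc <- unique(c(sp$E$qc_flags, sp$S$qc_flags, ab$qc_flags))
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = sp$id, band = bn, reflectivity_R = R,
        transmissivity_T = T_, absorptivity_A = ab$A,
        qc_flags = paste(qc, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Fraction of source energy within a band
#'
#' The share of the integrated irradiance (optionally filtered) that falls
#' inside a band, relative to a configurable reference range. Useful for
#' reporting how much of the source's energy each experimental band
#' captures; both the reference range and the spectrum are explicit inputs
#' because the answer depends on both.
#'
#' @param irradiance irradiance spectrum (kind `"I"`).
#' @param band an `elytherm_band`.
#' @param reference_band band over which the denominator integral runs
#'   (default TOTAL, 400-1700 nm).
#' @param step_nm grid spacing (default 1 nm).
#' @return Percent of reference-range energy inside `band`.
#' @export
band_energy_fraction <- function(irradiance, band,
                                 reference_band = band_definition("TOTAL"),
                                 step_nm = 1) {
  num_grid <- band_grid(band, step_nm)
  den_grid <- band_grid(reference_band, step_nm)
  num <- product_integral(num_grid,
                          spectrum_values(resample_spectrum(irradiance, num_grid)))
  den <- product_integral(den_grid,
                          spectrum_values(resample_spectrum(irradiance, den_grid)))
  if (den <= 0) stop("no energy in reference range", call. = FALSE)
  100 * num / den
}
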