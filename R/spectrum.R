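#' Construct a spectrum
#'
#' A spectrum is a sampled wavelength-to-value function. Four kinds are
#' distinguished: reflectance `"E"` and transmittance `"S"` spectra of a
#' sample (percent, against a white / open-beam standard), filter
#' transmittance `"F"` (percent), and source irradiance `"I"`
#' (W m^-2 nm^-1). Raw instrument output for E/S/F may stray outside
#' \[0, 100\]; such values are kept and flagged, never silently clamped, so
#' that instrument artifacts remain visible downstream.
#'
#' @param wavelength_nm numeric vector of wavelengths in nm, strictly
#'   increasing after sorting; duplicates are not allowed here (see
#'   [read_spectrum()] for the duplicate-collapsing reader).
#' @param value numeric vector, same length: percent for kinds E/S/F,
#'   W m^-2 nm^-1 for kind I.
#' @param kind one of `"E"`, `"S"`, `"F"`, `"I"`.
#' @param label free-text label carried through to outputs.
#' @return An object of class `elytherm_spectrum`: a list with fields
#'   `wavelength_nm`, `value`, `kind`, `label`, `qc_flags`.
#' @examples
#' sp <- spectrum_data(400:700, rep(50, 301), kind = "E", label = "flat")
#' range(wavelengths(sp))
#' @export
spectrum_data <- function(wavelength_nm, value, kind = c("E", "S", "F", "I"),
                          label = "") {
  kind <- match.arg(kind)
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) != length(value)) {
    stop("wavelength_nm and value must have the same length", call. = FALSE)
  }
  if (length(wavelength_nm) < 1L) {
    stop("a spectrum needs at least one point", call. = FALSE)
  }
  ord <- order(wavelength_nm)
  wavelength_nm <- wavelength_nm[ord]
  value <- value[ord]
  if (anyDuplicated(wavelength_nm)) {
    stop("duplicate wavelengths; collapse them first (read_spectrum does this)",
         call. = FALSE)
  }
  if (any(!is.finite(wavelength_nm))) {
    stop("non-finite wavelengths", call. = FALSE)
  }
  qc <- character(0)
  if (kind == "I") {
    if (any(!is.finite(value)) || any(value < 0)) {
      stop("irradiance values must be finite and >= 0", call. = FALSE)
    }
  } else {
    if (any(!is.finite(value))) {
      stop("spectrum values must be finite", call. = FALSE)
    }
    if (any(value < 0 | value > 100)) qc <- c(qc, "value_outside_0_100")
  }
  structure(
    list(wavelength_nm = wavelength_nm, value = value, kind = kind,
         label = label, qc_flags = qc),
    class = "elytherm_spectrum"
  )
}

#' @export
print.elytherm_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %s> %s: %d points, %g-%g nm, values [%.3g, %.3g]%s\n",
              x$kind, if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), min(x$value), max(x$value),
              if (length(x$qc_flags)) paste0(" [QC: ",
                paste(x$qc_flags, collapse = ", "), "]") else ""))
  invisible(x)
}

#' @rdname spectrum_data
#' @param s an `elytherm_spectrum`.
#' @export
wavelengths <- function(s) s$wavelength_nm

#' @rdname spectrum_data
#' @export
spectrum_values <- function(s) s$value

is_spectrum <- function(s) inherits(s, "elytherm_spectrum")

#' Read a spectrum from a two-column delimited file
#'
#' Reads a `(wavelength_nm, value)` table. The delimiter (comma, tab,
#' semicolon or whitespace) is autodetected and a header line is optional.
#' Rows are sorted by wavelength; duplicated wavelengths are collapsed to
#' their mean value with a `"duplicate_wavelengths_averaged"` QC flag.
#'
#' @param path file path.
#' @inheritParams spectrum_data
#' @return An `elytherm_spectrum`.
#' @export
read_spectrum <- function(path, kind = c("E", "S", "F", "I"), label = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty spectrum file: ", path, call. = FALSE)
  sep <- detect_delimiter(lines[[1]])
  split_row <- function(line) {
    if (sep == "") strsplit(trimws(line), "[[:space:]]+")[[1]]
    else strsplit(line, sep, fixed = TRUE)[[1]]
  }
  first <- suppressWarnings(as.numeric(split_row(lines[[1]])))
  has_header <- any(is.na(first))
  body <- if (has_header) lines[-1L] else lines
  if (length(body) == 0L) stop("no data rows in ", path, call. = FALSE)
  wl <- numeric(length(body))
  val <- numeric(length(body))
  for (i in seq_along(body)) {
    fields <- suppressWarnings(as.numeric(split_row(body[[i]])))
    if (length(fields) < 2L || any(is.na(fields[1:2]))) {
      stop(sprintf("malformed row at line %d of %s: '%s'",
                   i + has_header, path, body[[i]]), call. = FALSE)
    }
    wl[i] <- fields[[1]]
    val[i] <- fields[[2]]
  }
  qc <- character(0)
  if (anyDuplicated(wl)) {
    val <- as.numeric(tapply(val, wl, mean))
    wl <- sort(unique(wl))
    qc <- "duplicate_wavelengths_averaged"
    warning("duplicate wavelengths in ", path, " collapsed by mean",
            call. = FALSE)
  }
  s <- spectrum_data(wl, val, kind = kind,
                     label = label %||% basename(path))
  s$qc_flags <- union(s$qc_flags, qc)
  s
}

detect_delimiter <- function(line) {
  for (sep in c(",", "\t", ";")) {
    if (grepl(sep, line, fixed = TRUE)) return(sep)
  }
  ""
}

#' Write a spectrum to a two-column CSV
#'
#' @param s an `elytherm_spectrum`.
#' @param path output file path.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(is_spectrum(s))
  utils::write.csv(
    data.frame(wavelength_nm = s$wavelength_nm, value = s$value),
    path, row.names = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a wavelength grid
#'
#' Linear interpolation between measured points; grid points that coincide
#' with measured wavelengths are returned unchanged. Extrapolation outside
#' the spectrum's support is refused.
#'
#' @param s an `elytherm_spectrum`.
#' @param grid numeric vector of target wavelengths (nm), within the
#'   spectrum's support.
#' @return An `elytherm_spectrum` on `grid`.
#' @export
resample_spectrum <- function(s, grid) {
  stopifnot(is_spectrum(s))
  grid <- as.numeric(grid)
  lo <- min(s$wavelength_nm); hi <- max(s$wavelength_nm)
  if (any(grid < lo) || any(grid > hi)) {
    stop(sprintf(
      "grid extends outside the spectrum's support [%g, %g] nm; no extrapolation",
      lo, hi), call. = FALSE)
  }
  v <- stats::approx(s$wavelength_nm, s$value, xout = grid, method = "linear",
                     ties = "ordered")$y
  out <- spectrum_data(grid, v, kind = s$kind, label = s$label)
  out$qc_flags <- s$qc_flags
  out
}

#' Spectral band definitions
#'
#' The three bands used throughout: VIS 400-700 nm, NIR 700-1700 nm and
#' TOTAL 400-1700 nm.
#'
#' @param name band name, `"VIS"`, `"NIR"` or `"TOTAL"`.
#' @param lo_nm,hi_nm band edges in nm (defaults per `name`).
#' @return A list with `name`, `lo_nm`, `hi_nm` of class `elytherm_band`.
#' @export
band_definition <- function(name = c("VIS", "NIR", "TOTAL"),
                            lo_nm = NULL, hi_nm = NULL) {
  name <- match.arg(name)
  edges <- switch(name, VIS = c(400, 700), NIR = c(700, 1700),
                  TOTAL = c(400, 1700))
  lo_nm <- lo_nm %||% edges[[1]]
  hi_nm <- hi_nm %||% edges[[2]]
  if (!(lo_nm < hi_nm)) stop("band must have lo_nm < hi_nm", call. = FALSE)
  structure(list(name = name, lo_nm = lo_nm, hi_nm = hi_nm),
            class = "elytherm_band")
}

#' @rdname band_definition
#' @export
default_bands <- function() {
  list(VIS = band_definition("VIS"), NIR = band_definition("NIR"),
       TOTAL = band_definition("TOTAL"))
}

#' Smooth stand-in irradiance for a filtered solar simulator
#'
#' A 5800-K Planck curve over 400-1700 nm scaled so the integrated energy
#' density is `total_W_m2` over that range. This is a smooth synthetic
#' stand-in for a manufacturer-supplied lamp spectrum (AM1.5-like in shape);
#' substitute a measured table via [read_spectrum()] for real instruments.
#'
#' @param total_W_m2 integrated irradiance over 400-1700 nm (default 450,
#'   i.e. ~90% of a 0.5-Sun 500 W m^-2 source falls in this range).
#' @param step_nm sampling step (default 1 nm).
#' @return An `elytherm_spectrum` of kind `"I"`.
#' @export
solar_simulator_irradiance <- function(total_W_m2 = 450, step_nm = 1) {
  wl <- seq(400, 1700, by = step_nm)
  lam <- wl * 1e-9
  h <- 6.62607015e-34; c0 <- 2.99792458e8; kB <- 1.380649e-23; Tsun <- 5800
  planck <- (2 * pi * h * c0^2) / (lam^5 * (exp(h * c0 / (lam * kB * Tsun)) - 1))
  raw <- spectrum_data(wl, planck, kind = "I", label = "synthetic solar simulator")
  scale <- total_W_m2 / trapezoid_integral(wl, planck)
  spectrum_data(wl, planck * scale, kind = "I",
                label = "synthetic solar simulator (0.5 Sun class)")
}

#' Band-pass filter transmittance spectra
#'
#' Ideal filter curves for the three illumination conditions: TOTAL is the
#' uncovered portal (flat 100%), VIS passes 400-700 nm, NIR passes
#' 700-1700 nm. Filter edges are represented as adjacent data points one
#' `edge_nm` apart; no special edge handling happens beyond ordinary linear
#' interpolation of those points.
#'
#' @param band band name `"VIS"`, `"NIR"` or `"TOTAL"`.
#' @param edge_nm width of the transition ramp at each cut-off (default 1).
#' @return An `elytherm_spectrum` of kind `"F"` covering 400-1700 nm.
#' @export
band_filter <- function(band = c("TOTAL", "VIS", "NIR"), edge_nm = 1) {
  band <- match.arg(band)
  if (band == "TOTAL") {
    return(spectrum_data(c(400, 1700), c(100, 100), kind = "F",
                         label = "open portal"))
  }
  cut <- 700
  if (band == "VIS") {
    wl <- c(400, cut, cut + edge_nm, 1700)
    tr <- c(100, 100, 0, 0)
  } else {
    wl <- c(400, cut - edge_nm, cut, 1700)
    tr <- c(0, 0, 100, 100)
  }
  spectrum_data(wl, tr, kind = "F", label = paste(band, "filter"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
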