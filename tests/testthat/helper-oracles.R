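# Independent oracles used to check the package's numerics. These stay
# deliberately naive: fine-grid midpoint Riemann sums, balanced-ANOVA
# closed forms, and direct textbook formulas, computed without touching
# the code paths they validate.

# Band-weighted fraction by brute force: interpolate each spectrum onto
# midpoints of a very fine grid and take the ratio of Riemann sums.
riemann_band_fraction <- function(irradiance, filter, x, band,
                                  step_nm = 0.01) {
  edges <- seq(band$lo_nm, band$hi_nm, by = step_nm)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  interp <- function(s) {
    stats::approx(s$wavelength_nm, s$value, xout = mids,
                  ties = "ordered")$y
  }
  iv <- interp(irradiance); fv <- interp(filter); xv <- interp(x)
  sum(iv * fv * xv) / sum(iv * fv)
}

# Closed-form intraclass correlation for a balanced one-way design from
# ANOVA mean squares: ICC = (MSB - MSW) / (MSB + (k - 1) MSW).
anova_icc <- function(values, group_ids) {
  group <- factor(group_ids)
  k <- unique(table(group))
  stopifnot(length(k) == 1)  # balanced designs only
  grand <- mean(values)
  means <- tapply(values, group, mean)
  msb <- k * sum((means - grand)^2) / (nlevels(group) - 1)
  msw <- sum((values - means[group])^2) / (length(values) - nlevels(group))
  (msb - msw) / (msb + (k - 1) * msw)
}

# Textbook Pearson correlation, Fisher-z interval and t-based p-value.
pearson_oracle <- function(x, y, conf_level = 0.95) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  crit <- qnorm(1 - (1 - conf_level) / 2)
  ci <- tanh(c(z - crit * se, z + crit * se))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(r = r, ci = ci, p = p)
}

# Random smooth spectrum fixture on a 1-nm grid: a baseline plus a few
# random sinusoids, kept inside [lo_val, hi_val].
random_smooth_spectrum <- function(seed, kind = "E", lo_val = 5,
                                   hi_val = 90) {
  set.seed(seed)
  wl <- 400:1700
  y <- runif(1, 20, 60)
  for (j in 1:3) {
    y <- y + runif(1, 2, 12) *
      sin(2 * pi * wl / runif(1, 300, 1500) + runif(1, 0, 2 * pi))
  }
  y <- pmin(pmax(y, lo_val), hi_val)
  spectrum_data(wl, y, kind = kind, label = paste0("fixture", seed))
}

# Random E/S pair with pointwise E + S <= 100.
random_es_pair <- function(seed) {
  E <- random_smooth_spectrum(seed, kind = "E", lo_val = 5, hi_val = 70)
  S <- random_smooth_spectrum(seed + 1000, kind = "S", lo_val = 1,
                              hi_val = 25)
  list(E = E, S = S)
}

flat_spectrum <- function(value, kind, lo = 400, hi = 1700) {
  spectrum_data(c(lo, hi), c(value, value), kind = kind)
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
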