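make_model_data <- function(n, beta_a = 0.03, beta_s = 0.25, beta_side = 0,
                            intercept = 2, sigma = 0, seed = 1) {
  set.seed(seed)
  d <- data.frame(
    absorptivity = runif(n, 20, 80),
    size = runif(n, 1.6, 3),
    side = rep(c("left", "right"), length.out = n))
  d$response <- intercept + beta_a * d$absorptivity + beta_s * d$size +
    beta_side * (d$side == "right") + rnorm(n, 0, sigma)
  d
}

test_that("zero-noise OLS recovers planted coefficients and a null side effect", {
  d <- make_model_data(40, sigma = 0)
  fit <- fit_heating_model(d, "delta_t5", "TOTAL")
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(est["(Intercept)"]), 2, tolerance = 1e-8)
  expect_equal(unname(est["absorptivity"]), 0.03, tolerance = 1e-8)
  expect_equal(unname(est["size"]), 0.25, tolerance = 1e-8)
  expect_equal(unname(est["sideright"]), 0, tolerance = 1e-8)
  expect_equal(fit$overall_R2, 100, tolerance = 1e-8)
  expect_equal(fit$n, 40)
})

test_that("partial R2 uses extra sums of squares and never exceeds the overall R2", {
  d <- make_model_data(200, sigma = 0.1, seed = 42)
  fit <- fit_heating_model(d)
  expect_true(all(fit$partial_R2 >= 0))
  expect_true(all(fit$partial_R2 <= fit$overall_R2 + 1e-9))

  # brute-force verification via explicit normal equations
  X_full <- cbind(1, d$absorptivity, d$size, d$side == "right")
  ssres <- function(X, y) {
    b <- solve(crossprod(X), crossprod(X, d$response))
    sum((d$response - X %*% b)^2)
  }
  ss_tot <- sum((d$response - mean(d$response))^2)
  ss_full <- ssres(X_full)
  for (j in 2:4) {
    term <- c("absorptivity", "size", "side")[j - 1]
    manual <- 100 * (ssres(X_full[, -j, drop = FALSE]) - ss_full) / ss_tot
    expect_equal(unname(fit$partial_R2[[term]]), manual, tolerance = 1e-9)
  }
  # side has no planted effect: its partial R2 is negligible
  expect_lt(fit$partial_R2[["side"]], 2)
})

test_that("partial R2 is additive for an exactly orthogonal balanced design", {
  # orthogonal coded predictors over a balanced 2^3-style grid
  g <- expand.grid(a = c(-1, 1), s = c(-1, 1), p = c(-1, 1))
  g <- g[rep(seq_len(nrow(g)), 5), ]
  set.seed(7)
  d <- data.frame(absorptivity = g$a, size = g$s,
                  side = ifelse(g$p > 0, "right", "left"))
  d$response <- 1 + 0.5 * g$a + 0.3 * g$s + 0.2 * g$p + rnorm(nrow(g), 0, 0.2)
  fit <- fit_heating_model(d)
  expect_equal(sum(fit$partial_R2), fit$overall_R2, tolerance = 1e-9)
})

test_that("rank-deficient heating designs are refused by name", {
  d <- make_model_data(30, sigma = 0.1)
  d$size <- d$absorptivity * 2  # collinear
  expect_error(fit_heating_model(d), "collinear")
  expect_error(fit_heating_model(d[1:4, ]), "at least 5")
  d2 <- make_model_data(30, sigma = 0.1)
  d2$response[3] <- NA
  expect_error(fit_heating_model(d2), "missing")
})

test_that("pearson_with_ci matches the direct-formula oracle to 1e-10", {
  set.seed(1)
  x <- rnorm(20)
  y <- 0.6 * x + rnorm(20, 0, 0.8)
  got <- pearson_with_ci(x, y)
  want <- pearson_oracle(x, y)
  expect_equal(got$r, want$r, tolerance = 1e-10)
  expect_equal(got$ci_95, want$ci, tolerance = 1e-10)
  expect_equal(got$p_value, want$p, tolerance = 1e-10)
  expect_equal(got$n, 20)
})

test_that("pearson_with_ci handles degenerate and invalid input per contract", {
  expect_error(pearson_with_ci(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_with_ci(1:3, 1:3), "n >= 4")
  perfect <- pearson_with_ci(1:5, 2 * (1:5) + 3)
  expect_equal(perfect$r, 1)
  expect_true(perfect$degenerate)
  expect_equal(perfect$ci_95, c(1, 1))
  anti <- pearson_with_ci(1:5, -(1:5))
  expect_equal(anti$r, -1)
  expect_true(anti$degenerate)
})

test_that("repeatability approaches 1 when within-group variance vanishes", {
  values <- rep(c(1, 5, 9), each = 4) + rep(c(0, 1e-6, -1e-6, 2e-6), 3)
  rp <- gaussian_repeatability(values, rep(c("a", "b", "c"), each = 4),
                               n_boot = 0)
  expect_gte(rp$R_point, 0.999)
})

test_that("repeatability matches the balanced-ANOVA closed form and recovers ICC 0.5", {
  # single-dataset sampling SE of an ICC near 0.5 at 30 x 10 is ~0.08, so
  # proximity to the truth is asserted on the mean over replicates; the
  # closed-form agreement is exact per dataset
  set.seed(42)
  g <- rep(sprintf("g%02d", 1:30), each = 10)
  r_hats <- vapply(1:20, function(i) {
    values <- rnorm(30, 0, 1)[as.integer(factor(g))] + rnorm(300, 0, 1)
    rp <- gaussian_repeatability(values, g, n_boot = 0)
    expect_equal(rp$R_point, anova_icc(values, g), tolerance = 1e-6)
    rp$R_point
  }, numeric(1))
  expect_lt(abs(mean(r_hats) - 0.5), 0.05)

  set.seed(42)
  values <- rnorm(30, 0, 1)[as.integer(factor(g))] + rnorm(300, 0, 1)
  rp <- gaussian_repeatability(values, g, n_boot = 200, seed = 42)
  expect_true(rp$ci_95[[1]] <= rp$R_point && rp$R_point <= rp$ci_95[[2]])
  expect_lt(rp$p_lrt, 1e-6)
  # bit-for-bit reproducible under the same seed
  rp2 <- gaussian_repeatability(values, g, n_boot = 200, seed = 42)
  expect_identical(rp$ci_95, rp2$ci_95)
  expect_identical(rp$boot_R, rp2$boot_R)
})

test_that("under the null the LRT has valid size and R-hat stays small", {
  set.seed(2024)
  n_rep <- 200
  p_vals <- numeric(n_rep)
  r_hats <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    values <- rnorm(48)
    g <- rep(letters[1:6], each = 8)
    rp <- suppressWarnings(
      gaussian_repeatability(values, g, n_boot = 0))
    p_vals[i] <- rp$p_lrt
    r_hats[i] <- rp$R_point
  }
  expect_lt(mean(r_hats), 0.12)
  # boundary-mixture null: p has an atom above 0.5 but P(p <= a) ~ a below;
  # binomial 99.9% bounds at n = 200
  for (alpha in c(0.05, 0.10)) {
    rate <- mean(p_vals <= alpha)
    bounds <- qbinom(c(5e-4, 1 - 5e-4), n_rep, alpha) / n_rep
    expect_gte(rate, bounds[[1]])
    expect_lte(rate, bounds[[2]])
  }
})

test_that("singleton groups are dropped with a warning; all-singleton input errors", {
  expect_warning(
    rp <- gaussian_repeatability(c(1, 2, 3, 4, 9),
                                 c("a", "a", "b", "b", "c"), n_boot = 0),
    "singleton")
  expect_equal(rp$n_groups, 2)
  expect_equal(rp$n_obs, 4)
  expect_error(
    gaussian_repeatability(1:3, c("a", "b", "c"), n_boot = 0),
    "single observation")
})

test_that("paired bootstrap handles exact and degenerate cases per contract", {
  zero <- paired_bootstrap_dt(rep(1.5, 5), rep(1.5, 5), n_boot = 500,
                              seed = 3)
  expect_equal(zero$mean_D, 0)
  expect_equal(zero$ci_95, c(0, 0))
  const <- paired_bootstrap_dt(rep(2.0, 6), rep(1.7, 6), n_boot = 500,
                               seed = 3)
  expect_equal(const$mean_D, -0.3)
  expect_equal(const$ci_95, c(-0.3, -0.3))
  expect_error(paired_bootstrap_dt(1:4, 1:5), "paired")
  expect_error(paired_bootstrap_dt(1:2, 1:2), "at least 3")
})

test_that("paired bootstrap sign convention: negative interval means hotter without elytra", {
  set.seed(11)
  closed <- rnorm(11, 1.5, 0.2)
  open <- closed + 0.4 + rnorm(11, 0, 0.05)  # body heats more when open
  pb <- paired_bootstrap_dt(open, closed, n_boot = 2000, seed = 5)
  expect_lt(pb$ci_95[[2]], 0)
  # reproducibility under seed
  pb2 <- paired_bootstrap_dt(open, closed, n_boot = 2000, seed = 5)
  expect_identical(pb$boot_means, pb2$boot_means)
})
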