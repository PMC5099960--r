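test_that("noise-free series equal the model values exactly", {
  model <- default_diameter_model()
  s1 <- generate_diameter_series(model[1, ], noise_sd_log10 = 0,
                                 n_per_generation = 1)
  # hand-computed oracle values: 10^(intercept + slope * g)
  expect_equal(s1$diameter_mm[s1$generation == 0], 10^1.3094, tolerance = 1e-12)
  expect_equal(s1$diameter_mm[s1$generation == 11],
               10^(1.3094 - 0.0438 * 11), tolerance = 1e-12)
  flat <- generate_diameter_series(
    data.frame(g_min = 0, g_max = 5, slope = 0, intercept = 1),
    noise_sd_log10 = 0, n_per_generation = 2)
  expect_true(all(flat$diameter_mm == 10))
})

test_that("overlapping or invalid segment tables are rejected", {
  bad <- data.frame(g_min = c(0, 5), g_max = c(6, 9),
                    slope = c(-0.1, -0.1), intercept = c(1, 1))
  expect_error(generate_diameter_series(bad), "overlap")
  expect_error(generate_diameter_series(noise_sd_log10 = -1))
})

test_that("noisy series are reproducible by seed and have the right spread", {
  a <- generate_diameter_series(noise_sd_log10 = 0.05, seed = 10)
  b <- generate_diameter_series(noise_sd_log10 = 0.05, seed = 10)
  expect_identical(a, b)
  big <- generate_diameter_series(noise_sd_log10 = 0.05,
                                  n_per_generation = 400, seed = 3)
  res <- log10(big$diameter_mm) -
    log10(generate_diameter_series(noise_sd_log10 = 0,
                                   n_per_generation = 400)$diameter_mm)
  expect_equal(sd(res), 0.05, tolerance = 0.05)
})

test_that("piecewise fit recovers the printed coefficients from clean data", {
  series <- generate_diameter_series(noise_sd_log10 = 0, n_per_generation = 3)
  fit <- fit_loglinear_segments(series)
  expect_identical(nrow(fit$segments), 3L)
  expect_equal(fit$segments$slope, c(-0.0438, -0.0228, -0.0418),
               tolerance = 1e-9)
  expect_equal(fit$segments$intercept, c(1.3094, 1.0979, 1.488),
               tolerance = 1e-9)
})

test_that("a constant series fits slope 0 and intercept log10(D)", {
  series <- data.frame(generation = rep(0:8, 2), diameter_mm = 5)
  fit <- fit_loglinear_segments(series)
  expect_equal(fit$segments$slope[1], 0, tolerance = 1e-12)
  expect_equal(fit$segments$intercept[1], log10(5), tolerance = 1e-12)
})

test_that("segment OLS equals the closed-form normal-equation oracle", {
  set.seed(77)
  for (rep in 1:5) {
    series <- generate_diameter_series(noise_sd_log10 = 0.04,
                                       n_per_generation = 4,
                                       seed = 100 + rep)
    fit <- fit_loglinear_segments(series)
    for (i in seq_len(nrow(fit$segments))) {
      s <- fit$segments[i, ]
      sub <- series[series$generation >= s$g_min & series$generation <= s$g_max, ]
      x <- sub$generation
      y <- log10(sub$diameter_mm)
      slope_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
      int_hat <- mean(y) - slope_hat * mean(x)
      expect_equal(s$slope, slope_hat, tolerance = 1e-12)
      expect_equal(s$intercept, int_hat, tolerance = 1e-12)
    }
  }
})

test_that("95% CIs cover the true slope in at least 90% of replicates", {
  hits <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    series <- generate_diameter_series(noise_sd_log10 = 0.02,
                                       n_per_generation = 6, seed = 1000 + r)
    fit <- fit_loglinear_segments(series)
    s1 <- fit$segments[1, ]
    hits <- hits + as.integer(abs(s1$slope - (-0.0438)) <= s1$ci_slope_halfwidth)
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("segments outside the data are omitted; sparse segments error", {
  model <- default_diameter_model()
  s2 <- generate_diameter_series(model[2, ], noise_sd_log10 = 0)
  fit <- fit_loglinear_segments(s2)
  expect_identical(fit$segments$segment, 2L)
  one_pt <- data.frame(generation = c(0:5, 12), diameter_mm = 10)
  expect_error(fit_loglinear_segments(one_pt), "segment 2")
})

test_that("tidy, glance and autoplot work on fits", {
  fit <- fit_loglinear_segments(generate_diameter_series(noise_sd_log10 = 0))
  td <- tidy(fit)
  expect_identical(nrow(td), 6L)
  expect_true(all(c("segment", "term", "estimate", "conf.low") %in% names(td)))
  gl <- glance(fit)
  expect_identical(gl$n_segments, 3L)
  expect_s3_class(autoplot(fit), "ggplot")
})
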