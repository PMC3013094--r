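# Oxygen solubility, decline fitting and MO2 conversion

test_that("saturation concentration matches tabulated reference points", {
  # Benson-Krause values from the standard fresh-water DO tables (1 atm):
  # 20 degC -> 9.09 mg/L, 28 degC -> 7.83 mg/L
  expect_equal(o2_saturation(20) * 31.9988 / 1000, 9.092, tolerance = 2e-3)
  expect_equal(o2_saturation(28) * 31.9988 / 1000, 7.828, tolerance = 2e-3)
  # oracle value frozen from an independent implementation of the relation
  expect_equal(o2_saturation(28), 244.63, tolerance = 1e-4)
})

test_that("percent air saturation converts linearly to concentration", {
  sp <- std_tunnel()
  expect_equal(pct_as_to_concentration(0, sp), 0)
  c100 <- pct_as_to_concentration(100, sp)
  expect_equal(c100, 245, tolerance = 0.01)     # ~245 umol/L at 28 degC
  expect_equal(pct_as_to_concentration(50, sp), c100 / 2)
  # monotone increasing
  pct <- seq(0, 110, by = 5)
  expect_true(all(diff(pct_as_to_concentration(pct, sp)) > 0))
  expect_error(pct_as_to_concentration(-1, sp), "non-negative")
  expect_error(tunnel_spec(temperature = 45), "temperature")
  expect_error(tunnel_spec(barometric_pressure = -1), "pressure")
})

test_that("concentration/percent-saturation roundtrip is the identity", {
  sp <- std_tunnel()
  pct <- c(0, 12.5, 50, 100, 117)
  expect_equal(concentration_to_pct_as(pct_as_to_concentration(pct, sp), sp),
               pct, tolerance = 1e-12)
})

test_that("fit_decline recovers exact and noisy slopes", {
  sp <- std_tunnel()
  fit <- fit_decline(linear_trace(-10, sp), sp)
  expect_equal(fit$slope, -10, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  flat <- suppressWarnings(fit_decline(linear_trace(0, sp), sp))
  expect_equal(flat$slope, 0, tolerance = 1e-9)

  set.seed(421)
  noisy <- linear_trace(-8.5, sp, duration = 1198, by = 2, noise_sd = 0.5)
  nf <- suppressWarnings(fit_decline(noisy, sp))
  expect_equal(nf$n_points, 600)
  expect_lt(abs(nf$slope - (-8.5)), 0.5)
  # OLS oracle: closed-form slope from covariance arithmetic
  sat <- o2_saturation(28)
  x <- noisy$time_s / 3600
  y <- noisy$oxygen / 100 * sat
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(nf$slope, beta, tolerance = 1e-10)
})

test_that("fit_decline enforces its preconditions and QC options", {
  sp <- std_tunnel()
  tr <- linear_trace(-10, sp, duration = 100)
  tr$phase[-1] <- "flush"
  expect_error(fit_decline(tr, sp), "at least 2 closed-phase")
  expect_error(oxygen_trace(c(0, 2, 2), c(100, 99, 98)), "strictly increasing")
  expect_error(oxygen_trace(c(0, 2), c(100, 150)), "within")
  set.seed(7)
  wob <- linear_trace(-0.5, sp, duration = 60, noise_sd = 1)
  expect_warning(fit_decline(wob, sp), "r-squared")
  # trimming drops samples at the phase edges
  full <- fit_decline(linear_trace(-10, sp), sp)
  trimmed <- fit_decline(linear_trace(-10, sp), sp,
                         trim_leading = 60, trim_trailing = 60)
  expect_lt(trimmed$n_points, full$n_points)
  expect_equal(trimmed$slope, full$slope, tolerance = 1e-9)
  # blank subtraction shifts the slope by exactly the blank rate
  blanked <- fit_decline(linear_trace(-10, sp), sp, blank_slope = -2)
  expect_equal(blanked$slope, -8, tolerance = 1e-9)
  expect_true(blanked$blank_corrected)
})

test_that("mo2 scales slope by volume over mass", {
  sp <- std_tunnel(volume = 1.8)
  f <- fit_decline(linear_trace(-10, sp), sp)
  expect_equal(mo2(f, sp, body_mass = 0.43), 10 * 1.8 / 0.43,
               tolerance = 1e-9)                  # 41.86 umol/g/h
  expect_equal(mo2(fit_decline(linear_trace(0, sp), sp), sp, 0.43), 0,
               tolerance = 1e-9)
  big <- std_tunnel(volume = 3.6)
  f2 <- fit_decline(linear_trace(-10, big), big)
  expect_equal(mo2(f2, big, 0.43), 2 * mo2(f, sp, 0.43), tolerance = 1e-9)
  rising <- fit_decline(linear_trace(5, sp), sp)
  expect_error(mo2(rising, sp, 0.43), "increased")
  expect_warning(v <- mo2(rising, sp, 0.43, allow_positive_slope = TRUE))
  expect_equal(v, 0)
  expect_error(mo2(f, sp, body_mass = 0), "positive")
})

test_that("MO2 pipeline is exact on noiseless traces and time-shift invariant", {
  sp <- std_tunnel()
  truth <- noiseless_truth()
  for (speed in c(25, 50, 75, 100)) {
    tr <- simulate_o2_trace(truth, body_mass = 0.43, speed_pct = speed,
                            duration = 1200, spec = sp)
    got <- mo2(fit_decline(tr, sp), sp, 0.43)
    expect_equal(got, true_mo2(truth, speed), tolerance = 1e-10)
  }
  tr <- linear_trace(-10, sp)
  shifted <- oxygen_trace(tr$time_s + 5000, tr$oxygen, tr$phase)
  expect_equal(fit_decline(shifted, sp)$slope, fit_decline(tr, sp)$slope,
               tolerance = 1e-9)
})

test_that("trace CSV roundtrips through the reader", {
  sp <- std_tunnel()
  truth <- noiseless_truth()
  tr <- simulate_o2_trace(truth, speed_pct = 50, spec = sp, fish_id = "f9")
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(fish_id = "f9", time_s = tr$time_s,
                       o2_pct_as = tr$oxygen, phase = tr$phase,
                       speed_pct_ucrit = 50), path, row.names = FALSE)
  traces <- read_trace_csv(path)
  expect_length(traces, 1L)
  expect_equal(traces[[1]]$oxygen, tr$oxygen, tolerance = 1e-9)
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(fish_id = "f9", time_s = 1), bad, row.names = FALSE)
  expect_error(read_trace_csv(bad), "o2_pct_as")
})
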