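# Quadratic metabolic model, cost of transport, optimal swimming speed

test_that("fit_vo2_curve recovers generating coefficients exactly", {
  u <- c(25, 50, 75, 100)
  v <- 43.79 + 0.0081 * u^2 - 0.4353 * u
  fit <- fit_vo2_curve(u, v)
  expect_equal(fit$smr, 43.79, tolerance = 1e-10)
  expect_equal(fit$a, 0.0081, tolerance = 1e-10)
  expect_equal(fit$b, -0.4353, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(predict(fit, 0), fit$smr)
})

test_that("fit_vo2_curve degenerate and error cases", {
  fit <- fit_vo2_curve(c(10, 20, 30, 40), rep(5.5, 4))
  expect_equal(fit$smr, 5.5, tolerance = 1e-9)
  expect_equal(fit$a, 0, tolerance = 1e-9)
  expect_equal(fit$b, 0, tolerance = 1e-9)
  # any noiseless quadratic through 3 points is interpolated, r2 = 1
  fit3 <- fit_vo2_curve(c(10, 55, 90), 2 + 0.03 * c(10, 55, 90)^2)
  expect_equal(fit3$r_squared, 1, tolerance = 1e-9)
  expect_error(fit_vo2_curve(c(10, 10, 10), c(1, 2, 3)), "distinct")
})

test_that("cost of transport is uptake per distance", {
  expect_equal(cot_from_vo2(36, 1), 1.0)          # 1 cm/s = 36 m/h
  expect_equal(cot_from_vo2(72, 1), 2 * cot_from_vo2(36, 1))
  expect_equal(cot_from_vo2(54.6, 39.6), 54.6 / (39.6 * 36), tolerance = 1e-12)
  expect_equal(cot_from_vo2(54.6, 39.6), 0.0383, tolerance = 1e-3)
  # strictly decreasing in speed at fixed uptake
  sp <- seq(5, 100, by = 5)
  expect_true(all(diff(cot_from_vo2(50, sp)) < 0))
  expect_error(cot_from_vo2(36, 0), "undefined")
  # curve scale is the plain ratio on the given axis
  expect_equal(cot_from_vo2(50, 25, scale = "curve"), 2)
})

test_that("fit_cot_curve recovers printed-style coefficients exactly", {
  u <- c(25, 50, 75, 100)
  cot <- 0.0104 * u^2 - 1.6239 * u + 88.767
  fit <- fit_cot_curve(u, cot)
  expect_equal(fit$a2, 0.0104, tolerance = 1e-10)
  expect_equal(fit$b2, -1.6239, tolerance = 1e-10)
  expect_equal(fit$c2, 88.767, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # symmetric points about U0 put the vertex at U0
  u0 <- 40
  us <- u0 + c(-20, -10, 10, 20)
  sym <- fit_cot_curve(us, (us - u0)^2 + 3)
  expect_equal(find_uopt(sym)$uopt, u0, tolerance = 1e-9)
})

test_that("find_uopt locates the vertex and matches a grid search", {
  opt <- find_uopt(cot_curve(0.0104, -1.6239, 88.767))
  expect_equal(opt$uopt, 1.6239 / (2 * 0.0104), tolerance = 1e-12) # 78.07
  expect_equal(opt$cot_opt, 25.3763, tolerance = 1e-4)
  expect_equal(find_uopt(cot_curve(1, 0, 5)), list(uopt = 0, cot_opt = 5))
  expect_equal(find_uopt(cot_curve(1, -4, 0)), list(uopt = 2, cot_opt = -4))
  expect_error(find_uopt(cot_curve(-1, 2, 3)), "minimum")
  # brute-force oracle over random upward parabolas
  set.seed(5)
  grid <- seq(0, 120, by = 1e-3)
  for (i in 1:10) {
    cv <- cot_curve(runif(1, 0.001, 0.05), -runif(1, 0.1, 3), runif(1, 10, 90))
    vertex <- find_uopt(cv)$uopt
    if (vertex >= 0 && vertex <= 120) {
      expect_lt(abs(vertex - grid[which.min(predict(cv, grid))]), 1e-2)
    }
  }
})

test_that("summarize_group reports mean and SEM", {
  s <- summarize_group(c(1, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1)
  expect_equal(summarize_group(rep(4.2, 6))$sem, 0)
  expect_error(summarize_group(1), "at least 2")
  # Monte-Carlo: ten fish with true U_opt 0.396 and noise SD 0.06
  set.seed(19)
  draws <- replicate(200, {
    s <- summarize_group(rnorm(10, 0.396, 0.06))
    abs(s$mean - 0.396) <= 3 * s$sem
  })
  expect_gt(mean(draws), 0.95)
})

test_that("noiseless traces round-trip to the generating curve", {
  sp <- std_tunnel()
  truth <- noiseless_truth()
  speeds <- c(25, 50, 75, 100)
  pts <- vapply(speeds, function(s) {
    tr <- simulate_o2_trace(truth, body_mass = 0.43, speed_pct = s, spec = sp)
    mo2(fit_decline(tr, sp), sp, 0.43)
  }, numeric(1))
  fit <- fit_vo2_curve(speeds, pts)
  expect_equal(fit$smr, truth$smr, tolerance = 1e-8)
  expect_equal(fit$a, truth$a, tolerance = 1e-8)
  expect_equal(fit$b, truth$b, tolerance = 1e-8)
})

test_that("swim_fitness keeps speed representations mutually consistent", {
  u <- c(25, 50, 75, 100)
  v <- 43.79 + 0.0081 * u^2 - 0.4353 * u
  f <- swim_fitness(u, v, ucrit_ms = 0.548, standard_bl_cm = 3.05, rmr = 38.13)
  expect_equal(f$uopt_ms, f$uopt_pct / 100 * f$ucrit_ms, tolerance = 1e-12)
  expect_equal(f$uopt_bls, to_relative_speed(f$uopt_ms, 3.05),
               tolerance = 1e-12)
  expect_equal(f$smr, 43.79, tolerance = 1e-9)
  expect_equal(f$vo2max, predict(f$vo2_curve, 100), tolerance = 1e-12)
  expect_true(f$uopt_pct > 0 && f$uopt_pct < 100)
})
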