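# Generators: determinism, per-fish stream isolation, parameter recovery

test_that("every generator is deterministic under a fixed seed", {
  truth <- synthetic_truth(seed = 5)
  sp <- std_tunnel()
  t1 <- simulate_o2_trace(truth, speed_pct = 50, spec = sp)
  t2 <- simulate_o2_trace(truth, speed_pct = 50, spec = sp)
  expect_identical(t1$oxygen, t2$oxygen)
  expect_identical(simulate_ucrit_trial(truth, jitter_sd = 20),
                   simulate_ucrit_trial(truth, jitter_sd = 20))
  expect_identical(simulate_cohort(truth, 5, 5), simulate_cohort(truth, 5, 5))
  expect_identical(simulate_ct_table(truth, 3), simulate_ct_table(truth, 3))
  # and different seeds give different noise
  other <- synthetic_truth(seed = 6)
  expect_false(identical(simulate_o2_trace(other, speed_pct = 50,
                                           spec = sp)$oxygen, t1$oxygen))
})

test_that("adding a fish never perturbs the others' data", {
  truth <- synthetic_truth(seed = 9)
  small <- simulate_cohort(truth, 4, 4)
  large <- simulate_cohort(truth, 5, 5)
  sub <- large[large$fish_id %in% small$fish_id, ]
  rownames(sub) <- NULL
  expect_identical(small, sub)
  p_small <- simulate_ct_table(truth, 3, genes = "myhz2")
  p_large <- simulate_ct_table(truth, 4, genes = "myhz2")
  keep <- p_large$fish_id %in% p_small$fish_id
  expect_equal(sort(p_large$rep1_ct[keep]), sort(p_small$rep1_ct),
               tolerance = 1e-12)
})

test_that("noiseless trace implies the exact generating slope", {
  truth <- noiseless_truth()
  sp <- std_tunnel()
  tr <- simulate_o2_trace(truth, body_mass = 0.43, speed_pct = 75, spec = sp)
  fit <- fit_decline(tr, sp)
  expect_equal(abs(fit$slope), true_mo2(truth, 75) * 0.43 / sp$volume,
               tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("trace generation guards its domain", {
  truth <- noiseless_truth()
  expect_error(simulate_o2_trace(truth, duration = 3), "duration")
  # a huge fish in a tiny tunnel empties it: truncation warning
  hungry <- noiseless_truth(smr = 500)
  expect_warning(
    simulate_o2_trace(hungry, body_mass = 20, speed_pct = 100,
                      duration = 7200, spec = std_tunnel(volume = 0.5)),
    "truncated")
})

test_that("fatigue trials reproduce the true U_crit exactly", {
  truth <- noiseless_truth(true_ucrit = 0.548)
  trial <- simulate_ucrit_trial(truth)
  expect_equal(nrow(trial), 3L)          # three repeated fatigue events
  est <- ucrit_from_trials(trial)
  expect_equal(est$ucrit_ms, 0.548, tolerance = 1e-12)
  # true U_crit on an interval boundary is handled without error
  edge <- noiseless_truth(true_ucrit = 0.50)
  tr <- simulate_ucrit_trial(edge, n_events = 1)
  expect_true(tr$t_i_s %in% c(0, tr$t_ii_s))
  expect_equal(compute_ucrit(tr$u_i_ms, tr$u_ii_ms, tr$t_i_s, tr$t_ii_s),
               0.50, tolerance = 1e-12)
  expect_error(simulate_ucrit_trial(noiseless_truth(true_ucrit = 0.04)),
               "degenerate")
})

test_that("jittered fatigue times stay unbiased around the true U_crit", {
  ests <- vapply(1:100, function(i) {
    truth <- synthetic_truth(seed = 1000 + i)
    tr <- simulate_ucrit_trial(truth, fish_id = sprintf("j%03d", i),
                               jitter_sd = 30, n_events = 1)
    compute_ucrit(tr$u_i_ms, tr$u_ii_ms, tr$t_i_s, tr$t_ii_s)
  }, numeric(1))
  sem <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.548), 2 * sem + 1e-4)
})

test_that("cohort generator honours zero-effect and default-effect regimes", {
  flat <- synthetic_truth(seed = 3, cohort = list(
    swimmer = list(tl_mean = 3.6, tl_sd = 0, bw_mean = 0.4, bw_sd = 0,
                   d_tl_mean = 0, d_tl_sd = 0, d_bw_mean = 0, d_bw_sd = 0),
    rester = list(tl_mean = 3.6, tl_sd = 0, bw_mean = 0.4, bw_sd = 0,
                  d_tl_mean = 0, d_tl_sd = 0, d_bw_mean = 0, d_bw_sd = 0)))
  co <- simulate_cohort(flat, 3, 3)
  pre <- co[co$stage == "pre", ]
  post <- co[co$stage == "post", ]
  expect_equal(pre$body_weight_g, post$body_weight_g)
  expect_equal(pre$total_tl_cm, post$total_tl_cm)
  # default effects produce a decisive between-group body-weight contrast
  hits <- vapply(1:20, function(s) {
    co <- simulate_cohort(synthetic_truth(seed = s), 78, 79)
    g <- compare_growth(co, "body_weight_g", "unpaired_t_one_tailed",
                        groups = c("swimmer", "rester"), stage = "post",
                        alternative = "greater")
    g$p_value < 1e-5
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  expect_error(simulate_cohort(synthetic_truth(), 1, 5), "at least 2")
})

test_that("ct generator enforces its parameter domain", {
  expect_error(synthetic_truth(true_fold_changes = c(myhz2 = -1)), "positive")
  expect_error(simulate_ct_table(synthetic_truth(), genes = "nosuchgene"),
               "unknown gene")
})
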