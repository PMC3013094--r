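# Triplicate QC, ddCt fold changes, Grubbs screening, Mann-Whitney tests

test_that("triplicate aggregation flags inconsistent replicates", {
  expect_equal(aggregate_triplicates(c(20, 20, 20)),
               list(mean_ct = 20, sd = 0, qc_pass = TRUE))
  ok <- aggregate_triplicates(c(20.0, 20.2, 19.8))
  expect_equal(ok$mean_ct, 20)
  expect_true(ok$qc_pass)
  flagged <- aggregate_triplicates(c(20.0, 22.5, 20.1))  # SD ~1.42 cycles
  expect_false(flagged$qc_pass)
  expect_error(aggregate_triplicates(c(20, 20)), "exactly 3")
  expect_error(aggregate_triplicates(c(20, 20, 45)), "\\(0, 40\\]")
})

test_that("dCt normalisation requires a shared primer set", {
  expect_equal(normalize_dct(25, 20), 5)
  expect_equal(normalize_dct(20, 20), 0)
  expect_equal(normalize_dct(25 + 3, 20 + 3), normalize_dct(25, 20))
  expect_error(normalize_dct(25, 20, target_set = "A",
                             housekeeping_set = "B"), "primer sets")
})

test_that("fold change follows the Livak identities", {
  eq <- fold_change(c(5, 5, 5), c(5, 5, 5))
  expect_equal(eq$fold_change_mean, 1)
  expect_equal(eq$fold_change_sem, 0)
  up <- fold_change(c(4, 4, 4, 4), c(5, 5, 5))   # ddCt = -1 for every fish
  expect_equal(up$fold_change_mean, 2)
  expect_equal(up$fold_change_geometric, 2)
  expect_error(fold_change(c(1), c(2, 3)), "at least 2")
  expect_error(fold_change(c(1, 2), c(2, 3), efficiency = 1), "efficiency")
})

test_that("a single synthetic dataset recovers the true myhz2 fold change", {
  truth <- synthetic_truth(seed = 104, ct_noise_sd = 0.2)
  plates <- simulate_ct_table(truth, n_per_group = 8, genes = "myhz2")
  res <- qpcr_pipeline(plates)
  g <- res$genes[res$genes$gene == "myhz2", ]
  expect_lt(abs(g$fold_change_mean - 7.92), 2 * g$fold_change_sem)
  expect_lt(g$p_value, 0.05)
})

test_that("Grubbs screening removes gross outliers and nothing else", {
  scr <- remove_outliers(c(1, 1.1, 0.9, 1.0, 15))
  expect_equal(scr$removed_indices, 5L)
  expect_equal(scr$removed_values, 15)
  clean <- remove_outliers(c(1.0, 1.05, 0.95, 1.02, 0.98))
  expect_length(clean$removed_indices, 0)
  none <- remove_outliers(c(1, 1.1, 0.9, 1.0, 15), max_removals = 0)
  expect_equal(none$values, c(1, 1.1, 0.9, 1.0, 15))
  expect_warning(small <- remove_outliers(c(1, 2, 100)), "fewer than 4")
  expect_length(small$removed_indices, 0)
  # critical value at n = 5, alpha = 0.05 from the published Grubbs table
  expect_equal(swimfit:::grubbs_critical(5, 0.05), 1.715, tolerance = 1e-3)
})

# exhaustive permutation oracle for the exact Mann-Whitney p value
mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  idx <- utils::combn(length(pooled), n_a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_all <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  u_obs <- u_of(a, b)
  p_low <- mean(u_all <= u_obs + 1e-9)
  p_high <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(p_low, p_high))
}

test_that("Mann-Whitney exact p matches exhaustive enumeration", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_true(res$exact)
  expect_equal(res$p_value, 0.1)        # 2/20 arrangements
  expect_equal(mw_exact_oracle(c(1, 2, 3), c(4, 5, 6)), 0.1)
  set.seed(13)
  for (n_a in 2:6) {
    for (n_b in 2:6) {
      vals <- sample(seq_len(50), n_a + n_b)   # distinct, no ties
      a <- vals[seq_len(n_a)]
      b <- vals[-seq_len(n_a)]
      got <- mann_whitney(a, b)
      expect_true(got$exact)
      expect_equal(got$p_value, mw_exact_oracle(a, b), tolerance = 1e-12,
                   label = sprintf("exact p (n_a=%d, n_b=%d)", n_a, n_b))
    }
  }
})

test_that("Mann-Whitney degenerate and large-sample behaviour", {
  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$u, 8)               # null centre n_a*n_b/2
  expect_gt(same$p_value, 0.95)
  big <- mann_whitney(rnorm(15), rnorm(15))
  expect_false(big$exact)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("fold change of identically distributed groups centres on 1", {
  set.seed(21)
  fcs <- replicate(1000, {
    fold_change(rnorm(8, 5, 0.3), rnorm(8, 5, 0.3))$fold_change_mean
  })
  expect_lt(abs(mean(fcs) - 1), 3 * sd(fcs) / sqrt(length(fcs)) + 0.02)
})

test_that("pipeline is invariant to plate-wide additive Ct shifts", {
  truth <- synthetic_truth(seed = 30)
  plates <- simulate_ct_table(truth, n_per_group = 6,
                              genes = c("ghrb", "myhz2"))
  shifted <- plates
  shifted[, c("rep1_ct", "rep2_ct", "rep3_ct")] <-
    shifted[, c("rep1_ct", "rep2_ct", "rep3_ct")] + 2.5
  a <- qpcr_pipeline(plates)
  b <- qpcr_pipeline(shifted)
  expect_equal(a$genes$fold_change_mean, b$genes$fold_change_mean,
               tolerance = 1e-12)
  expect_equal(a$genes$p_value, b$genes$p_value, tolerance = 1e-12)
})

test_that("noiseless plates return the true fold change for every gene", {
  truth <- noiseless_truth(seed = 2)
  plates <- simulate_ct_table(truth, n_per_group = 4)
  res <- suppressWarnings(qpcr_pipeline(plates))
  fc <- setNames(res$genes$fold_change_mean, res$genes$gene)
  for (g in names(truth$true_fold_changes)) {
    expect_equal(unname(fc[g]), unname(truth$true_fold_changes[[g]]),
                 tolerance = 1e-9, label = paste("fc of", g))
  }
})

test_that("housekeeping stability check flags between-group rps18 shifts", {
  set.seed(17)
  stable <- housekeeping_stability(rnorm(8, 18, 0.1), rnorm(8, 18, 0.1))
  expect_true(stable$stable)
  shifted <- housekeeping_stability(rnorm(8, 18, 0.1), rnorm(8, 20, 0.1))
  expect_false(shifted$stable)
  # and the full pipeline warns on an unstable housekeeping gene
  truth <- synthetic_truth(seed = 31)
  plates <- simulate_ct_table(truth, n_per_group = 6, genes = "myhz2")
  hk <- plates$gene == "rps18" & plates$group == "swimmer"
  plates[hk, c("rep1_ct", "rep2_ct", "rep3_ct")] <-
    plates[hk, c("rep1_ct", "rep2_ct", "rep3_ct")] + 3
  expect_warning(qpcr_pipeline(plates), "rps18")
})
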