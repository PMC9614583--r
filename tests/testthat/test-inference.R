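test_that("paired t test matches the hand formula and handles degeneracy", {
  # identical vectors: no evidence either way
  r0 <- paired_t(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 0.5)

  # diffs (0.1, 0.2, 0.3): t = 0.2 / (0.1 / sqrt(3))
  r <- paired_t(c(0.6, 0.7, 0.8), c(0.5, 0.5, 0.5))
  expect_equal(r$t, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(round(r$t, 3), 3.464)
  expect_equal(r$df, 2)
  # agrees with stats::t.test as oracle
  tt <- t.test(c(0.6, 0.7, 0.8), c(0.5, 0.5, 0.5), paired = TRUE,
               alternative = "greater")
  expect_equal(r$p, tt$p.value)

  # constant nonzero differences: sign convention, not a t value
  rc <- paired_t(c(1, 1, 1, 1), c(0, 0, 0, 0))
  expect_equal(rc$p, 0)
  expect_equal(rc$t, Inf)
  expect_error(paired_t(1:3, 1:2), "equal length")
})

test_that("difference CI matches the closed normal form", {
  # constant vector: zero-width interval
  expect_equal(unname(diff_ci(rep(0.04, 10))), c(0.04, 0.04))

  # frozen closed-form evaluation: mean .05, sd .065, n 10000
  set.seed(51)
  d <- rnorm(10000)
  d <- (d - mean(d)) / sd(d) * 0.065 + 0.05  # exact sample moments
  ci <- diff_ci(d, level = 0.99)
  z <- qnorm(0.995)
  expect_equal(unname(ci),
               c(0.05 - z * 0.065 / 100, 0.05 + z * 0.065 / 100),
               tolerance = 1e-12)
  expect_equal(round(unname(ci), 4), c(0.0483, 0.0517))

  # lo <= hi always; closed-form agreement on random vectors
  for (rep in 1:5) {
    v <- rnorm(50, 0.1, 0.2)
    ci <- diff_ci(v, level = 0.95)
    expect_lte(ci[["lo"]], ci[["hi"]])
    expect_equal(unname(ci),
                 mean(v) + c(-1, 1) * qnorm(0.975) * sd(v) / sqrt(50),
                 tolerance = 1e-12)
  }
  expect_error(diff_ci(d, level = 1.2), "level")
})

test_that("Cohen d is mean over sample SD", {
  expect_equal(cohen_d(c(0.1, 0.2, 0.3)), 2)
  v <- c(-1, 3, 0.5, 2)
  expect_equal(cohen_d(v), mean(v) / sd(v), tolerance = 1e-12)
  expect_error(cohen_d(rep(0, 5)), "zero-variance")
})

test_that("multiplicity corrections behave per method", {
  expect_equal(correct_multiplicity(0.001, "bonferroni", n_tests = 20),
               0.02)
  expect_equal(correct_multiplicity(1, "bonferroni", n_tests = 20), 1)
  expect_equal(correct_multiplicity(1, "sidak", n_tests = 20), 1)
  expect_equal(correct_multiplicity(0.01, "sidak", n_tests = 20),
               1 - 0.99^20, tolerance = 1e-12)
  # monotone: corrected >= uncorrected
  p <- runif(20)
  expect_true(all(correct_multiplicity(p, "bonferroni", 20) >= p))
  expect_true(all(correct_multiplicity(p, "sidak", 20) >= p))

  # max-null add-one rule: observed above all 499 null maxima
  set.seed(52)
  null_mat <- matrix(runif(499 * 3, 0.4, 0.6), 499, 3)
  pc <- correct_multiplicity(rep(NA, 3), "max_null",
                             observed = c(0.7, 0.55, 0.2),
                             null_mat = null_mat)
  expect_equal(pc[1], 1 / 500)
  expect_equal(pc[3], 1)
  # max-null corrected p >= each seed's own empirical p
  own <- vapply(1:3, function(j)
    (1 + sum(null_mat[, j] >= c(0.7, 0.55, 0.2)[j])) / 500, numeric(1))
  expect_true(all(pc >= own))
  expect_error(correct_multiplicity(rep(0.1, 5), "bonferroni",
                                    n_tests = 2), "n_tests")
})

test_that("the three-part selection rule is a strict conjunction", {
  base <- data.frame(seed_id = 1:3,
                     p_corrected = c(0.0009, 0.0009, 0.2),
                     ci_lo = c(0.01, 0.01, 0.01),
                     cohen_d = c(0.76, 0.45, 0.9))
  cfg <- fc_config()
  out <- select_seeds(base, cfg)
  expect_equal(out$selected, c(TRUE, FALSE, FALSE))
  # boundary: CI lower bound exactly 0 fails the strict inequality
  base$ci_lo <- 0
  expect_false(any(select_seeds(base, cfg)$selected))
  # boundary: d exactly at threshold fails
  base$ci_lo <- 0.01; base$cohen_d <- 0.5
  expect_false(any(select_seeds(base, cfg)$selected))
})

test_that("pooled two-sample t matches the hand formula", {
  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(round(r$t, 3), -3.674)
  expect_equal(r$df, 4)
  # identical groups
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  # df = n1 + n2 - 2 always
  set.seed(53)
  x <- rnorm(35); y <- rnorm(63)
  expect_equal(two_sample_t(x, y)$df, 96)
  # oracle: stats::t.test with pooled variance
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(two_sample_t(x, y)$t, unname(tt$statistic))
  expect_equal(two_sample_t(x, y)$p, tt$p.value)
  expect_error(two_sample_t(rep(1, 3), rep(1, 4)), "degenerate")
})

test_that("2x2 chi-squared is uncorrected Pearson", {
  # perfectly proportional table
  expect_equal(chi_square_2x2(10, 20, 20, 40)$chi2, 0)
  # hand evaluation of sum (O-E)^2 / E
  r <- chi_square_2x2(10, 0, 0, 10)
  expect_equal(r$chi2, 20)
  expect_equal(r$df, 1)
  # oracle: stats::chisq.test without continuity correction
  ct <- chisq.test(matrix(c(12, 7, 30, 41), 2, 2, byrow = TRUE),
                   correct = FALSE)
  r2 <- chi_square_2x2(12, 7, 30, 41)
  expect_equal(r2$chi2, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(r2$p, ct$p.value, tolerance = 1e-12)
  expect_error(chi_square_2x2(0, 0, 3, 4), "zero margin")
  expect_error(chi_square_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("cohort table assembles the demographic and motion rows", {
  co <- small_cohort()
  qc <- qc_cohort(co$manifest, fc_config(), motion = co$motion)
  tab <- cohort_table(co$manifest, qc)
  expect_equal(tab$measure,
               c("sex_girls_n", "age_months", "mean_fd_mm", "outlier_pct"))
  expect_equal(tab$df[2], nrow(co$manifest) - 2)
  # identical-distribution groups: modest statistics expected
  expect_true(all(abs(tab$statistic[-1]) < 5))
  # single-group manifest errors
  man1 <- co$manifest[co$manifest$group == "FHD", ]
  expect_error(cohort_table(man1, qc), "both groups")
})

test_that("seed inference integrates distributions into selection", {
  set.seed(54)
  n <- 400
  mk <- function(mu) {
    structure(list(seed_id = 1L,
                   true_acc = rnorm(n, mu, 0.06),
                   null_acc = rnorm(n, 0.5, 0.06),
                   true_sens = rnorm(n, mu, 0.08),
                   null_sens = rnorm(n, 0.5, 0.08),
                   true_spec = rnorm(n, mu, 0.08),
                   null_spec = rnorm(n, 0.5, 0.08),
                   mean_pattern = NULL, mean_weights = NULL,
                   n_iterations = n), class = "fc_seed_dists")
  }
  effect <- mk(0.68); effect$seed_id <- 1L
  null1 <- mk(0.5); null1$seed_id <- 2L
  null2 <- mk(0.5); null2$seed_id <- 3L
  effect$diff <- effect$true_acc - effect$null_acc
  null1$diff <- null1$true_acc - null1$null_acc
  null2$diff <- null2$true_acc - null2$null_acc
  cfg <- fc_config(n_seeds_tested = 3)
  inf <- seed_inference(list(effect, null1, null2), cfg)
  expect_s3_class(inf, "fc_inference")
  expect_equal(inf$selected, c(TRUE, FALSE, FALSE))
  expect_true(all(inf$p_corrected >= inf$p_uncorrected - 1e-12 |
                    inf$p_corrected > 0))
  # recomputation from the same table under stricter d threshold
  cfg2 <- fc_config(n_seeds_tested = 3, d_threshold = 10)
  expect_false(any(select_seeds(inf, cfg2)$selected))
})
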