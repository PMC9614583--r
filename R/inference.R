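#' One-sided paired t test across iterations
#'
#' Tests whether the true-label metric distribution exceeds the paired
#' permutation-null distribution, treating iterations as paired samples.
#'
#' @param true_dist,null_dist equal-length numeric vectors, paired by
#'   iteration.
#' @return list with `t`, `df`, `p` (one-sided, alternative true > null).
#' @export
paired_t <- function(true_dist, null_dist) {
  if (length(true_dist) != length(null_dist))
    stop_fmt("distributions must have equal length")
  n <- length(true_dist)
  if (n < 2) stop_fmt("need at least 2 paired values")
  d <- true_dist - null_dist
  if (sd(d) == 0) {
    # degenerate: direction decided by the (common) sign of the differences
    m <- mean(d)
    t_stat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 0.5 else if (m > 0) 0 else 1
    return(list(t = t_stat, df = n - 1L, p = p))
  }
  tt <- t.test(true_dist, null_dist, paired = TRUE,
               alternative = "greater")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Normal-approximation CI on the mean of a difference distribution
#'
#' `mean(d) +/- z * sd(d)/sqrt(n)` at the requested level: a CI on the
#' *mean* true-minus-null performance difference across iterations. Seed
#' selection requires its lower bound to be above 0.
#'
#' @param diff_dist numeric vector of per-iteration differences.
#' @param level confidence level in (0, 1), default 0.99.
#' @return numeric `c(lo, hi)`.
#' @export
diff_ci <- function(diff_dist, level = 0.99) {
  if (level <= 0 || level >= 1) stop_fmt("level must be in (0, 1)")
  n <- length(diff_dist)
  if (n < 2) stop_fmt("need at least 2 values")
  m <- mean(diff_dist)
  se <- sd(diff_dist) / sqrt(n)
  z <- qnorm((1 + level) / 2)
  c(lo = m - z * se, hi = m + z * se)
}

#' Cohen d of a difference distribution
#'
#' `mean(d) / sd(d)` with the sample (n-1) standard deviation: the
#' standardised size of the true-minus-null performance difference.
#'
#' @param diff_dist numeric vector of per-iteration differences.
#' @return Cohen d.
#' @export
cohen_d <- function(diff_dist) {
  s <- sd(diff_dist)
  if (!is.finite(s) || s == 0)
    stop_fmt("zero-variance difference distribution")
  mean(diff_dist) / s
}

#' Family-wise correction across seed tests
#'
#' `method = "max_null"` performs the Monte-Carlo max-statistic
#' correction: each seed's observed mean true-label metric is referred to
#' the empirical distribution of the per-iteration *maximum* null metric
#' across all tested seeds, with the add-one rule
#' `p = (1 + #\{max_null >= observed\}) / (1 + n_iterations)`.
#' `"bonferroni"` and `"sidak"` adjust the supplied uncorrected p values
#' analytically with `n_tests` comparisons.
#'
#' @param p numeric vector of uncorrected p values (one per seed).
#' @param method `"max_null"`, `"bonferroni"` or `"sidak"`.
#' @param n_tests number of tests in the family (>= number of seeds).
#' @param observed for `"max_null"`: each seed's observed statistic
#'   (mean true metric).
#' @param null_mat for `"max_null"`: iterations x seeds matrix of null
#'   metrics.
#' @return numeric vector of corrected p values.
#' @export
correct_multiplicity <- function(p, method = c("max_null", "bonferroni",
                                               "sidak"),
                                 n_tests = length(p), observed = NULL,
                                 null_mat = NULL) {
  method <- match.arg(method)
  if (n_tests < length(p))
    stop_fmt("n_tests (%d) smaller than number of seeds supplied (%d)",
             n_tests, length(p))
  switch(method,
    bonferroni = pmin(1, p * n_tests),
    sidak = 1 - (1 - p)^n_tests,
    max_null = {
      if (is.null(observed) || is.null(null_mat))
        stop_fmt("max_null correction needs 'observed' and 'null_mat'")
      null_mat <- as.matrix(null_mat)
      if (ncol(null_mat) != length(observed))
        stop_fmt("null_mat columns must match observed length")
      max_null <- apply(null_mat, 1, max)
      n_iter <- length(max_null)
      vapply(observed,
             function(o) (1 + sum(max_null >= o)) / (1 + n_iter),
             numeric(1))
    })
}

metric_triple <- function(true_d, null_d, level) {
  d <- true_d - null_d
  ci <- diff_ci(d, level)
  list(mean_true = mean(true_d),
       mean_diff = mean(d),
       ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
       p = paired_t(true_d, null_d)$p,
       d = if (sd(d) == 0) NA_real_ else cohen_d(d))
}

#' Seed-level inference over all tested seeds
#'
#' Applies, per seed, the paired t test, the difference CI and Cohen d to
#' the accuracy distributions (and the same triple to sensitivity and
#' specificity), corrects the accuracy p values across seeds, and applies
#' the three-part selection rule: a seed exhibits distinct FC patterns iff
#' corrected p < alpha AND the CI lower bound on the accuracy difference
#' is above 0 AND Cohen d exceeds `d_threshold`.
#'
#' @param dist_list list of `fc_seed_dists`, one per tested seed.
#' @param config an [fc_config()].
#' @param atlas optional `fc_atlas` to attach seed names.
#' @return data.frame of class `fc_inference`, one row per seed.
#' @export
seed_inference <- function(dist_list, config = fc_config(), atlas = NULL) {
  stopifnot(length(dist_list) >= 1)
  rows <- lapply(dist_list, function(sd_) {
    acc <- metric_triple(sd_$true_acc, sd_$null_acc, config$ci_level)
    sen <- metric_triple(sd_$true_sens, sd_$null_sens, config$ci_level)
    spe <- metric_triple(sd_$true_spec, sd_$null_spec, config$ci_level)
    data.frame(seed_id = sd_$seed_id,
               mean_true_acc = acc$mean_true, mean_diff = acc$mean_diff,
               ci_lo = acc$ci_lo, ci_hi = acc$ci_hi,
               p_uncorrected = acc$p, cohen_d = acc$d,
               sens = sen$mean_true, sens_ci_lo = sen$ci_lo,
               sens_ci_hi = sen$ci_hi, sens_p = sen$p, sens_d = sen$d,
               spec = spe$mean_true, spec_ci_lo = spe$ci_lo,
               spec_ci_hi = spe$ci_hi, spec_p = spe$p, spec_d = spe$d)
  })
  res <- do.call(rbind, rows)
  res$p_corrected <- correct_multiplicity(
    res$p_uncorrected, config$correction_method,
    n_tests = max(config$n_seeds_tested, nrow(res)),
    observed = res$mean_true_acc,
    null_mat = do.call(cbind, lapply(dist_list, `[[`, "null_acc")))
  res$selected <- (res$p_corrected < config$alpha) &
    (res$ci_lo > 0) & !is.na(res$cohen_d) &
    (res$cohen_d > config$d_threshold)
  if (!is.null(atlas)) {
    res$seed_name <- atlas$regions$name[match(res$seed_id,
                                              atlas$regions$region_id)]
    res <- res[, c("seed_id", "seed_name",
                   setdiff(names(res), c("seed_id", "seed_name")))]
  }
  class(res) <- c("fc_inference", "data.frame")
  res
}

#' Apply the three-part selection rule to an inference table
#'
#' Recomputes the `selected` flags of a seed-inference table under
#' (possibly new) alpha / CI / d thresholds, without re-training.
#'
#' @param results an `fc_inference` data.frame.
#' @param config an [fc_config()].
#' @return the table with `selected` recomputed.
#' @export
select_seeds <- function(results, config = fc_config()) {
  results$selected <- (results$p_corrected < config$alpha) &
    (results$ci_lo > 0) & (results$cohen_d > config$d_threshold)
  results
}

#' Pooled-variance two-sample t test
#'
#' Student t with pooled variance, df = n1 + n2 - 2, two-sided p; the
#' convention behind the cohort table's group comparisons.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop_fmt("each group needs at least 2 values")
  if (sd(x) == 0 && sd(y) == 0)
    stop_fmt("degenerate variance in both groups")
  tt <- t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' No continuity correction, df = 1. Cell order: `a, b` = first row,
#' `c, d` = second row.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return list with `chi2`, `df`, `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop_fmt("counts must be non-negative integers")
  tab <- matrix(cnt, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_fmt("zero margin in 2x2 table")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Cohort demographics and head-movement table
#'
#' Group mean (SD) of age, mean FD after outlier removal and outlier
#' percentage, sex counts, with pooled-variance t statistics (chi-squared
#' for sex) and two-sided p values.
#'
#' @param manifest manifest data.frame.
#' @param qc data.frame from [qc_cohort()] (NULL to omit motion rows).
#' @return data.frame of class `fc_cohort_table`: one row per measure.
#' @export
cohort_table <- function(manifest, qc = NULL) {
  groups <- unique(manifest$group)
  if (length(groups) < 2)
    stop_fmt("cohort table needs both groups, found: %s",
             paste(groups, collapse = ", "))
  g_fhd <- manifest$group == "FHD"
  fmt_row <- function(measure, x_fhd, x_ctl) {
    ts <- two_sample_t(x_fhd, x_ctl)
    data.frame(measure = measure,
               fhd_mean = mean(x_fhd), fhd_sd = sd(x_fhd),
               control_mean = mean(x_ctl), control_sd = sd(x_ctl),
               statistic = ts$t, df = ts$df, p = ts$p,
               stringsAsFactors = FALSE)
  }
  sex_counts <- table(factor(manifest$group, c("FHD", "control")),
                      factor(manifest$sex, c("F", "M")))
  cs <- chi_square_2x2(sex_counts["FHD", "F"], sex_counts["FHD", "M"],
                       sex_counts["control", "F"], sex_counts["control", "M"])
  rows <- list(data.frame(measure = "sex_girls_n",
                          fhd_mean = sex_counts["FHD", "F"], fhd_sd = NA,
                          control_mean = sex_counts["control", "F"],
                          control_sd = NA, statistic = cs$chi2, df = cs$df,
                          p = cs$p, stringsAsFactors = FALSE),
               fmt_row("age_months", manifest$age_months[g_fhd],
                       manifest$age_months[!g_fhd]))
  if (!is.null(qc)) {
    q_fhd <- qc$group == "FHD"
    rows <- c(rows,
              list(fmt_row("mean_fd_mm", qc$mean_fd_after_removal[q_fhd],
                           qc$mean_fd_after_removal[!q_fhd]),
                   fmt_row("outlier_pct", qc$outlier_pct[q_fhd],
                           qc$outlier_pct[!q_fhd])))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("fc_cohort_table", "data.frame")
  out
}
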