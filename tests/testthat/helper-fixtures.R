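# Shared fixtures, built in code at test time.

toy_atlas <- function() {
  atlas(region_id = 1:4,
        name = c("front_L", "front_R", "occ_L", "occ_R"),
        hemisphere = c("L", "R", "L", "R"),
        is_seed = c(TRUE, FALSE, TRUE, FALSE))
}

# Feature table built directly from Gaussian features (no time series):
# fast input for classifier/engine tests. `shift` adds a group mean
# difference to the first `n_shift` features of the FHD group.
gaussian_feature_table <- function(n_fhd = 35, n_control = 63, p = 20,
                                   shift = 0, n_shift = 0, sd = 0.12,
                                   seed = 1) {
  set.seed(seed)
  n <- n_fhd + n_control
  X <- matrix(rnorm(n * p, mean = 0.3, sd = sd), n, p)
  if (n_shift > 0)
    X[seq_len(n_fhd), seq_len(n_shift)] <-
      X[seq_len(n_fhd), seq_len(n_shift)] + shift
  ids <- sprintf("s%03d", seq_len(n))
  colnames(X) <- sprintf("feat_%02d", seq_len(p))
  rownames(X) <- ids
  labels <- c(rep("FHD", n_fhd), rep("control", n_control))
  structure(list(seed_id = 99L, X = X, labels = labels,
                 subject_ids = ids,
                 covariates = data.frame(
                   age_months = round(runif(n, 4, 13), 1),
                   sex = sample(c("F", "M"), n, replace = TRUE)),
                 feature_map = data.frame(feature_index = seq_len(p),
                                          region_id = 100L + seq_len(p),
                                          name = colnames(X))),
            class = "fc_feature_table")
}

# Small synthetic cohort wrapper with reduced dimensions.
small_cohort <- function(n_fhd = 10, n_control = 18, R = 20, T_frames = 60,
                         n_seeds = 3, effect = NULL, rng_seed = 123) {
  generate_cohort(cohort_spec(n_fhd = n_fhd, n_control = n_control, R = R,
                              T_frames = T_frames, n_seeds = n_seeds,
                              effect = effect, rng_seed = rng_seed))
}
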