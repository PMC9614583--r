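test_that("balanced subsampling is uniform without replacement", {
  pool <- sprintf("c%02d", 1:63)
  # forced full pool
  expect_setequal(draw_balanced_subsample(pool[1:35], 35), pool[1:35])
  expect_error(draw_balanced_subsample(pool[1:10], 11), "pool")
  # reproducible under a fixed RNG state
  set.seed(41); s1 <- draw_balanced_subsample(pool, 35)
  set.seed(41); s2 <- draw_balanced_subsample(pool, 35)
  expect_identical(s1, s2)
  expect_length(unique(s1), 35)
  # inclusion frequency ~ 35/63 (binomial sampling oracle)
  set.seed(42)
  n_draw <- 4000
  counts <- integer(63); names(counts) <- pool
  for (i in seq_len(n_draw)) {
    s <- draw_balanced_subsample(pool, 35)
    counts[s] <- counts[s] + 1
  }
  p <- 35 / 63
  se <- sqrt(p * (1 - p) / n_draw)
  expect_true(all(abs(counts / n_draw - p) < 4 * se))
})

test_that("pairing is a perfect matching", {
  f <- sprintf("f%02d", 1:35); c_ <- sprintf("c%02d", 1:35)
  set.seed(43)
  pr <- make_pairs(f, c_)
  expect_equal(nrow(pr), 35)
  expect_setequal(pr$fhd, f)
  expect_setequal(pr$control, c_)
  expect_setequal(c(pr$fhd, pr$control), c(f, c_))
  expect_equal(nrow(make_pairs("f1", "c1")), 1)
  expect_error(make_pairs(f, c_[1:10]), "equal size")
})

test_that("leave-one-pair-out folds partition the balanced sample", {
  set.seed(44)
  pr <- make_pairs(sprintf("f%02d", 1:35), sprintf("c%02d", 1:35))
  folds <- leave_one_pair_out_folds(pr)
  expect_length(folds, 35)
  for (fl in folds) {
    expect_length(fl$test, 2)
    expect_length(fl$train, 68)
    expect_length(intersect(fl$train, fl$test), 0)
    # one subject per group in every test set
    expect_equal(sum(grepl("^f", fl$test)), 1)
  }
  # every subject appears in exactly one test set
  all_test <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(all_test, c(pr$fhd, pr$control))
  expect_equal(anyDuplicated(all_test), 0)
  expect_error(leave_one_pair_out_folds(pr[1, ]), "2 pairs")
})

test_that("stratified k-fold folds balance group counts", {
  ids <- sprintf("s%02d", 1:70)
  labels <- rep(c("FHD", "control"), each = 35)
  set.seed(45)
  folds <- kfold_folds(ids, labels, k = 5)
  expect_length(folds, 5)
  for (fl in folds) {
    expect_length(fl$test, 14)
    expect_equal(sum(labels[match(fl$test, ids)] == "FHD"), 7)
  }
  expect_setequal(unlist(lapply(folds, `[[`, "test")), ids)
  expect_error(kfold_folds(ids, labels, k = 1), "at least 2")
  expect_error(kfold_folds(ids[1:6], labels[c(1:3, 36:38)], k = 5),
               "smallest group")
})

test_that("label permutation preserves counts and is uniform", {
  labels <- rep(c("FHD", "control"), each = 35)
  set.seed(46)
  keep_first <- 0
  n_draw <- 2000
  for (i in seq_len(n_draw)) {
    p <- permute_labels(labels)
    expect_equal(sum(p == "FHD"), 35)
    if (p[1] == "FHD") keep_first <- keep_first + 1
  }
  # P(any fixed subject keeps its label) = 0.5 (combinatorial oracle)
  expect_equal(keep_first / n_draw, 0.5,
               tolerance = 4 * sqrt(0.25 / n_draw) / 0.5)
  set.seed(47); p1 <- permute_labels(labels)
  set.seed(47); p2 <- permute_labels(labels)
  expect_identical(p1, p2)
})

test_that("covariate residualisation removes training-fitted effects", {
  set.seed(48)
  n <- 40; p <- 6
  age <- runif(n, 4, 13)
  # X exactly linear in age: residuals vanish on training rows
  slope <- rnorm(p)
  X <- outer(age, slope) + 1
  adj <- residualize_covariates(X[1:30, ], X[31:40, ],
                                matrix(age[1:30]), matrix(age[31:40]))
  expect_lt(max(abs(adj$X_train)), 1e-10)
  expect_lt(max(abs(adj$X_test)), 1e-10)

  # closed-form regression oracle on noisy data
  Xn <- X + matrix(rnorm(n * p, sd = 0.1), n, p)
  adj2 <- residualize_covariates(Xn[1:30, ], Xn[31:40, ],
                                 matrix(age[1:30]), matrix(age[31:40]))
  D <- cbind(1, age[1:30])
  beta <- solve(t(D) %*% D, t(D) %*% Xn[1:30, ])
  expect_equal(adj2$X_train, Xn[1:30, ] - D %*% beta, tolerance = 1e-10)
  expect_equal(adj2$X_test,
               Xn[31:40, ] - cbind(1, age[31:40]) %*% beta,
               tolerance = 1e-10)

  # a covariate orthogonal to the (centred) features gets a zero slope:
  # residualisation reduces to plain column centring
  v <- rnorm(30); v <- v - mean(v)
  Xo <- Xn[1:30, ]
  Xo <- Xo - outer(v, colSums(sweep(Xo, 2, colMeans(Xo)) * v) / sum(v^2))
  adj3 <- residualize_covariates(Xo, Xn[31:40, ], matrix(v),
                                 matrix(rnorm(10)))
  expect_equal(adj3$X_train, sweep(Xo, 2, colMeans(Xo)),
               tolerance = 1e-10)
  # rank-deficient design (duplicated covariate) errors
  expect_error(residualize_covariates(Xn[1:30, ], Xn[31:40, ],
                                      cbind(age[1:30], age[1:30]),
                                      cbind(age[31:40], age[31:40])),
               "rank-deficient")
})

test_that("one iteration is deterministic and detects a huge effect", {
  ft <- gaussian_feature_table(n_fhd = 20, n_control = 30, p = 15,
                               shift = 2, n_shift = 10, sd = 0.1)
  cfg <- fc_config(n_iterations = 1, rng_seed = 1)
  it1 <- run_iteration(ft, cfg, seed = 77)
  it2 <- run_iteration(ft, cfg, seed = 77)
  expect_identical(it1, it2)
  expect_gte(it1$true_acc, 0.95)
  expect_length(it1$weights, 15)
  expect_length(it1$control_subset, 20)
  expect_true(all(it1$control_subset %in%
                    ft$subject_ids[ft$labels == "control"]))
})

test_that("pre-randomised labels yield chance-level accuracy", {
  # a single fixed cohort retains some accidental separability, so the
  # chance property is asserted on the average over independent
  # relabelings of the same features
  ft <- gaussian_feature_table(n_fhd = 18, n_control = 30, p = 10,
                               seed = 5)
  set.seed(49)
  accs <- replicate(10, {
    ft$labels <- sample(ft$labels)
    cfg <- fc_config(n_iterations = 30,
                     rng_seed = sample.int(1e6, 1))
    mean(run_seed_classification(ft, cfg)$true_acc)
  })
  expect_equal(mean(accs), 0.5, tolerance = 0.03)
})

test_that("seed-level distributions are paired, bounded and reproducible", {
  ft <- gaussian_feature_table(n_fhd = 12, n_control = 20, p = 8,
                               seed = 6)
  cfg <- fc_config(n_iterations = 3, rng_seed = 11)
  d <- run_seed_classification(ft, cfg)
  expect_length(d$true_acc, 3)
  expect_true(all(d$true_acc >= 0 & d$true_acc <= 1))
  expect_true(all(d$null_acc >= 0 & d$null_acc <= 1))
  expect_true(all(d$true_sens >= 0 & d$true_sens <= 1))
  # paired difference is elementwise
  expect_equal(d$diff, d$true_acc - d$null_acc)
  # full determinism under the master seed
  d2 <- run_seed_classification(ft, cfg)
  expect_identical(d, d2)

  # distributions persist and read back identically
  p <- withr::local_tempfile(fileext = ".tsv")
  write_seed_dists(d, p)
  d3 <- read_seed_dists(p, d$seed_id)
  expect_equal(d3$true_acc, d$true_acc)
  expect_equal(d3$diff, d$diff)
})

test_that("permutation null is centred at chance on null data", {
  ft <- gaussian_feature_table(n_fhd = 15, n_control = 25, p = 10,
                               seed = 8)
  cfg <- fc_config(n_iterations = 500, rng_seed = 13)
  d <- run_seed_classification(ft, cfg)
  expect_equal(mean(d$null_acc), 0.5, tolerance = 0.02)
})

test_that("5-fold CV and covariate residualisation variants run", {
  ft <- gaussian_feature_table(n_fhd = 15, n_control = 25, p = 8,
                               shift = 0.4, n_shift = 4, seed = 9)
  cfg_k <- fc_config(n_iterations = 25, rng_seed = 17,
                     cv_scheme = "kfold5")
  dk <- run_seed_classification(ft, cfg_k)
  expect_gt(mean(dk$true_acc), 0.7)
  cfg_cov <- fc_config(n_iterations = 10, rng_seed = 19,
                       covariates = "age_months")
  dc <- run_seed_classification(ft, cfg_cov)
  expect_true(all(is.finite(dc$true_acc)))
  expect_gt(mean(dc$true_acc), 0.7)
})
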