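# Labels are coded internally as +1 = FHD (positive class), -1 = control.
label_to_y <- function(labels) {
  if (!all(labels %in% c("FHD", "control")))
    stop_fmt("labels must be 'FHD' or 'control'")
  ifelse(labels == "FHD", 1, -1)
}

#' Draw a balanced control subsample
#'
#' One bootstrap step of the balanced-sample construction: `n` ids drawn
#' uniformly without replacement from the control pool, to be combined
#' with the full smaller group. Uses the current RNG state.
#'
#' @param control_ids character vector of control subject ids.
#' @param n subsample size (typically the FHD group size).
#' @return character vector of `n` ids.
#' @export
draw_balanced_subsample <- function(control_ids, n) {
  if (n > length(control_ids))
    stop_fmt("requested %d controls from a pool of %d", n,
             length(control_ids))
  control_ids[sample.int(length(control_ids), n)]
}

#' Randomly pair FHD with control subjects
#'
#' Builds the perfect matching that defines leave-one-pair-out folds: each
#' FHD subject is paired with exactly one control. The matching is drawn
#' uniformly at random (no covariate matching), fresh per iteration.
#'
#' @param fhd_ids,control_ids equal-length id vectors.
#' @return data.frame with columns `fhd`, `control`, one row per pair.
#' @export
make_pairs <- function(fhd_ids, control_ids) {
  if (length(fhd_ids) != length(control_ids))
    stop_fmt("groups must have equal size to pair (%d vs %d)",
             length(fhd_ids), length(control_ids))
  data.frame(fhd = fhd_ids,
             control = control_ids[sample.int(length(control_ids))],
             stringsAsFactors = FALSE)
}

#' Leave-one-pair-out cross-validation folds
#'
#' One fold per pair: the held-out test set is that pair (one subject per
#' group), the training set is every other subject.
#'
#' @param pairs data.frame from [make_pairs()].
#' @return list of folds, each a list with `train` and `test` id vectors.
#' @export
leave_one_pair_out_folds <- function(pairs) {
  if (nrow(pairs) < 2) stop_fmt("need at least 2 pairs")
  all_ids <- c(pairs$fhd, pairs$control)
  lapply(seq_len(nrow(pairs)), function(i) {
    test <- c(pairs$fhd[i], pairs$control[i])
    list(train = setdiff(all_ids, test), test = test)
  })
}

#' Stratified k-fold cross-validation folds
#'
#' Randomly partitions each group into k folds so every fold's group
#' counts differ by at most one from perfect balance.
#'
#' @param ids subject ids.
#' @param labels group labels aligned with `ids`.
#' @param k number of folds (default 5).
#' @return list of folds, each with `train` and `test` id vectors.
#' @export
kfold_folds <- function(ids, labels, k = 5) {
  if (k < 2) stop_fmt("k must be at least 2")
  counts <- table(labels)
  if (k > min(counts))
    stop_fmt("k = %d exceeds smallest group size (%d)", k, min(counts))
  fold_of <- integer(length(ids))
  for (g in names(counts)) {
    idx <- which(labels == g)
    fold_of[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  lapply(seq_len(k), function(f) {
    list(train = ids[fold_of != f], test = ids[fold_of == f])
  })
}

#' Permute group labels
#'
#' Uniform random permutation of the label vector; group counts are
#' preserved exactly. This is the within-iteration null: the identical CV
#' is re-run on the same subsample and folds with these labels.
#'
#' @param labels character label vector.
#' @return permuted label vector.
#' @export
permute_labels <- function(labels) {
  labels[sample.int(length(labels))]
}

#' Residualise features on covariates
#'
#' Per-feature least-squares regression of X on the covariates, fitted on
#' the training rows only; both training and test features are replaced by
#' their residuals under the training fit (the test set never influences
#' the adjustment).
#'
#' @param X_train,X_test numeric feature matrices.
#' @param cov_train,cov_test numeric covariate matrices (same columns).
#' @return list with adjusted `X_train` and `X_test`.
#' @export
residualize_covariates <- function(X_train, X_test, cov_train, cov_test) {
  cov_train <- as.matrix(cov_train)
  cov_test <- as.matrix(cov_test)
  if (ncol(cov_train) != ncol(cov_test))
    stop_fmt("covariate matrices must have matching columns")
  D_train <- cbind(1, cov_train)
  if (qr(D_train)$rank < ncol(D_train))
    stop_fmt("rank-deficient covariate design")
  beta <- lm.fit(D_train, X_train)$coefficients
  beta <- matrix(beta, ncol = ncol(X_train))
  list(X_train = X_train - D_train %*% beta,
       X_test = X_test - cbind(1, cov_test) %*% beta)
}

#' Train a linear soft-margin SVM
#'
#' Linear C-SVC with default cost C = 1 and no feature scaling; FHD is the
#' positive class. The default engine is the package's SMO solver
#' (compiled); `engine = "e1071"` routes the identical problem through
#' LIBSVM via e1071 and is used as an independent cross-check.
#'
#' @param X N x p feature matrix.
#' @param labels length-N labels in `{"FHD", "control"}`.
#' @param C soft-margin cost.
#' @param engine `"smo"` (default) or `"e1071"`.
#' @param eps KKT convergence tolerance of the SMO solver.
#' @return list of class `fc_svm`: `weights` (length p), `bias`, oriented
#'   so the decision score `w.x + b` is positive for FHD.
#' @export
train_linear_classifier <- function(X, labels, C = 1,
                                    engine = c("smo", "e1071"),
                                    eps = 1e-3) {
  engine <- match.arg(engine)
  X <- as.matrix(X)
  y <- label_to_y(labels)
  if (length(unique(y)) < 2)
    stop_fmt("training data contains a single class")
  if (!all(is.finite(X))) stop_fmt("non-finite features")
  if (engine == "smo") {
    fit <- .svm_train_cpp(X, y, C, eps, 500000L)
    w <- as.vector(fit$w)
    b <- fit$b
  } else {
    yf <- factor(labels, levels = c("control", "FHD"))
    fit <- e1071::svm(x = X, y = yf, kernel = "linear", cost = C,
                      scale = FALSE, tolerance = eps)
    # libsvm orients decision values toward the class it saw first;
    # read the orientation off the decision-value column name and flip
    # so positive scores mean FHD.
    dv <- attr(predict(fit, X, decision.values = TRUE),
               "decision.values")
    pos_class <- strsplit(colnames(dv), "/")[[1]][1]
    w <- as.vector(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    if (pos_class != "FHD") {
      w <- -w
      b <- -b
    }
  }
  names(w) <- colnames(X)
  structure(list(weights = w, bias = b, C = C, engine = engine),
            class = "fc_svm")
}

#' Decision scores and predicted labels of a linear classifier
#' @param object an `fc_svm` fit.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return character vector of predicted labels; scores as attribute
#'   `"score"`. Ties (score exactly 0) go to control.
#' @export
predict.fc_svm <- function(object, newdata, ...) {
  score <- as.vector(as.matrix(newdata) %*% object$weights + object$bias)
  out <- ifelse(score > 0, "FHD", "control")
  attr(out, "score") <- score
  out
}

# Fold-aggregated CV metrics for one label assignment. Fold structure is
# expressed as an integer fold id per row; prediction runs in compiled
# code. Sensitivity = proportion of FHD test members called FHD;
# specificity = proportion of control test members called control.
cv_metrics <- function(X, y, fold_id, C, eps = 1e-3, cov = NULL,
                       standardize = FALSE) {
  if (is.null(cov) && !standardize) {
    pred <- as.vector(.svm_cv_predict_cpp(X, y, as.integer(fold_id), C, eps,
                                          500000L))
  } else {
    pred <- numeric(length(y))
    for (f in sort(unique(fold_id))) {
      tr <- fold_id != f
      Xtr <- X[tr, , drop = FALSE]
      Xte <- X[!tr, , drop = FALSE]
      if (!is.null(cov)) {
        adj <- residualize_covariates(Xtr, Xte, cov[tr, , drop = FALSE],
                                      cov[!tr, , drop = FALSE])
        Xtr <- adj$X_train
        Xte <- adj$X_test
      }
      if (standardize) {
        mu <- colMeans(Xtr)
        sg <- apply(Xtr, 2, sd)
        sg[sg == 0] <- 1
        Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
        Xte <- sweep(sweep(Xte, 2, mu), 2, sg, "/")
      }
      fit <- .svm_train_cpp(Xtr, y[tr], C, eps, 500000L)
      sc <- as.vector(Xte %*% fit$w + fit$b)
      pred[!tr] <- ifelse(sc > 0, 1, -1)
    }
  }
  list(acc = mean(pred == y),
       sens = mean(pred[y == 1] == 1),
       spec = mean(pred[y == -1] == -1))
}

#' One bootstrap iteration of the classification loop
#'
#' Performs, for a single seed's feature table: (a) draw a balanced
#' control subsample; (b) build CV folds (random pairing for
#' leave-one-pair-out, stratified assignment for 5-fold); (c) estimate
#' cross-validated accuracy/sensitivity/specificity under the true labels;
#' (d) re-run the identical CV (same subsample, same folds) with permuted
#' labels to obtain the paired null metrics; (e) retrain on the full
#' balanced sample to obtain the weight vector and its Haufe forward-model
#' activation pattern.
#'
#' @param ft an `fc_feature_table`.
#' @param config an [fc_config()].
#' @param seed integer seed for this iteration's randomness (subsample,
#'   pairing/folds, permutation).
#' @return list of class `fc_iteration`: `control_subset`, `true_acc`,
#'   `null_acc`, `true_sens`, `true_spec`, `null_sens`, `null_spec`,
#'   `weights`, `bias`, `pattern`.
#' @export
run_iteration <- function(ft, config = fc_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lab <- ft$labels
  fhd_ids <- ft$subject_ids[lab == "FHD"]
  ctl_ids <- ft$subject_ids[lab == "control"]
  if (length(fhd_ids) < 2 || length(ctl_ids) < 2)
    stop_fmt("need at least 2 subjects per group")
  n_bal <- config$balance_n %||% min(length(fhd_ids), length(ctl_ids))
  ctl_sub <- draw_balanced_subsample(ctl_ids, n_bal)
  fhd_sub <- if (length(fhd_ids) > n_bal)
    draw_balanced_subsample(fhd_ids, n_bal) else fhd_ids

  ids <- c(fhd_sub, ctl_sub)
  idx <- match(ids, ft$subject_ids)
  X <- ft$X[idx, , drop = FALSE]
  labels <- lab[idx]
  y <- label_to_y(labels)

  cov <- NULL
  if (!is.null(config$covariates)) {
    cov <- covariate_matrix(ft, config$covariates)[idx, , drop = FALSE]
  }

  # True-label CV, then the paired permutation null: same subjects, same
  # procedure, but the labels are randomly reassigned and the fold
  # construction is re-run on them, so the null CV is exactly the
  # procedure a permuted dataset would have received.
  fold_id <- make_fold_ids(ids, labels, config$cv_scheme)
  true_m <- cv_metrics(X, y, fold_id, config$svm_cost, cov = cov,
                       standardize = config$standardize)
  perm <- permute_labels(labels)
  fold_perm <- make_fold_ids(ids, perm, config$cv_scheme)
  null_m <- cv_metrics(X, label_to_y(perm), fold_perm, config$svm_cost,
                       cov = cov, standardize = config$standardize)

  fit <- train_linear_classifier(X, labels, C = config$svm_cost)
  structure(list(control_subset = ctl_sub,
                 true_acc = true_m$acc, null_acc = null_m$acc,
                 true_sens = true_m$sens, true_spec = true_m$spec,
                 null_sens = null_m$sens, null_spec = null_m$spec,
                 weights = fit$weights, bias = fit$bias,
                 pattern = haufe_pattern(fit$weights, X)),
            class = "fc_iteration")
}

# Integer fold id per subject for a given label assignment: random
# FHD-control pairing for leave-one-pair-out, stratified assignment for
# 5-fold. Consumes RNG state.
make_fold_ids <- function(ids, labels, cv_scheme) {
  if (cv_scheme == "leave_one_pair_out") {
    pairs <- make_pairs(ids[labels == "FHD"], ids[labels == "control"])
    folds <- leave_one_pair_out_folds(pairs)
  } else {
    folds <- kfold_folds(ids, labels, k = 5)
  }
  fold_id <- integer(length(ids))
  for (f in seq_along(folds))
    fold_id[match(folds[[f]]$test, ids)] <- f
  fold_id
}

covariate_matrix <- function(ft, covariates) {
  cols <- lapply(covariates, function(v) {
    x <- ft$covariates[[v]]
    if (is.null(x)) stop_fmt("unknown covariate: %s", v)
    if (!is.numeric(x)) x <- as.numeric(factor(x))
    x
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  m
}

#' Full bootstrapped classification for one seed
#'
#' Repeats [run_iteration()] `config$n_iterations` times and collects the
#' paired true/null metric distributions and the mean Haufe pattern.
#' Per-iteration child seeds are derived deterministically from
#' `config$rng_seed` (and the seed region id), so the result is fully
#' reproducible and independent of execution order.
#'
#' @param ft an `fc_feature_table`.
#' @param config an [fc_config()].
#' @return list of class `fc_seed_dists`: `seed_id`, vectors `true_acc`,
#'   `null_acc`, `diff` (= true - null, paired by iteration), `true_sens`,
#'   `null_sens`, `true_spec`, `null_spec`, matrices-free summaries
#'   `mean_pattern` and `mean_weights`, and `n_iterations`.
#' @export
run_seed_classification <- function(ft, config = fc_config()) {
  n <- config$n_iterations
  seeds <- derive_seeds(config$rng_seed, n, stream = as.integer(ft$seed_id))
  true_acc <- null_acc <- numeric(n)
  true_sens <- null_sens <- true_spec <- null_spec <- numeric(n)
  pat_sum <- numeric(ncol(ft$X))
  w_sum <- numeric(ncol(ft$X))
  for (i in seq_len(n)) {
    it <- run_iteration(ft, config, seed = seeds[i])
    true_acc[i] <- it$true_acc
    null_acc[i] <- it$null_acc
    true_sens[i] <- it$true_sens
    null_sens[i] <- it$null_sens
    true_spec[i] <- it$true_spec
    null_spec[i] <- it$null_spec
    pat_sum <- pat_sum + it$pattern
    w_sum <- w_sum + it$weights
  }
  structure(list(seed_id = ft$seed_id,
                 true_acc = true_acc, null_acc = null_acc,
                 diff = true_acc - null_acc,
                 true_sens = true_sens, null_sens = null_sens,
                 true_spec = true_spec, null_spec = null_spec,
                 mean_pattern = stats::setNames(pat_sum / n, colnames(ft$X)),
                 mean_weights = stats::setNames(w_sum / n, colnames(ft$X)),
                 n_iterations = n),
            class = "fc_seed_dists")
}

#' @export
print.fc_seed_dists <- function(x, ...) {
  cat(sprintf("<fc_seed_dists> seed %s: %d iterations, mean true acc %.3f, mean null acc %.3f\n",
              x$seed_id, x$n_iterations, mean(x$true_acc),
              mean(x$null_acc)))
  invisible(x)
}

#' Persist per-seed distributions as TSV
#'
#' One row per iteration with the paired true/null metrics, so inference
#' can be re-run (e.g. with a different alpha) without re-training.
#'
#' @param dists an `fc_seed_dists`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_seed_dists <- function(dists, path) {
  df <- data.frame(iteration = seq_len(dists$n_iterations),
                   true_acc = dists$true_acc, null_acc = dists$null_acc,
                   diff = dists$diff,
                   true_sens = dists$true_sens, null_sens = dists$null_sens,
                   true_spec = dists$true_spec, null_spec = dists$null_spec)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back persisted per-seed distributions
#' @param path TSV written by [write_seed_dists()].
#' @param seed_id seed region id to attach.
#' @param mean_pattern optional mean pattern vector to attach.
#' @return an `fc_seed_dists` (without weights/pattern unless supplied).
#' @export
read_seed_dists <- function(path, seed_id, mean_pattern = NULL) {
  df <- read.delim(path)
  structure(list(seed_id = seed_id,
                 true_acc = df$true_acc, null_acc = df$null_acc,
                 diff = df$diff,
                 true_sens = df$true_sens, null_sens = df$null_sens,
                 true_spec = df$true_spec, null_spec = df$null_spec,
                 mean_pattern = mean_pattern, mean_weights = NULL,
                 n_iterations = nrow(df)),
            class = "fc_seed_dists")
}
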