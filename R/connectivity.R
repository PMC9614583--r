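#' Fisher z transformation of a correlation coefficient
#'
#' `atanh(r)` after clamping `r` to +/- (1 - 1e-7), so that perfectly
#' correlated (degenerate) inputs map to a large finite z rather than
#' infinity. Vectorised.
#'
#' @param r correlation value(s) in \[-1, 1\].
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) > 1))
    stop_fmt("correlations must be finite and within [-1, 1]")
  lim <- 1 - 1e-7
  atanh(pmin(lim, pmax(-lim, r)))
}

#' Seed-based FC pattern for one subject
#'
#' Pearson-correlates the seed region's time series with every other
#' region's and Fisher-transforms the coefficients. The result is the
#' length-(R-1) feature vector used by the classifier; entries follow
#' atlas order and exclude the seed's self-correlation.
#'
#' @param ts T x R time-series matrix in atlas order (see
#'   [read_timeseries()]).
#' @param atlas an `fc_atlas`.
#' @param seed_id region id of the seed.
#' @param scrub_mask optional logical length-T vector; only TRUE frames
#'   enter the correlations (at least 3 required).
#' @return named numeric vector of length R-1 (names = target regions).
#' @export
seed_fc_pattern <- function(ts, atlas, seed_id, scrub_mask = NULL) {
  ts <- validate_timeseries(as.matrix(ts), atlas)
  seed_idx <- match(seed_id, atlas$regions$region_id)
  if (is.na(seed_idx)) stop_fmt("seed_id %s not in atlas", seed_id)
  if (!is.null(scrub_mask)) {
    if (length(scrub_mask) != nrow(ts))
      stop_fmt("scrub_mask length != frame count")
    ts <- ts[scrub_mask, , drop = FALSE]
    if (nrow(ts) < 3)
      stop_fmt("fewer than 3 frames retained after scrubbing")
  }
  sds <- apply(ts, 2, sd)
  if (any(sds == 0))
    stop_fmt("zero-variance region time series: %s",
             paste(colnames(ts)[sds == 0], collapse = ", "))
  r <- as.vector(cor(ts[, seed_idx], ts[, -seed_idx, drop = FALSE]))
  z <- fisher_z(r)
  names(z) <- colnames(ts)[-seed_idx]
  z
}

#' Assemble the per-seed feature table for a cohort
#'
#' One row per subject (manifest order): the subject's seed FC pattern.
#' Together with the group labels this is the complete input to the
#' classification engine for one seed.
#'
#' @param manifest manifest data.frame.
#' @param atlas an `fc_atlas`.
#' @param seed_id seed region id.
#' @param data_dir directory against which relative `timeseries_ref` paths
#'   are resolved.
#' @param series optional named list of in-memory T x R matrices keyed by
#'   subject_id; takes precedence over file refs.
#' @param scrub optional named list of logical scrub masks (see
#'   [scrub_masks()]).
#' @return list of class `fc_feature_table`: `seed_id`, `X`
#'   (N x (R-1) matrix), `labels` (character), `subject_ids`,
#'   `covariates` (data.frame of age/sex from the manifest),
#'   `feature_map` (see [seed_feature_map()]).
#' @export
build_feature_table <- function(manifest, atlas, seed_id, data_dir = ".",
                                series = NULL, scrub = NULL) {
  if (nrow(manifest) == 0) stop_fmt("empty manifest")
  fmap <- seed_feature_map(atlas, seed_id)
  X <- matrix(NA_real_, nrow(manifest), nrow(fmap),
              dimnames = list(manifest$subject_id, fmap$name))
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    ts <- if (!is.null(series) && sid %in% names(series)) {
      validate_timeseries(series[[sid]], atlas, context = sid)
    } else {
      path <- file.path(data_dir, manifest$timeseries_ref[i])
      if (!file.exists(path))
        stop_fmt("subject %s: time-series file not found: %s", sid, path)
      tryCatch(read_timeseries(path, atlas),
               error = function(e) stop_fmt("subject %s: %s", sid,
                                            conditionMessage(e)))
    }
    mask <- if (!is.null(scrub)) scrub[[sid]] else NULL
    X[i, ] <- tryCatch(seed_fc_pattern(ts, atlas, seed_id, mask),
                       error = function(e) stop_fmt("subject %s: %s", sid,
                                                    conditionMessage(e)))
  }
  structure(list(seed_id = seed_id,
                 X = X,
                 labels = manifest$group,
                 subject_ids = manifest$subject_id,
                 covariates = manifest[, c("age_months", "sex"),
                                       drop = FALSE],
                 feature_map = fmap),
            class = "fc_feature_table")
}

#' @export
print.fc_feature_table <- function(x, ...) {
  cat(sprintf("<fc_feature_table> seed %s: %d subjects (%d FHD / %d control), %d features\n",
              x$seed_id, nrow(x$X), sum(x$labels == "FHD"),
              sum(x$labels == "control"), ncol(x$X)))
  invisible(x)
}

#' Export a feature table as TSV for audit
#' @param ft an `fc_feature_table`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(subject_id = ft$subject_ids, label = ft$labels,
                   ft$X, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
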