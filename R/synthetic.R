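#' Specification of a synthetic two-group cohort
#'
#' Defines the simulated study conditions: group sizes mirroring the
#' 35 FHD / 63 control cohort, a block-structured baseline correlation
#' shared by everyone, an optional group-specific perturbation of
#' seed-to-target correlations (the signal the classifier must find),
#' subject-level heterogeneity, and head-motion parameters.
#'
#' @param n_fhd,n_control group sizes (defaults 35 and 63).
#' @param R region count (default 90).
#' @param T_frames frames per subject (default 120).
#' @param n_seeds number of seed regions in the synthetic atlas.
#' @param base_corr within-block correlation of the baseline matrix.
#' @param n_blocks number of network blocks in the baseline matrix.
#' @param effect NULL for a null cohort, or a list with `seed_id`,
#'   `target_ids` and `delta` (correlation-scale shift applied to the
#'   FHD group's seed-target correlations; sign gives direction).
#' @param subject_sd SD of the symmetric subject-level jitter added to
#'   off-diagonal correlations.
#' @param motion_drift_sd per-frame random-walk SD of translations (mm).
#' @param motion_spike_prob per-frame probability of a motion spike.
#' @param motion_spike_amp spike amplitude (mm).
#' @param rng_seed master seed; the whole cohort is reproducible from it.
#' @return list of class `fc_cohort_spec`.
#' @export
cohort_spec <- function(n_fhd = 35L, n_control = 63L, R = 90L,
                        T_frames = 120L, n_seeds = min(20L, R),
                        base_corr = 0.3, n_blocks = 6L, effect = NULL,
                        subject_sd = 0.1, motion_drift_sd = 0.017,
                        motion_spike_prob = 0.035, motion_spike_amp = 0.6,
                        rng_seed = 1L) {
  stopifnot(n_fhd >= 2, n_control >= 2, R >= 3, T_frames >= 3,
            base_corr >= 0, base_corr < 1, subject_sd >= 0,
            motion_spike_prob >= 0, motion_spike_prob <= 1)
  if (!is.null(effect)) {
    stopifnot(is.list(effect),
              all(c("seed_id", "target_ids", "delta") %in% names(effect)))
  }
  structure(list(n_fhd = as.integer(n_fhd),
                 n_control = as.integer(n_control), R = as.integer(R),
                 T_frames = as.integer(T_frames),
                 n_seeds = as.integer(n_seeds), base_corr = base_corr,
                 n_blocks = as.integer(n_blocks), effect = effect,
                 subject_sd = subject_sd,
                 motion_drift_sd = motion_drift_sd,
                 motion_spike_prob = motion_spike_prob,
                 motion_spike_amp = motion_spike_amp,
                 rng_seed = as.integer(rng_seed)),
            class = "fc_cohort_spec")
}

#' Project a symmetric matrix to the nearest valid correlation matrix
#'
#' Eigenvalue clipping: eigenvalues below `floor` are raised to it, the
#' matrix is reassembled and rescaled to unit diagonal. Identity on inputs
#' that are already valid.
#'
#' @param m symmetric matrix.
#' @param floor eigenvalue floor (default 1e-6).
#' @return positive-definite correlation matrix.
#' @export
repair_correlation <- function(m, floor = 1e-6) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= floor && all(abs(diag(m) - 1) < 1e-12)) {
    diag(m) <- 1
    return(m)
  }
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  out
}

#' Block-structured baseline correlation matrix
#'
#' `n_blocks` contiguous networks of near-equal size with correlation
#' `base_corr` within a block and 0 between blocks, projected to the
#' nearest positive-definite correlation matrix.
#'
#' @param R region count.
#' @param base_corr within-block correlation in \[0, 1).
#' @param n_blocks number of blocks.
#' @return R x R correlation matrix.
#' @export
make_base_correlation <- function(R, base_corr = 0.3, n_blocks = 6L) {
  if (base_corr < 0 || base_corr >= 1)
    stop_fmt("base_corr must be in [0, 1)")
  block <- sort(rep_len(seq_len(n_blocks), R))
  m <- outer(block, block, function(a, b) ifelse(a == b, base_corr, 0))
  diag(m) <- 1
  m <- repair_correlation(m)
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop_fmt("baseline correlation matrix is not positive definite")
  m
}

#' Inject a seed-targeted group effect into a correlation matrix
#'
#' Shifts the correlations between one seed region and a set of target
#' regions by `delta` (symmetrically), then repairs the matrix to valid
#' correlation form. The realised (post-repair) shifts are returned as an
#' attribute, and downstream checks compare against these rather than the
#' requested delta.
#'
#' @param corr R x R correlation matrix.
#' @param seed_id seed region id (row/column index via the atlas).
#' @param target_ids target region ids.
#' @param delta correlation shift (may be negative).
#' @param atlas the `fc_atlas` binding ids to matrix positions.
#' @return modified correlation matrix with attribute
#'   `realized_delta` (named by target id).
#' @export
inject_effect <- function(corr, seed_id, target_ids, delta, atlas) {
  si <- match(seed_id, atlas$regions$region_id)
  ti <- match(target_ids, atlas$regions$region_id)
  if (is.na(si) || any(is.na(ti)))
    stop_fmt("seed or target ids not in atlas")
  if (si %in% ti) stop_fmt("seed cannot be its own target")
  new_vals <- corr[si, ti] + delta
  if (any(abs(new_vals) >= 1))
    stop_fmt("delta pushes correlation out of (-1, 1)")
  out <- corr
  out[si, ti] <- new_vals
  out[ti, si] <- new_vals
  out <- repair_correlation(out)
  attr(out, "realized_delta") <- stats::setNames(out[si, ti] - corr[si, ti],
                                                 target_ids)
  out
}

#' Simulate one subject's parcellated time series
#'
#' The subject's own correlation matrix is the population matrix plus
#' symmetric Gaussian jitter (SD `subject_sd`) on the off-diagonals,
#' repaired to valid form; `T_frames` frames are then drawn i.i.d. from a
#' zero-mean multivariate normal with that matrix.
#'
#' @param corr population correlation matrix.
#' @param T_frames number of frames.
#' @param subject_sd jitter SD on off-diagonal correlations.
#' @param region_names optional column names.
#' @return T x R time-series matrix.
#' @export
simulate_subject_ts <- function(corr, T_frames, subject_sd = 0.1,
                                region_names = NULL) {
  R <- nrow(corr)
  if (subject_sd > 0) {
    jit <- matrix(0, R, R)
    jit[upper.tri(jit)] <- rnorm(R * (R - 1) / 2, 0, subject_sd)
    jit <- jit + t(jit)
    corr <- repair_correlation(pmin(pmax(corr + jit, -0.999), 0.999))
  }
  ts <- MASS::mvrnorm(T_frames, mu = rep(0, R), Sigma = corr)
  if (!is.null(region_names)) colnames(ts) <- region_names
  ts
}

#' Simulate a head-motion trace
#'
#' Gaussian random-walk drift on all six rigid-body parameters
#' (rotational drift scaled down by the head radius so its FD
#' contribution matches the translations), plus transient Bernoulli
#' spikes of `spike_amp` mm on the translation columns (the head jumps at
#' the spiked frame and returns at the next).
#'
#' @param T_frames number of frames.
#' @param drift_sd per-frame random-walk SD (mm).
#' @param spike_prob per-frame spike probability.
#' @param spike_amp spike amplitude (mm).
#' @param head_radius_mm radius scaling rotational drift.
#' @return T x 6 motion matrix (translations mm, rotations rad).
#' @export
simulate_motion <- function(T_frames, drift_sd = 0.017,
                            spike_prob = 0.035, spike_amp = 0.6,
                            head_radius_mm = 50) {
  stopifnot(T_frames >= 1)
  m <- matrix(0, T_frames, 6)
  if (T_frames > 1 && drift_sd > 0) {
    for (j in 1:3)
      m[, j] <- cumsum(c(0, rnorm(T_frames - 1, 0, drift_sd)))
    for (j in 4:6)
      m[, j] <- cumsum(c(0, rnorm(T_frames - 1, 0,
                                  drift_sd / head_radius_mm)))
  }
  if (spike_prob > 0 && spike_amp > 0) {
    spikes <- which(runif(T_frames) < spike_prob)
    spikes <- spikes[spikes > 1]
    for (s in spikes) {
      ax <- sample.int(3, 1)
      m[s, ax] <- m[s, ax] + spike_amp * sample(c(-1, 1), 1)
    }
  }
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  m
}

#' Generate a complete synthetic cohort
#'
#' Draws FHD subjects from the effect-modified correlation matrix and
#' controls from the baseline matrix; samples ages and sexes from
#' group-specific distributions emulating a typical infant cohort;
#' simulates motion traces. With `out_dir` the cohort is written in
#' exactly the formats the readers expect (atlas TSV, manifest CSV,
#' per-subject time-series and motion TSVs, provenance JSON); with
#' `out_dir = NULL` everything is returned in memory.
#'
#' @param spec an [cohort_spec()].
#' @param out_dir output directory, or NULL for an in-memory cohort.
#' @param atlas optional `fc_atlas`; default is
#'   [synthetic_atlas()]`(spec$R, spec$n_seeds)`.
#' @return list of class `fc_cohort`: `atlas`, `manifest`, `series`
#'   (named list of T x R matrices), `motion` (named list of T x 6
#'   matrices), `realized_delta` (NULL for null cohorts), `spec`,
#'   and `dir` (NULL for in-memory cohorts).
#' @export
generate_cohort <- function(spec, out_dir = NULL, atlas = NULL) {
  stopifnot(inherits(spec, "fc_cohort_spec"))
  set.seed(spec$rng_seed)
  if (is.null(atlas)) atlas <- synthetic_atlas(spec$R, spec$n_seeds)
  if (nrow(atlas$regions) != spec$R)
    stop_fmt("atlas region count != spec R")

  base <- make_base_correlation(spec$R, spec$base_corr, spec$n_blocks)
  realized <- NULL
  fhd_corr <- base
  if (!is.null(spec$effect)) {
    fhd_corr <- inject_effect(base, spec$effect$seed_id,
                              spec$effect$target_ids, spec$effect$delta,
                              atlas)
    realized <- attr(fhd_corr, "realized_delta")
  }

  n <- spec$n_fhd + spec$n_control
  sid <- sprintf("sub-%03d", seq_len(n))
  group <- c(rep("FHD", spec$n_fhd), rep("control", spec$n_control))
  # age/sex distributions emulating a typical infant cohort
  # (FHD slightly older, slightly fewer girls)
  age <- ifelse(group == "FHD",
                rnorm(n, 8.9, 2.4), rnorm(n, 8.3, 2.3))
  age <- pmin(pmax(age, 4), 13)
  sex <- ifelse(runif(n) < ifelse(group == "FHD", 15 / 35, 36 / 63),
                "F", "M")
  manifest <- data.frame(subject_id = sid, group = group,
                         age_months = round(age, 1), sex = sex,
                         timeseries_ref = file.path("timeseries",
                                                    paste0(sid, ".tsv")),
                         motion_ref = file.path("motion",
                                                paste0(sid, ".tsv")),
                         stringsAsFactors = FALSE)

  series <- vector("list", n)
  motion <- vector("list", n)
  names(series) <- names(motion) <- sid
  for (i in seq_len(n)) {
    corr_i <- if (group[i] == "FHD") fhd_corr else base
    series[[i]] <- simulate_subject_ts(corr_i, spec$T_frames,
                                       spec$subject_sd,
                                       atlas$regions$name)
    motion[[i]] <- simulate_motion(spec$T_frames, spec$motion_drift_sd,
                                   spec$motion_spike_prob,
                                   spec$motion_spike_amp)
  }

  cohort <- structure(list(atlas = atlas, manifest = manifest,
                           series = series, motion = motion,
                           realized_delta = realized, spec = spec,
                           dir = out_dir),
                      class = "fc_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat(sprintf("<fc_cohort> %d FHD / %d control, R = %d, T = %d%s\n",
              sum(x$manifest$group == "FHD"),
              sum(x$manifest$group == "control"),
              nrow(x$atlas$regions), nrow(x$series[[1]]),
              if (is.null(x$spec$effect)) " (null cohort)" else ""))
  invisible(x)
}

#' Write an in-memory cohort to disk
#' @param cohort an `fc_cohort`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(file.path(out_dir, "timeseries"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "motion"), recursive = TRUE,
             showWarnings = FALSE)
  write_atlas(cohort$atlas, file.path(out_dir, "atlas.tsv"))
  write_manifest(cohort$manifest, file.path(out_dir, "manifest.csv"))
  for (sid in cohort$manifest$subject_id) {
    write_timeseries(cohort$series[[sid]],
                     file.path(out_dir, "timeseries",
                               paste0(sid, ".tsv")))
    write_motion(cohort$motion[[sid]],
                 file.path(out_dir, "motion", paste0(sid, ".tsv")))
  }
  prov <- list(spec = unclass(cohort$spec),
               realized_delta = as.list(cohort$realized_delta),
               package_version = as.character(packageVersion("infantfc")))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir cohort directory.
#' @return an `fc_cohort` (spec restored from provenance when present).
#' @export
read_cohort <- function(dir) {
  atl <- read_atlas(file.path(dir, "atlas.tsv"))
  man <- read_manifest(file.path(dir, "manifest.csv"))
  series <- lapply(seq_len(nrow(man)), function(i)
    read_timeseries(file.path(dir, man$timeseries_ref[i]), atl))
  names(series) <- man$subject_id
  motion <- lapply(seq_len(nrow(man)), function(i)
    read_motion(file.path(dir, man$motion_ref[i])))
  names(motion) <- man$subject_id
  prov_path <- file.path(dir, "provenance.json")
  spec <- realized <- NULL
  if (file.exists(prov_path)) {
    prov <- jsonlite::read_json(prov_path, simplifyVector = TRUE)
    spec_args <- prov$spec
    if (!is.null(spec_args$effect) && length(spec_args$effect) == 0)
      spec_args$effect <- NULL
    spec <- do.call(cohort_spec, spec_args)
    if (length(prov$realized_delta))
      realized <- unlist(prov$realized_delta)
  }
  structure(list(atlas = atl, manifest = man, series = series,
                 motion = motion, realized_delta = realized, spec = spec,
                 dir = dir),
            class = "fc_cohort")
}
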