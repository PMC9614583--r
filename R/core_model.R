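#' Construct an atlas object
#'
#' An atlas is an ordered table of cerebral regions plus the subset flagged
#' as seed regions. The row order is fixed and defines feature-vector
#' indexing everywhere downstream: for a given seed, feature `j` always
#' refers to the j-th *non-seed-self* region in atlas order.
#'
#' @param region_id integer vector of unique region ids.
#' @param name character vector of region names (unique).
#' @param hemisphere character vector, each `"L"` or `"R"`.
#' @param is_seed logical vector flagging seed regions.
#' @return An object of class `fc_atlas`: a list with `regions`
#'   (data.frame: region_id, name, hemisphere, is_seed) and `seed_ids`.
#' @export
atlas <- function(region_id, name, hemisphere, is_seed) {
  region_id <- as.integer(region_id)
  name <- as.character(name)
  hemisphere <- as.character(hemisphere)
  is_seed <- as.logical(is_seed)
  n <- length(region_id)
  if (length(name) != n || length(hemisphere) != n || length(is_seed) != n)
    stop_fmt("atlas columns have unequal lengths")
  if (anyDuplicated(region_id))
    stop_fmt("duplicated region_id in atlas: %s",
             paste(unique(region_id[duplicated(region_id)]), collapse = ", "))
  if (anyDuplicated(name))
    stop_fmt("duplicated region name in atlas")
  if (!all(hemisphere %in% c("L", "R")))
    stop_fmt("unknown hemisphere code: %s",
             paste(setdiff(unique(hemisphere), c("L", "R")), collapse = ", "))
  if (any(is.na(is_seed))) stop_fmt("is_seed must be TRUE/FALSE")
  regions <- data.frame(region_id = region_id, name = name,
                        hemisphere = hemisphere, is_seed = is_seed,
                        stringsAsFactors = FALSE)
  structure(list(regions = regions, seed_ids = region_id[is_seed]),
            class = "fc_atlas")
}

#' @export
print.fc_atlas <- function(x, ...) {
  cat(sprintf("<fc_atlas> %d regions, %d seeds\n",
              nrow(x$regions), length(x$seed_ids)))
  invisible(x)
}

#' Number of regions in an atlas
#' @param atlas an `fc_atlas`.
#' @return integer region count.
#' @export
n_regions <- function(atlas) nrow(atlas$regions)

#' Map a seed to its feature (target-region) indices
#'
#' Returns, for one seed, the atlas rows that form its FC feature vector:
#' all regions except the seed itself, in atlas order. Feature `j` of any
#' downstream weight/pattern vector refers to row `j` of this map.
#'
#' @param atlas an `fc_atlas`.
#' @param seed_id a region id present in the atlas.
#' @return data.frame with columns `feature_index`, `region_id`, `name`.
#' @export
seed_feature_map <- function(atlas, seed_id) {
  idx <- which(atlas$regions$region_id != seed_id)
  if (length(idx) == nrow(atlas$regions))
    stop_fmt("seed_id %s not in atlas", seed_id)
  data.frame(feature_index = seq_along(idx),
             region_id = atlas$regions$region_id[idx],
             name = atlas$regions$name[idx],
             stringsAsFactors = FALSE)
}

#' Read an atlas from a TSV file
#'
#' Expects columns `region_id`, `name`, `hemisphere`, `is_seed`
#' (is_seed as 0/1 or TRUE/FALSE). Row order is preserved.
#'
#' @param path path to the TSV file.
#' @return an `fc_atlas`.
#' @export
read_atlas <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "name", "hemisphere", "is_seed")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fmt("atlas file %s missing column(s): %s", path,
             paste(miss, collapse = ", "))
  atlas(df$region_id, df$name, df$hemisphere, as.logical(df$is_seed))
}

#' Write an atlas to a TSV file
#' @param atlas an `fc_atlas`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  df <- atlas$regions
  df$is_seed <- as.integer(df$is_seed)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The shipped default atlas
#'
#' A 90-region AAL-style cerebral parcellation with 20 seed regions (10
#' bilateral pairs) covering the inferior frontal (orbital, triangular,
#' opercular), precentral, temporoparietal (Heschl, inferior parietal,
#' supramarginal, angular) and occipitotemporal (inferior temporal,
#' fusiform) cortices implicated in language and reading development.
#'
#' @return an `fc_atlas` with 90 regions and 20 seeds.
#' @export
default_atlas <- function() {
  read_atlas(system.file("extdata", "atlas_default.tsv",
                         package = "infantfc", mustWork = TRUE))
}

#' Generate a synthetic atlas
#'
#' Plain numbered parcellation used by the synthetic cohort generator when
#' the analysis is run at a reduced region count. Seeds are spread evenly
#' across the regions, alternating hemispheres.
#'
#' @param n_regions number of regions.
#' @param n_seeds number of seed regions (default 20, capped at
#'   `n_regions`).
#' @return an `fc_atlas`.
#' @export
synthetic_atlas <- function(n_regions, n_seeds = min(20L, n_regions)) {
  stopifnot(n_regions >= 2, n_seeds >= 1, n_seeds <= n_regions)
  ids <- seq_len(n_regions)
  hemi <- rep(c("L", "R"), length.out = n_regions)
  seed_pos <- unique(round(seq(1, n_regions, length.out = n_seeds)))
  atlas(ids,
        sprintf("region_%03d_%s", ids, hemi),
        hemi,
        ids %in% seed_pos)
}

# ---------------------------------------------------------------------------
# Subject manifest

#' Read a subject manifest
#'
#' CSV with header `subject_id, group, age_months, sex, timeseries_ref,
#' motion_ref`. Group labels are normalised case-insensitively to
#' `"FHD"` / `"control"`; sex to `"F"` / `"M"`. `motion_ref` may be empty.
#'
#' @param path path to the CSV file.
#' @return data.frame of subject records, in file order.
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("subject_id", "group", "age_months", "sex", "timeseries_ref",
            "motion_ref")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fmt("manifest %s missing column(s): %s", path,
             paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(df[, need])
  df <- df[, need]
  if (anyDuplicated(df$subject_id))
    stop_fmt("duplicated subject_id in manifest")
  grp <- tolower(trimws(df$group))
  bad <- !grp %in% c("fhd", "control")
  if (any(bad))
    stop_fmt("unknown group label(s): %s",
             paste(unique(df$group[bad]), collapse = ", "))
  df$group <- ifelse(grp == "fhd", "FHD", "control")
  sx <- toupper(trimws(df$sex))
  if (!all(sx %in% c("F", "M")))
    stop_fmt("unknown sex code(s): %s",
             paste(unique(df$sex[!sx %in% c("F", "M")]), collapse = ", "))
  df$sex <- sx
  df$age_months <- as.numeric(df$age_months)
  if (any(!is.finite(df$age_months)) || any(df$age_months < 0))
    stop_fmt("age_months must be non-negative numbers")
  df
}

#' Write a subject manifest
#' @param manifest data.frame as returned by [read_manifest()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Parcellated time series

#' Read a parcellated time-series matrix
#'
#' TSV with a header row of region names and one row per frame. Columns are
#' matched to the atlas by name (any column order in the file) and
#' reordered to atlas order, so region identity never depends on the file's
#' column layout.
#'
#' @param path path to the TSV file.
#' @param atlas an `fc_atlas`; defines the required columns and their
#'   output order.
#' @return numeric matrix, T frames x R regions, columns named and in
#'   atlas order.
#' @export
read_timeseries <- function(path, atlas) {
  df <- read.delim(path, check.names = FALSE)
  miss <- setdiff(atlas$regions$name, names(df))
  if (length(miss))
    stop_fmt("time-series file %s missing region column(s): %s", path,
             paste(head(miss, 5), collapse = ", "))
  m <- as.matrix(df[, atlas$regions$name, drop = FALSE])
  storage.mode(m) <- "double"
  validate_timeseries(m, atlas, context = path)
}

validate_timeseries <- function(m, atlas, context = "time series") {
  if (!all(is.finite(m)))
    stop_fmt("%s: non-finite or non-numeric values", context)
  if (nrow(m) < 3)
    stop_fmt("%s: need at least 3 frames, got %d", context, nrow(m))
  if (ncol(m) != nrow(atlas$regions))
    stop_fmt("%s: %d columns but atlas has %d regions", context, ncol(m),
             nrow(atlas$regions))
  colnames(m) <- atlas$regions$name
  rownames(m) <- NULL
  m
}

#' Write a parcellated time-series matrix
#' @param ts numeric T x R matrix with region-name column names.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  # full precision so read -> write -> read round trips exactly
  df <- as.data.frame(ts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(ts), collapse = "\t"), con)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Average voxel time series into region time series
#'
#' Region signal at each frame is the arithmetic mean of the BOLD signal
#' across the voxels assigned to that region.
#'
#' @param voxel_ts numeric T x V matrix of voxel time series.
#' @param labels length-V vector of region ids assigning each voxel to an
#'   atlas region.
#' @param atlas an `fc_atlas`; every region must receive at least one
#'   voxel.
#' @return numeric T x R matrix in atlas order.
#' @export
aggregate_voxels <- function(voxel_ts, labels, atlas) {
  voxel_ts <- as.matrix(voxel_ts)
  if (length(labels) != ncol(voxel_ts))
    stop_fmt("labels length (%d) != voxel count (%d)", length(labels),
             ncol(voxel_ts))
  ids <- atlas$regions$region_id
  bad <- setdiff(unique(labels), ids)
  if (length(bad))
    stop_fmt("voxel labels not in atlas: %s", paste(bad, collapse = ", "))
  empty <- ids[!ids %in% labels]
  if (length(empty))
    stop_fmt("region(s) with zero voxels: %s", paste(empty, collapse = ", "))
  out <- vapply(ids, function(id) {
    rowMeans(voxel_ts[, labels == id, drop = FALSE])
  }, numeric(nrow(voxel_ts)))
  out <- matrix(out, nrow = nrow(voxel_ts))
  colnames(out) <- atlas$regions$name
  out
}

# ---------------------------------------------------------------------------
# Run configuration

#' Analysis run configuration
#'
#' Bundles every tunable of the classification pipeline. Defaults mirror
#' the standard analysis: 10,000 bootstrap iterations, 99% CI on the
#' true-minus-null accuracy difference, Cohen d threshold 0.5, alpha 0.05,
#' 20 seed tests, leave-one-pair-out CV and Monte-Carlo (max-statistic)
#' family-wise correction.
#'
#' @param n_iterations bootstrap/permutation iterations per seed.
#' @param ci_level confidence level for the difference CI.
#' @param d_threshold minimum Cohen d for seed selection.
#' @param alpha significance level applied to corrected p values.
#' @param n_seeds_tested number of seed tests entering the family-wise
#'   correction.
#' @param cv_scheme `"leave_one_pair_out"` or `"kfold5"`.
#' @param correction_method `"max_null"`, `"bonferroni"` or `"sidak"`.
#' @param rng_seed master seed; all randomness in a run derives from it.
#' @param covariates optional character vector of manifest fields (e.g.
#'   `"age_months"`) residualised out of the features within CV folds.
#' @param balance_n balanced per-group sample size for the bootstrap
#'   (`NULL` = size of the smaller group).
#' @param svm_cost soft-margin cost C of the linear SVM.
#' @param standardize z-score features within training folds (off by
#'   default; the classifier is run with plain defaults).
#' @param scrub drop motion-outlier frames from FC computation.
#' @param fd_threshold_mm framewise-displacement outlier threshold.
#' @param head_radius_mm head radius for rotational displacement.
#' @return a list of class `fc_config`.
#' @export
fc_config <- function(n_iterations = 10000L,
                      ci_level = 0.99,
                      d_threshold = 0.5,
                      alpha = 0.05,
                      n_seeds_tested = 20L,
                      cv_scheme = c("leave_one_pair_out", "kfold5"),
                      correction_method = c("max_null", "bonferroni", "sidak"),
                      rng_seed = 1L,
                      covariates = NULL,
                      balance_n = NULL,
                      svm_cost = 1,
                      standardize = FALSE,
                      scrub = FALSE,
                      fd_threshold_mm = 0.5,
                      head_radius_mm = 50) {
  cv_scheme <- match.arg(cv_scheme)
  correction_method <- match.arg(correction_method)
  stopifnot(n_iterations >= 1, ci_level > 0, ci_level < 1,
            alpha > 0, alpha < 1, n_seeds_tested >= 1, svm_cost > 0,
            fd_threshold_mm > 0, head_radius_mm > 0)
  structure(list(n_iterations = as.integer(n_iterations),
                 ci_level = ci_level, d_threshold = d_threshold,
                 alpha = alpha, n_seeds_tested = as.integer(n_seeds_tested),
                 cv_scheme = cv_scheme, correction_method = correction_method,
                 rng_seed = as.integer(rng_seed), covariates = covariates,
                 balance_n = balance_n, svm_cost = svm_cost,
                 standardize = standardize, scrub = scrub,
                 fd_threshold_mm = fd_threshold_mm,
                 head_radius_mm = head_radius_mm),
            class = "fc_config")
}

#' Read a run configuration from a YAML/JSON key-value file
#' @param path path to a YAML (or JSON) file whose keys mirror
#'   [fc_config()] arguments.
#' @return an `fc_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(fc_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_fmt("unknown config key(s) in %s: %s", path,
             paste(unknown, collapse = ", "))
  do.call(fc_config, vals)
}
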