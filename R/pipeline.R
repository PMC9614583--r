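#' Simulate a cohort from a spec file
#'
#' Thin wrapper over [generate_cohort()]: reads a YAML spec whose keys
#' mirror [cohort_spec()] arguments (with `effect` as a nested map) and
#' writes the cohort under `out_dir`.
#'
#' @param spec_file YAML file of cohort parameters.
#' @param out_dir output directory.
#' @return the `fc_cohort`, invisibly.
#' @export
pipeline_simulate <- function(spec_file, out_dir) {
  vals <- yaml::read_yaml(spec_file)
  known <- names(formals(cohort_spec))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_fmt("unknown cohort spec key(s) in %s: %s", spec_file,
             paste(unknown, collapse = ", "))
  spec <- do.call(cohort_spec, vals)
  invisible(generate_cohort(spec, out_dir = out_dir))
}

#' Run the full classification pipeline
#'
#' Executes the complete chain on a cohort: motion QC, per-seed Fisher-z
#' feature tables, bootstrapped classification with paired permutation
#' null for every seed, seed-level inference with family-wise correction
#' and the three-part selection rule, and Haufe pattern / edge-t tables
#' for the selected seeds. All randomness derives from
#' `config$rng_seed`; per-seed work is seeded independently, so results
#' do not depend on the order seeds are processed.
#'
#' @param data data directory (as written by [write_cohort()]) or an
#'   in-memory `fc_cohort`.
#' @param config an [fc_config()] or path to a YAML config file.
#' @param out_dir optional output directory for TSV tables, per-seed
#'   distribution files and a provenance record.
#' @param seed_ids seeds to test (default: all atlas seeds).
#' @return list of class `fc_run_report`: `config`, `inference`
#'   (per-seed table), `selected` (ids), `patterns` (named list of
#'   `fc_edge_patterns` for selected seeds), `cohort_table`, `qc`,
#'   `dists` (per-seed distributions).
#' @export
pipeline_run <- function(data, config = fc_config(), out_dir = NULL,
                         seed_ids = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cohort <- if (inherits(data, "fc_cohort")) data else read_cohort(data)
  atl <- cohort$atlas
  man <- cohort$manifest
  seed_ids <- seed_ids %||% atl$seed_ids
  if (!length(seed_ids)) stop_fmt("no seed regions to test")

  qc <- tryCatch(qc_cohort(man, config, motion = cohort$motion),
                 error = function(e) NULL)
  masks <- NULL
  if (config$scrub) {
    masks <- scrub_masks(man, config, motion = cohort$motion)
  }

  dists <- vector("list", length(seed_ids))
  tables <- vector("list", length(seed_ids))
  names(dists) <- names(tables) <- as.character(seed_ids)
  for (k in seq_along(seed_ids)) {
    sid <- seed_ids[k]
    ft <- build_feature_table(man, atl, sid, series = cohort$series,
                              scrub = masks)
    tables[[k]] <- ft
    dists[[k]] <- run_seed_classification(ft, config)
  }

  inf <- seed_inference(dists, config, atlas = atl)
  selected <- inf$seed_id[inf$selected]
  patterns <- lapply(as.character(selected), function(s)
    edge_pattern_table(dists[[s]], tables[[s]]))
  names(patterns) <- as.character(selected)

  ctab <- cohort_table(man, qc)
  report <- structure(list(config = config, inference = inf,
                           selected = selected, patterns = patterns,
                           cohort_table = ctab, qc = qc, dists = dists),
                      class = "fc_run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir, atlas = atl)
  report
}

#' @export
print.fc_run_report <- function(x, ...) {
  cat(sprintf("<fc_run_report> %d seeds tested, %d selected\n",
              nrow(x$inference), length(x$selected)))
  if (length(x$selected))
    cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Write the tables of a run report
#'
#' Persists the seed-level inference table, per-seed iteration
#' distributions, per-selected-seed pattern tables, the cohort table, the
#' QC table and a provenance record (config, master seed, package
#' version) under `out_dir`.
#'
#' @param report an `fc_run_report`.
#' @param out_dir output directory.
#' @param atlas optional atlas echoed into the output directory.
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir, atlas = NULL) {
  dir.create(file.path(out_dir, "dists"), recursive = TRUE,
             showWarnings = FALSE)
  write.table(report$inference, file.path(out_dir, "seed_inference.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in names(report$dists))
    write_seed_dists(report$dists[[s]],
                     file.path(out_dir, "dists",
                               sprintf("seed_%s.tsv", s)))
  for (s in names(report$patterns)) {
    pt <- report$patterns[[s]]
    write.table(pt, file.path(out_dir, sprintf("patterns_seed_%s.tsv", s)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    corr <- attr(pt, "correlation")
    jsonlite::write_json(corr,
                         file.path(out_dir,
                                   sprintf("pattern_t_corr_seed_%s.json",
                                           s)),
                         auto_unbox = TRUE, digits = NA)
  }
  write.table(report$cohort_table, file.path(out_dir, "cohort_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$qc))
    write.table(report$qc, file.path(out_dir, "qc_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(atlas)) write_atlas(atlas, file.path(out_dir, "atlas.tsv"))
  prov <- list(config = unclass(report$config),
               selected = report$selected,
               package_version = as.character(packageVersion("infantfc")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Regenerate inference tables from persisted distributions
#'
#' Re-runs seed-level inference and selection from the per-seed iteration
#' TSVs written by a previous [pipeline_run()], without touching time
#' series or re-training classifiers. Thresholds (alpha, CI level, d) may
#' differ from the original run.
#'
#' @param out_dir directory of a previous run.
#' @param config an [fc_config()]; defaults to the persisted run config.
#' @return the regenerated `fc_inference` table (also rewritten to
#'   `seed_inference.tsv`).
#' @export
pipeline_report <- function(out_dir, config = NULL) {
  dist_dir <- file.path(out_dir, "dists")
  files <- list.files(dist_dir, pattern = "^seed_.*\\.tsv$",
                      full.names = TRUE)
  if (!length(files))
    stop_fmt("no persisted distributions under %s", dist_dir)
  if (is.null(config)) {
    prov_path <- file.path(out_dir, "provenance.json")
    if (!file.exists(prov_path))
      stop_fmt("no config given and no provenance record in %s", out_dir)
    prov <- jsonlite::read_json(prov_path, simplifyVector = TRUE)
    cfg_args <- prov$config
    cfg_args <- cfg_args[!vapply(cfg_args, is.null, logical(1))]
    config <- do.call(fc_config, cfg_args)
  }
  ids <- sub("^seed_(.*)\\.tsv$", "\\1", basename(files))
  ord <- order(suppressWarnings(as.numeric(ids)))
  files <- files[ord]
  ids <- ids[ord]
  dists <- mapply(function(f, id) read_seed_dists(f, as.integer(id)),
                  files, ids, SIMPLIFY = FALSE)
  atl_path <- file.path(out_dir, "atlas.tsv")
  atl <- if (file.exists(atl_path)) read_atlas(atl_path) else NULL
  inf <- seed_inference(dists, config, atlas = atl)
  write.table(inf, file.path(out_dir, "seed_inference.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  inf
}
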