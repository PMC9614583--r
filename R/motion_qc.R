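#' Read a rigid-body motion trace
#'
#' TSV with six columns and one row per frame: translations in mm
#' (columns 1-3) followed by rotations in radians (columns 4-6).
#'
#' @param path path to the TSV file.
#' @return numeric T x 6 matrix.
#' @export
read_motion <- function(path) {
  m <- as.matrix(read.delim(path, header = TRUE))
  storage.mode(m) <- "double"
  if (ncol(m) != 6)
    stop_fmt("motion file %s: expected 6 columns, got %d", path, ncol(m))
  if (!all(is.finite(m)))
    stop_fmt("motion file %s: non-finite values", path)
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

#' Write a motion trace
#' @param motion T x 6 numeric matrix.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_motion <- function(motion, path) {
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  write.table(format(as.data.frame(motion), digits = 17, trim = TRUE,
                     scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Framewise displacement
#'
#' Power-style FD: the sum of absolute frame-to-frame differences of the
#' three translations (mm) plus the three rotations converted to arc
#' length on a sphere of radius `head_radius_mm`. The first frame has no
#' predecessor and is assigned 0.
#'
#' @param motion T x 6 numeric matrix (translations mm, rotations rad).
#' @param head_radius_mm sphere radius converting radians to mm. The 50 mm
#'   adult convention is the default; infant analyses may reduce it.
#' @return numeric length-T vector of FD values in mm.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop_fmt("motion must have 6 columns")
  if (!all(is.finite(motion))) stop_fmt("non-finite motion values")
  if (nrow(motion) < 1) stop_fmt("empty motion trace")
  if (nrow(motion) == 1) return(0)
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Flag motion-outlier frames
#'
#' A frame is an outlier when its FD exceeds `threshold_mm`. The summary
#' reports the outlier fraction over all T frames and the mean FD after
#' outlier removal, computed over retained frames excluding frame 1
#' (whose FD is 0 by construction, not by measurement).
#'
#' @param fd length-T FD vector (mm), as from [framewise_displacement()].
#' @param threshold_mm positive FD threshold in mm.
#' @return list of class `fc_qc`: `fd`, `outlier_mask`, `outlier_fraction`,
#'   `mean_fd_after_removal`.
#' @export
flag_outliers <- function(fd, threshold_mm = 0.5) {
  if (threshold_mm <= 0) stop_fmt("threshold_mm must be positive")
  if (!all(is.finite(fd))) stop_fmt("non-finite FD values")
  mask <- fd > threshold_mm
  t_tot <- length(fd)
  keep <- !mask
  keep[1] <- FALSE  # frame 1 carries no displacement measurement
  mfd <- if (any(keep)) mean(fd[keep]) else NA_real_
  structure(list(fd = fd,
                 outlier_mask = mask,
                 outlier_fraction = sum(mask) / t_tot,
                 mean_fd_after_removal = mfd),
            class = "fc_qc")
}

#' Per-subject motion QC table for a cohort
#'
#' Computes FD and outlier statistics for every subject in the manifest
#' that has a motion trace.
#'
#' @param manifest manifest data.frame (see [read_manifest()]).
#' @param config an [fc_config()] (uses `fd_threshold_mm`,
#'   `head_radius_mm`).
#' @param data_dir directory against which relative `motion_ref` paths are
#'   resolved.
#' @param motion optional named list of in-memory T x 6 motion matrices,
#'   keyed by subject_id; takes precedence over file refs.
#' @return data.frame: subject_id, group, mean_fd_after_removal,
#'   outlier_pct, n_frames.
#' @export
qc_cohort <- function(manifest, config = fc_config(), data_dir = ".",
                      motion = NULL) {
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    sid <- manifest$subject_id[i]
    m <- if (!is.null(motion) && sid %in% names(motion)) {
      motion[[sid]]
    } else if (!is.na(manifest$motion_ref[i]) && nzchar(manifest$motion_ref[i])) {
      read_motion(file.path(data_dir, manifest$motion_ref[i]))
    } else {
      return(NULL)
    }
    fd <- framewise_displacement(m, config$head_radius_mm)
    qc <- flag_outliers(fd, config$fd_threshold_mm)
    data.frame(subject_id = sid, group = manifest$group[i],
               mean_fd_after_removal = qc$mean_fd_after_removal,
               outlier_pct = 100 * qc$outlier_fraction,
               n_frames = length(fd), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop_fmt("no subject has motion data")
  do.call(rbind, rows)
}

#' Per-subject scrub masks for FC computation
#'
#' Returns, for each subject with motion data, the logical mask of frames
#' retained (TRUE) after FD-based outlier removal. Subjects without motion
#' data get NULL (all frames retained).
#'
#' @inheritParams qc_cohort
#' @return named list of logical vectors (or NULL), keyed by subject_id.
#' @export
scrub_masks <- function(manifest, config = fc_config(), data_dir = ".",
                        motion = NULL) {
  out <- vector("list", nrow(manifest))
  names(out) <- manifest$subject_id
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    m <- if (!is.null(motion) && sid %in% names(motion)) {
      motion[[sid]]
    } else if (!is.na(manifest$motion_ref[i]) && nzchar(manifest$motion_ref[i])) {
      read_motion(file.path(data_dir, manifest$motion_ref[i]))
    } else {
      next
    }
    fd <- framewise_displacement(m, config$head_radius_mm)
    out[[sid]] <- !flag_outliers(fd, config$fd_threshold_mm)$outlier_mask
  }
  out
}
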