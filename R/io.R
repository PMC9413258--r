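#' Read and write IMU trace CSV files
#'
#' The on-disk dialect is a plain comma-separated file with a single header
#' line `time_s,acc_vt,acc_ml,acc_ap,yaw,pitch,roll`, UTF-8 encoded, `.`
#' decimal separator. Acceleration is stored in m/s^2 and angular velocity in
#' deg/s (the segmentation thresholds are specified in deg/s). The sampling
#' rate is recovered from the time column.
#'
#' @param path file path.
#' @param subject_id,test,trial_index recording metadata (the CSV stores only
#'   the signals; metadata normally comes from the cohort manifest).
#' @return [read_imu_csv()] returns an [imu_recording()];
#'   [write_imu_csv()] returns `path` invisibly.
#' @export
read_imu_csv <- function(path, subject_id = "unknown",
                         test = c("TUG", "SIXMWT"), trial_index = 1L) {
  test <- match.arg(test)
  if (!file.exists(path)) stop_gaitage(paste0("no such file: ", path), "format")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_s", imu_channels())
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop_gaitage(paste0("IMU CSV ", path, " is missing column(s): ",
                        paste(missing, collapse = ", ")), "format")
  }
  dt <- diff(df$time_s)
  if (length(dt) < 1 || any(dt <= 0)) {
    stop_gaitage("time_s must be strictly increasing", "sampling")
  }
  fs <- 1 / median(dt)
  rec <- new_imu_recording(df[need], subject_id = subject_id, test = test,
                           trial_index = trial_index, fs = fs)
  validate_imu_recording(rec)
  rec
}

#' @rdname read_imu_csv
#' @param rec an [imu_recording()].
#' @export
write_imu_csv <- function(rec, path) {
  validate_imu_recording(rec)
  readr::write_csv(as_tibble(rec)[c("time_s", imu_channels())], path,
                   progress = FALSE)
  invisible(path)
}

#' Read and write per-subject feature tables
#'
#' Feature tables are CSV with columns `subject_id`, `age`, then the 132
#' feature columns in schema order (134 columns in total). Round-tripping
#' preserves values to full double precision.
#'
#' @param table a feature table (see [validate_feature_table()]).
#' @param path file path.
#' @return [read_feature_table()] returns a validated tibble;
#'   [write_feature_table()] returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  ordered <- table[c("subject_id", "age", feature_schema()$feature)]
  readr::write_csv(ordered, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_gaitage(paste0("no such file: ", path), "format")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_feature_table(df)
  df
}

#' Read and write cohort manifests
#'
#' A manifest lists one subject per row: `subject_id, age, height_cm, sex`
#' plus any number of file-path columns pointing at that subject's IMU CSVs.
#'
#' @param meta a tibble of subject metadata.
#' @param path file path.
#' @return [read_manifest()] returns the manifest tibble.
#' @export
write_manifest <- function(meta, path) {
  need <- c("subject_id", "age", "height_cm", "sex")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0) {
    stop_gaitage(paste0("manifest is missing column(s): ",
                        paste(missing, collapse = ", ")), "format")
  }
  if (anyDuplicated(meta$subject_id)) {
    stop_gaitage("duplicate subject_id in manifest", "integrity")
  }
  readr::write_csv(meta, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_gaitage(paste0("no such file: ", path), "format")
  meta <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "age", "height_cm", "sex")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0) {
    stop_gaitage(paste0("manifest is missing column(s): ",
                        paste(missing, collapse = ", ")), "format")
  }
  if (anyDuplicated(meta$subject_id)) {
    stop_gaitage("duplicate subject_id in manifest", "integrity")
  }
  meta
}
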