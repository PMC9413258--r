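#' IMU recording container
#'
#' A trunk-IMU recording is a tibble with a time column `time_s` and six
#' signal channels: linear acceleration along the vertical (`acc_vt`),
#' mediolateral (`acc_ml`) and anterior-posterior (`acc_ap`) trunk axes in
#' m/s^2, and angular velocity about the same axes — `yaw` (vertical),
#' `pitch` (mediolateral) and `roll` (anterior-posterior) — in deg/s.
#' Sampling is uniform; metadata (subject, test, trial, sampling rate) ride
#' along as attributes so the object still behaves like a plain tibble in
#' dplyr pipelines.
#'
#' @param time_s numeric vector of sample times in seconds, uniformly spaced.
#' @param acc_vt,acc_ml,acc_ap linear acceleration channels (m/s^2).
#' @param yaw,pitch,roll angular velocity channels (deg/s).
#' @param subject_id subject identifier.
#' @param test `"TUG"` or `"SIXMWT"`.
#' @param trial_index trial number within the test (>= 1).
#' @param fs sampling rate in Hz.
#'
#' @return A tibble of class `imu_recording`.
#' @export
imu_recording <- function(time_s, acc_vt, acc_ml, acc_ap, yaw, pitch, roll,
                          subject_id = "unknown", test = c("TUG", "SIXMWT"),
                          trial_index = 1L, fs = 100) {
  test <- match.arg(test)
  df <- tibble(
    time_s = as.numeric(time_s),
    acc_vt = as.numeric(acc_vt), acc_ml = as.numeric(acc_ml),
    acc_ap = as.numeric(acc_ap),
    yaw = as.numeric(yaw), pitch = as.numeric(pitch), roll = as.numeric(roll)
  )
  rec <- new_imu_recording(df, subject_id = subject_id, test = test,
                           trial_index = as.integer(trial_index), fs = fs)
  validate_imu_recording(rec)
}

new_imu_recording <- function(df, subject_id, test, trial_index, fs) {
  structure(
    df,
    subject_id = subject_id, test = test,
    trial_index = as.integer(trial_index), fs = fs,
    class = c("imu_recording", class(tibble()))
  )
}

#' Channel names of an IMU recording
#' @return Character vector of the six signal channel names.
#' @export
imu_channels <- function() {
  c("acc_vt", "acc_ml", "acc_ap", "yaw", "pitch", "roll")
}

#' Validate an IMU recording
#'
#' Checks channel completeness, equal lengths (>= 2 samples), positive
#' sampling rate and uniform time spacing (|dt - 1/fs| < 1e-9).
#'
#' @param rec an [imu_recording()].
#' @return `rec`, invisibly unchanged, or an error.
#' @export
validate_imu_recording <- function(rec) {
  need <- c("time_s", imu_channels())
  missing <- setdiff(need, names(rec))
  if (length(missing) > 0) {
    stop_gaitage(paste0("recording is missing column(s): ",
                        paste(missing, collapse = ", ")), "format")
  }
  fs <- attr(rec, "fs")
  if (is.null(fs) || fs <= 0) stop_gaitage("sampling rate fs must be > 0", "format")
  if (nrow(rec) < 2) stop_gaitage("recording must have at least 2 samples", "format")
  dt <- diff(rec$time_s)
  if (any(abs(dt - 1 / fs) >= 1e-9)) {
    stop_gaitage(sprintf(
      "timestamps are not uniform at fs = %g Hz (max deviation %.3g s)",
      fs, max(abs(dt - 1 / fs))), "sampling")
  }
  invisible(rec)
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> subject %s, %s trial %d, %g Hz, %d samples (%.1f s)\n",
              attr(x, "subject_id"), attr(x, "test"), attr(x, "trial_index"),
              attr(x, "fs"), nrow(x), nrow(x) / attr(x, "fs")))
  NextMethod()
}

rec_fs <- function(rec) attr(rec, "fs")
rec_test <- function(rec) attr(rec, "test")
rec_duration <- function(rec) nrow(rec) / attr(rec, "fs")
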