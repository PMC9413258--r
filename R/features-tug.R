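#' Descriptive statistics of a signal segment
#'
#' The three descriptive statistics used for every TUG signal/sub-task
#' combination: root mean square `sqrt(mean(x^2))`, minimum and maximum.
#'
#' @param x non-empty numeric series.
#' @return Named list with `rms`, `min`, `max`.
#' @export
descriptive_stats <- function(x) {
  if (length(x) == 0) stop_gaitage("cannot compute statistics of an empty series", "value")
  list(rms = sqrt(mean(x^2)), min = min(x), max = max(x))
}

tug_stat_signals <- function() {
  c("acc_vt", "acc_ml", "acc_ap", "acc_res", "yaw", "pitch", "roll")
}

# stats of the 7 filtered signals restricted to [start_s, end_s]
interval_stats <- function(prep, start_s, end_s, fs, label) {
  i0 <- floor(start_s * fs) + 1L
  i1 <- floor(end_s * fs) + 1L
  i1 <- min(i1, nrow(prep))
  if (i1 - i0 + 1L < 2L) {
    stop_gaitage(paste0("sub-task '", label, "' spans fewer than 2 samples"),
                 "extraction")
  }
  out <- list()
  for (sig in tug_stat_signals()) {
    st <- descriptive_stats(prep[[sig]][i0:i1])
    out[[paste(sig, "rms", sep = ".")]] <- st$rms
    out[[paste(sig, "min", sep = ".")]] <- st$min
    out[[paste(sig, "max", sep = ".")]] <- st$max
  }
  unlist(out)
}

#' Extract the 111 TUG features from one trial
#'
#' Six timing features plus rms/min/max of the seven filtered signals
#' (acc_vt, acc_ml, acc_ap, acc_res, yaw, pitch, roll) over five sub-task
#' groups. The `gait` group is the feature-wise arithmetic mean of the
#' forward-gait and backward-gait statistics.
#'
#' @param rec a TUG [imu_recording()] (raw; preprocessing happens inside).
#' @param seg its `tug_segmentation`; computed with [segment_tug()] if `NULL`.
#' @param filter a [filter_spec()] used for the statistics signals.
#' @return Named numeric vector of exactly 111 features in schema order.
#' @export
extract_tug_features <- function(rec, seg = NULL, filter = tug_filter_spec()) {
  validate_imu_recording(rec)
  if (is.null(seg)) seg <- segment_tug(rec, filter = filter)
  fs <- rec_fs(rec)
  prep <- preprocess_recording(rec, filter)

  time_f <- tug_time_features(seg)
  by_task <- lapply(seq_len(nrow(seg)), function(i) {
    interval_stats(prep, seg$start_s[i], seg$end_s[i], fs, seg$subtask[i])
  })
  names(by_task) <- seg$subtask

  groups <- list(
    sit_to_stand = by_task$sit_to_stand,
    gait = (by_task$forward_gait + by_task$backward_gait) / 2,
    mid_turn = by_task$mid_turn,
    end_turn = by_task$end_turn,
    stand_to_sit = by_task$stand_to_sit
  )
  stat_f <- unlist(lapply(names(groups), function(g) {
    setNames(groups[[g]], paste("tug", g, names(groups[[g]]), sep = "."))
  }))

  feats <- c(time_f, stat_f)
  feats[tug_feature_names()]
}

#' Aggregate TUG feature vectors across trials
#'
#' Per-subject TUG features are the elementwise mean of the per-trial
#' feature vectors (the protocol collects three trials per subject).
#'
#' @param trials a list of named feature vectors from
#'   [extract_tug_features()].
#' @return A single named feature vector.
#' @export
aggregate_trials <- function(trials) {
  if (length(trials) < 1) stop_gaitage("need at least one trial", "value")
  nm <- names(trials[[1]])
  for (tr in trials) {
    if (!identical(names(tr), nm)) {
      stop_gaitage("trials have inconsistent feature names", "schema")
    }
  }
  Reduce(`+`, trials) / length(trials)
}
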