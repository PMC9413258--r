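#' Threshold specification for TUG sub-task segmentation
#'
#' Chair activity (sit-to-stand, stand-to-sit) is detected on rectified,
#' filtered pitch angular velocity; turn activity (mid-turn, end-turn) on
#' rectified, filtered yaw. The defaults are 25 deg/s (pitch) and 32 deg/s
#' (yaw). `min_event_s` and `merge_gap_s` de-bounce the threshold crossings:
#' supra-threshold runs closer than `merge_gap_s` are merged, then runs
#' shorter than `min_event_s` are dropped.
#'
#' @param pitch_thresh,yaw_thresh thresholds in deg/s.
#' @param min_event_s minimum event duration in seconds.
#' @param merge_gap_s maximum gap to merge in seconds.
#' @return A list of class `threshold_spec`.
#' @export
threshold_spec <- function(pitch_thresh = 25, yaw_thresh = 32,
                           min_event_s = 0.3, merge_gap_s = 0.3) {
  if (pitch_thresh <= 0 || yaw_thresh <= 0) {
    stop_gaitage("thresholds must be > 0 deg/s", "parameter")
  }
  structure(list(pitch_thresh = pitch_thresh, yaw_thresh = yaw_thresh,
                 min_event_s = min_event_s, merge_gap_s = merge_gap_s),
            class = "threshold_spec")
}

#' Detect supra-threshold events in a rectified series
#'
#' Finds maximal runs of samples strictly above `threshold`, merges runs
#' separated by less than `merge_gap_s`, and drops merged runs shorter than
#' `min_event_s`.
#'
#' @param x rectified, filtered series.
#' @param threshold detection threshold (same units as `x`).
#' @param min_event_s,merge_gap_s de-bouncing parameters in seconds.
#' @param fs sampling rate in Hz.
#' @return A tibble with columns `start_s`, `end_s` (times relative to the
#'   first sample), ordered by start; zero rows if nothing crosses.
#' @export
detect_events <- function(x, threshold, min_event_s = 0.3, merge_gap_s = 0.3,
                          fs = 100) {
  above <- x > threshold
  if (!any(above)) {
    return(tibble(start_s = numeric(0), end_s = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(start = starts[r$values], end = ends[r$values])

  # merge runs separated by < merge_gap_s
  if (nrow(runs) > 1) {
    gap_s <- (runs$start[-1] - runs$end[-nrow(runs)] - 1L) / fs
    grp <- cumsum(c(0L, as.integer(gap_s >= merge_gap_s)))
    runs <- runs %>%
      mutate(grp = grp) %>%
      group_by(grp) %>%
      summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  }
  runs <- runs %>%
    mutate(start_s = (.data$start - 1L) / fs, end_s = (.data$end - 1L) / fs) %>%
    filter(.data$end_s - .data$start_s >= min_event_s) %>%
    arrange(.data$start_s)
  runs[c("start_s", "end_s")]
}

tug_subtasks <- function() {
  c("sit_to_stand", "forward_gait", "mid_turn",
    "backward_gait", "end_turn", "stand_to_sit")
}

#' Segment a TUG trial into its six sub-tasks
#'
#' Applies rectification then zero-phase low-pass filtering to pitch and yaw,
#' detects chair events (pitch) and turn events (yaw) by threshold, and
#' requires exactly two of each in chair-turn-turn-chair order. The two gait
#' phases are the gaps between chair and turn events: forward gait runs from
#' the end of sit-to-stand to the start of mid-turn, backward gait from the
#' end of mid-turn to the start of end-turn.
#'
#' @param rec a TUG [imu_recording()] (raw; filtering happens inside).
#' @param spec a [threshold_spec()].
#' @param filter a [filter_spec()] for the pitch/yaw channels.
#' @param rectify_first rectify before filtering (default) or after.
#' @return A tibble of class `tug_segmentation` with columns `subtask`,
#'   `start_s`, `end_s` (six rows in temporal order).
#' @export
segment_tug <- function(rec, spec = threshold_spec(),
                        filter = tug_filter_spec(), rectify_first = TRUE) {
  validate_imu_recording(rec)
  fs <- rec_fs(rec)
  prep <- function(x) {
    if (rectify_first) lowpass(rectify(x), filter, fs) else rectify(lowpass(x, filter, fs))
  }
  chair <- detect_events(prep(rec$pitch), spec$pitch_thresh,
                         spec$min_event_s, spec$merge_gap_s, fs)
  turn <- detect_events(prep(rec$yaw), spec$yaw_thresh,
                        spec$min_event_s, spec$merge_gap_s, fs)
  if (nrow(chair) != 2 || nrow(turn) != 2) {
    stop_gaitage(sprintf(
      "%d chair event(s), expected 2; %d turn event(s), expected 2",
      nrow(chair), nrow(turn)), "segmentation")
  }
  ok_order <- chair$end_s[1] <= turn$start_s[1] &&
    turn$end_s[1] <= turn$start_s[2] &&
    turn$end_s[2] <= chair$start_s[2]
  if (!ok_order) {
    stop_gaitage("events are not in chair-turn-turn-chair order", "segmentation")
  }
  seg <- tibble(
    subtask = tug_subtasks(),
    start_s = c(chair$start_s[1], chair$end_s[1], turn$start_s[1],
                turn$end_s[1], turn$start_s[2], chair$start_s[2]),
    end_s = c(chair$end_s[1], turn$start_s[1], turn$end_s[1],
              turn$start_s[2], turn$end_s[2], chair$end_s[2])
  )
  structure(seg, class = c("tug_segmentation", class(tibble())))
}

#' TUG timing features
#'
#' Six durations from a segmentation: total time (start of sit-to-stand to
#' end of stand-to-sit), the four chair/turn sub-task durations, and the gait
#' time as the mean of the forward- and backward-gait durations.
#'
#' @param seg a `tug_segmentation`.
#' @return A named numeric vector of 6 features (`tug.time.*`).
#' @export
tug_time_features <- function(seg) {
  stopifnot(identical(seg$subtask, tug_subtasks()))
  dur <- setNames(seg$end_s - seg$start_s, seg$subtask)
  c(
    tug.time.total = unname(seg$end_s[6] - seg$start_s[1]),
    tug.time.sit_to_stand = unname(dur["sit_to_stand"]),
    tug.time.gait = unname(mean(dur[c("forward_gait", "backward_gait")])),
    tug.time.mid_turn = unname(dur["mid_turn"]),
    tug.time.end_turn = unname(dur["end_turn"]),
    tug.time.stand_to_sit = unname(dur["stand_to_sit"])
  )
}
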