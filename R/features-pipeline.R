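#' Extract the full 132-feature vector for one subject
#'
#' Segments and extracts each TUG trial, averages the per-trial TUG feature
#' vectors, and appends the 21 6MWT features.
#'
#' @param tug_recs list of TUG [imu_recording()]s (>= 1).
#' @param sixmwt_rec the subject's 6MWT recording.
#' @param height_cm subject height in cm.
#' @param tug_filter,sixmwt_filter [filter_spec()]s for the two tests.
#' @param ... passed to [extract_6mwt_features()].
#' @return Named numeric vector of 132 features in schema order.
#' @export
extract_subject_features <- function(tug_recs, sixmwt_rec, height_cm,
                                     tug_filter = tug_filter_spec(),
                                     sixmwt_filter = sixmwt_filter_spec(),
                                     ...) {
  tug <- aggregate_trials(lapply(tug_recs, extract_tug_features,
                                 filter = tug_filter))
  six <- extract_6mwt_features(sixmwt_rec, height_cm, filter = sixmwt_filter, ...)
  c(tug, six)
}

#' Extract the feature table for a whole cohort
#'
#' Applies [extract_subject_features()] to every subject of a simulated (or
#' assembled) cohort and returns the subjects-by-features table used by the
#' modelling functions.
#'
#' @param cohort a `gaitage_cohort` from [simulate_cohort()].
#' @param ... passed to [extract_subject_features()].
#' @return A validated feature table: tibble with `subject_id`, `age` and
#'   the 132 feature columns.
#' @export
extract_cohort_features <- function(cohort, ...) {
  stopifnot(inherits(cohort, "gaitage_cohort"))
  meta <- cohort$meta
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    sid <- meta$subject_id[i]
    recs <- cohort$recordings[cohort$recordings$subject_id == sid, ]
    tug_recs <- recs$recording[recs$test == "TUG"]
    six_rec <- recs$recording[recs$test == "SIXMWT"][[1]]
    feats <- extract_subject_features(tug_recs, six_rec, meta$height_cm[i], ...)
    bind_cols(tibble(subject_id = sid, age = meta$age[i]),
              as_tibble(as.list(feats)))
  })
  table <- bind_rows(rows)
  validate_feature_table(table)
  table
}
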