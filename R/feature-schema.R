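#' The 132-feature schema
#'
#' The pipeline extracts 132 named features per subject: 111 from the TUG
#' test and 21 from the 6MWT. TUG features are the six sub-task timing
#' features plus \{rms, min, max\} of seven signals (three acceleration axes,
#' the resultant acceleration, and yaw/pitch/roll angular velocity) over five
#' sub-task groups (forward and backward gait are averaged into one `gait`
#' group): 6 + 3 x 7 x 5 = 111. 6MWT features are six gait parameters, step
#' and stride regularity and symmetry index on \{vt, ap, res\} acceleration,
#' and harmonic ratio and approximate entropy on \{vt, ml, ap\}:
#' 6 + 3 + 3 + 3 + 3 + 3 = 21.
#'
#' Names are stable dotted identifiers (e.g. `tug.end_turn.yaw.rms`,
#' `6mwt.gp.average_gait_speed`) so that feature-importance reports are
#' unambiguous.
#'
#' @return A tibble with columns `feature` (name) and `set`
#'   (`"TUG"` or `"SIXMWT"`), 132 rows in canonical order.
#' @export
feature_schema <- function() {
  groups <- c("sit_to_stand", "gait", "mid_turn", "end_turn", "stand_to_sit")
  signals <- c("acc_vt", "acc_ml", "acc_ap", "acc_res", "yaw", "pitch", "roll")
  stats <- c("rms", "min", "max")

  time_feats <- paste0("tug.time.",
                       c("total", "sit_to_stand", "gait", "mid_turn",
                         "end_turn", "stand_to_sit"))
  stat_feats <- as.vector(t(outer(
    as.vector(t(outer(groups, signals, paste, sep = "."))),
    stats, paste, sep = ".")))
  stat_feats <- paste0("tug.", stat_feats)

  gp <- paste0("6mwt.gp.", c("number_of_steps", "steps_per_s", "step_time",
                             "stride_length", "gait_distance",
                             "average_gait_speed"))
  gs_axes <- c("acc_vt", "acc_ap", "acc_res")
  ha_axes <- c("acc_vt", "acc_ml", "acc_ap")
  six <- c(gp,
           paste0("6mwt.sr.", gs_axes),
           paste0("6mwt.str.", gs_axes),
           paste0("6mwt.si.", gs_axes),
           paste0("6mwt.hr.", ha_axes),
           paste0("6mwt.apen.", ha_axes))

  tibble(
    feature = c(time_feats, stat_feats, six),
    set = c(rep("TUG", length(time_feats) + length(stat_feats)),
            rep("SIXMWT", length(six)))
  )
}

tug_feature_names <- function() {
  sch <- feature_schema()
  sch$feature[sch$set == "TUG"]
}

sixmwt_feature_names <- function() {
  sch <- feature_schema()
  sch$feature[sch$set == "SIXMWT"]
}

#' Validate a feature table against the schema
#'
#' A feature table has one row per subject with columns `subject_id`, `age`
#' and the 132 features of [feature_schema()].
#'
#' @param table a data frame.
#' @return `table` invisibly, or an error describing the census mismatch.
#' @export
validate_feature_table <- function(table) {
  if (!all(c("subject_id", "age") %in% names(table))) {
    stop_gaitage("feature table must have 'subject_id' and 'age' columns", "schema")
  }
  if (anyDuplicated(table$subject_id)) {
    stop_gaitage("duplicate subject_id in feature table", "integrity")
  }
  sch <- feature_schema()
  present_tug <- intersect(tug_feature_names(), names(table))
  present_six <- intersect(sixmwt_feature_names(), names(table))
  if (length(present_tug) != 111L || length(present_six) != 21L) {
    stop_gaitage(sprintf(
      "feature census mismatch: %d != 111 TUG columns, %d != 21 6MWT columns",
      length(present_tug), length(present_six)), "schema")
  }
  miss <- vapply(table[sch$feature], function(x) any(is.na(x)), logical(1))
  if (any(miss)) {
    stop_gaitage(paste0("missing values in feature(s): ",
                        paste(names(miss)[miss], collapse = ", ")), "schema")
  }
  invisible(table)
}
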