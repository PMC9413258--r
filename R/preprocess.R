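#' Low-pass filter specifications
#'
#' Filters are specified the way interactive signal-processing toolboxes
#' specify a `lowpass()` call: a passband edge in normalized frequency
#' (`passband` in units of pi rad/sample, i.e. a fraction of the Nyquist
#' frequency), a `steepness` in (0.5, 1) that places the stopband edge at
#' `passband + (1 - steepness) * (1 - passband)` (the steeper, the narrower
#' the transition band), and a stopband attenuation in dB. The design used
#' here is the minimal-order Butterworth meeting 3 dB of passband ripple at
#' the passband edge and `stopband_atten` dB at the stopband edge, with the
#' cutoff placed so the stopband requirement is met exactly; it is applied
#' forward-backward (zero phase) so event boundaries are not delayed.
#'
#' `tug_filter_spec()` (passband 0.01 pi/sample, steepness 0.83, 60 dB) and
#' `sixmwt_filter_spec()` (0.02 pi/sample, 0.86, 40 dB) are the defaults used
#' for the two tests; at 100 Hz the TUG passband edge is 0.5 Hz, which is
#' aggressive for gait-band content but retained as the protocol default —
#' both specs are plain arguments everywhere they are used.
#'
#' @param passband passband edge, fraction of Nyquist, in (0, 1).
#' @param steepness transition steepness in (0.5, 1).
#' @param stopband_atten stopband attenuation in dB.
#' @param zero_phase apply the filter forward and backward.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(passband, steepness, stopband_atten, zero_phase = TRUE) {
  if (!(passband > 0 && passband < 1)) {
    stop_gaitage("passband must be in (0, 1) (fraction of Nyquist)", "parameter")
  }
  if (!(steepness > 0.5 && steepness < 1)) {
    stop_gaitage("steepness must be in (0.5, 1)", "parameter")
  }
  if (stopband_atten <= 0) stop_gaitage("stopband_atten must be > 0 dB", "parameter")
  structure(list(passband = passband, steepness = steepness,
                 stopband_atten = stopband_atten, zero_phase = zero_phase),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @export
tug_filter_spec <- function() filter_spec(0.01, 0.83, 60)

#' @rdname filter_spec
#' @export
sixmwt_filter_spec <- function() filter_spec(0.02, 0.86, 40)

# minimal-order Butterworth for a filter_spec; returns list(n, wc, filt)
design_butterworth <- function(spec, rp = 3) {
  wp <- spec$passband
  ws <- wp + (1 - spec$steepness) * (1 - wp)
  rs <- spec$stopband_atten
  n <- ceiling(log10((10^(rs / 10) - 1) / (10^(rp / 10) - 1)) /
                 (2 * log10(ws / wp)))
  n <- max(n, 1)
  # cutoff meeting the stopband attenuation exactly -> maximal passband flatness
  wc <- ws / (10^(rs / 10) - 1)^(1 / (2 * n))
  list(n = n, wc = wc, filt = signal::butter(n, wc, type = "low"))
}

#' Zero-phase Butterworth low-pass filtering
#'
#' @param x numeric series.
#' @param spec a [filter_spec()].
#' @param fs sampling rate in Hz (used only for the length check; the design
#'   itself is in normalized frequency).
#' @return Filtered series of the same length.
#' @export
lowpass <- function(x, spec = tug_filter_spec(), fs = 100) {
  des <- design_butterworth(spec)
  if (length(x) <= 3 * max(des$n, 1)) {
    stop_gaitage(sprintf("series too short to filter: %d samples for order %d",
                         length(x), des$n), "length")
  }
  if (spec$zero_phase) {
    signal::filtfilt(des$filt, x)
  } else {
    as.numeric(signal::filter(des$filt, x))
  }
}

#' Resultant (Euclidean-norm) acceleration
#'
#' Combines the three linear acceleration axes into the resultant magnitude
#' `sqrt(acc_vt^2 + acc_ml^2 + acc_ap^2)`.
#'
#' @param acc_vt,acc_ml,acc_ap acceleration series of equal length.
#' @return Non-negative series of the same length.
#' @export
resultant_acceleration <- function(acc_vt, acc_ml, acc_ap) {
  n <- length(acc_vt)
  if (length(acc_ml) != n || length(acc_ap) != n) {
    stop_gaitage(sprintf("channel lengths differ: %d, %d, %d",
                         n, length(acc_ml), length(acc_ap)), "shape")
  }
  sqrt(acc_vt^2 + acc_ml^2 + acc_ap^2)
}

#' Full-wave rectification
#'
#' Elementwise absolute value; applied to pitch and yaw before threshold
#' detection so that turn/rise direction does not matter.
#'
#' @param x numeric series.
#' @return `abs(x)`.
#' @export
rectify <- function(x) abs(x)

#' Preprocess a recording for feature extraction
#'
#' Low-pass filters all six channels with the test-appropriate filter and
#' adds the resultant acceleration `acc_res` computed from the filtered
#' acceleration axes.
#'
#' @param rec an [imu_recording()].
#' @param spec a [filter_spec()]; default chosen by the recording's test tag.
#' @return The recording with filtered channels and an `acc_res` column.
#' @export
preprocess_recording <- function(rec, spec = NULL) {
  validate_imu_recording(rec)
  if (is.null(spec)) {
    spec <- if (rec_test(rec) == "TUG") tug_filter_spec() else sixmwt_filter_spec()
  }
  fs <- rec_fs(rec)
  out <- as_tibble(rec)
  for (ch in imu_channels()) out[[ch]] <- lowpass(rec[[ch]], spec, fs)
  out$acc_res <- resultant_acceleration(out$acc_vt, out$acc_ml, out$acc_ap)
  new_imu_recording(out, subject_id = attr(rec, "subject_id"),
                    test = rec_test(rec),
                    trial_index = attr(rec, "trial_index"), fs = fs)
}
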