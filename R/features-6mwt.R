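#' Detect steps from vertical trunk acceleration
#'
#' Step events during the 6MWT are the local maxima of the filtered vertical
#' acceleration that exceed an adaptive height threshold (a fraction of the
#' maximum of the de-meaned signal) and are separated by a minimum inter-peak
#' interval. The adaptive threshold keeps the weaker of the two alternating
#' step peaks detectable in asymmetric gait.
#'
#' @param acc_vt filtered vertical acceleration.
#' @param fs sampling rate in Hz.
#' @param height_frac adaptive threshold as a fraction of the signal maximum.
#' @param min_step_s minimum inter-peak interval in seconds.
#' @return Sorted numeric vector of step times in seconds (relative to the
#'   first sample); empty for flat signals.
#' @export
detect_steps <- function(acc_vt, fs = 100, height_frac = 0.25,
                         min_step_s = 0.35) {
  x <- acc_vt - mean(acc_vt)
  if (max(x) <= 0 || max(x) - min(x) < .Machine$double.eps^0.5) {
    return(numeric(0))
  }
  pk <- pracma::findpeaks(x, minpeakheight = height_frac * max(x),
                          minpeakdistance = max(1L, round(min_step_s * fs)))
  if (is.null(pk)) return(numeric(0))
  sort((pk[, 2] - 1) / fs)
}

#' Gait parameters from detected steps
#'
#' The six spatiotemporal 6MWT gait parameters. Stride length is estimated
#' from stature as `k_height * height`; a step covers half a stride, so the
#' walking distance is `step_count * stride_length / 2` and average gait
#' speed is distance over duration.
#'
#' @param step_times step event times in seconds.
#' @param height_cm subject height in cm.
#' @param duration_s walk duration in seconds.
#' @param k_height stride-length-to-height ratio (default 0.83, i.e. a step
#'   of 0.415 stature).
#' @return Named numeric vector of the six `6mwt.gp.*` features (distances in
#'   m, speed in m/s).
#' @export
gait_parameters <- function(step_times, height_cm, duration_s, k_height = 0.83) {
  if (duration_s <= 0) stop_gaitage("duration_s must be > 0", "parameter")
  n <- length(step_times)
  if (n < 2) {
    stop_gaitage(sprintf("need at least 2 steps to compute gait parameters (got %d)", n),
                 "gait_parameters")
  }
  stride_length <- k_height * height_cm / 100
  gait_distance <- (stride_length / 2) * n
  c(
    `6mwt.gp.number_of_steps` = as.numeric(n),
    `6mwt.gp.steps_per_s` = n / duration_s,
    `6mwt.gp.step_time` = mean(diff(step_times)),
    `6mwt.gp.stride_length` = stride_length,
    `6mwt.gp.gait_distance` = gait_distance,
    `6mwt.gp.average_gait_speed` = gait_distance / duration_s
  )
}

#' Unbiased autocorrelation of a series
#'
#' `A(m) = 1/(N - m) * sum_i x_i x_(i+m)` computed on the mean-removed
#' signal and normalized by the zero-lag value, so `A(0) = 1` and regularity
#' peaks are directly interpretable as correlation coefficients.
#'
#' @param x numeric series.
#' @param max_lag maximum lag in samples (< length(x)).
#' @return Numeric vector of length `max_lag + 1`, lags 0..max_lag.
#' @export
unbiased_autocorr <- function(x, max_lag) {
  n <- length(x)
  if (max_lag >= n) {
    stop_gaitage(sprintf("max_lag (%d) must be < series length (%d)", max_lag, n),
                 "lag")
  }
  x <- x - mean(x)
  a0 <- sum(x^2) / n
  if (a0 <= 0) stop_gaitage("series has zero variance", "value")
  a <- vapply(0:max_lag, function(m) {
    sum(x[seq_len(n - m)] * x[seq_len(n - m) + m]) / (n - m)
  }, numeric(1))
  a / a[1]
}

#' Step and stride regularity from the autocorrelation
#'
#' The first dominant peak of the normalized unbiased autocorrelation after
#' zero lag is the step regularity (SR); the second — at roughly twice the
#' step lag — is the stride regularity (STR). Each is located as the highest
#' local maximum within its lag window; `stride_window_s` defaults to twice
#' the step window. Passing windows centred on a measured step time (as
#' [extract_6mwt_features()] does) keeps minor harmonic ripples from being
#' mistaken for the gait peaks. Values close to 1 indicate highly regular
#' gait.
#'
#' @param autocorr normalized autocorrelation from [unbiased_autocorr()].
#' @param fs sampling rate in Hz.
#' @param step_window_s two-element lag window (seconds) for the step peak.
#' @param stride_window_s two-element lag window for the stride peak;
#'   `NULL` uses twice the step window.
#' @return Named list `sr`, `str`, `sr_lag_s`, `str_lag_s`.
#' @export
regularity <- function(autocorr, fs = 100, step_window_s = c(0.25, 1.2),
                       stride_window_s = NULL) {
  if (is.null(stride_window_s)) stride_window_s <- 2 * step_window_s
  pk <- pracma::findpeaks(autocorr)
  if (is.null(pk)) stop_gaitage("no autocorrelation peaks found", "regularity")
  lag_s <- (pk[, 2] - 1) / fs  # peak positions; index 1 is lag 0
  val <- pk[, 1]

  pick <- function(window, label) {
    in_win <- which(lag_s >= window[1] & lag_s <= window[2])
    if (length(in_win) == 0) {
      stop_gaitage(paste0("no autocorrelation peak in the ", label, " window"),
                   "regularity")
    }
    in_win[which.max(val[in_win])]
  }
  i_sr <- pick(step_window_s, "step-lag")
  i_str <- pick(stride_window_s, "stride-lag")
  list(sr = unname(val[i_sr]), str = unname(val[i_str]),
       sr_lag_s = unname(lag_s[i_sr]), str_lag_s = unname(lag_s[i_str]))
}

#' Gait symmetry index
#'
#' `SI = (SR - STR) / max(SR, STR)`. Zero indicates perfectly symmetric
#' gait; negative values arise when alternating steps differ (step
#' regularity suppressed relative to stride regularity).
#'
#' @param sr,str step and stride regularity.
#' @return The symmetry index.
#' @export
symmetry_index <- function(sr, str) {
  mx <- max(sr, str)
  if (mx == 0) stop_gaitage("SI undefined: max(SR, STR) is zero", "value")
  (sr - str) / mx
}

#' Harmonic ratio of gait acceleration
#'
#' Discrete Fourier magnitudes at integer multiples of the stride frequency
#' over windows of exactly ten strides. For the vertical and
#' anterior-posterior axes the harmonic ratio is the even-harmonic sum over
#' the odd-harmonic sum (step-periodic content is even relative to the
#' stride); for the mediolateral axis, where sway alternates side per
#' stride, it is odd over even. The ratio is averaged over consecutive
#' non-overlapping ten-stride windows and capped at `cap` when the
#' denominator vanishes. Smoother, more step-periodic acceleration gives a
#' higher ratio on vt/ap.
#'
#' @param x filtered acceleration series.
#' @param stride_time_s stride period in seconds (> 0).
#' @param fs sampling rate in Hz.
#' @param axis `"vt"`, `"ap"` (even/odd) or `"ml"` (odd/even).
#' @param n_harmonics number of stride harmonics summed (default 20: 10 even
#'   + 10 odd).
#' @param cap sentinel value returned when the denominator is zero.
#' @return The harmonic ratio (>= 0).
#' @export
harmonic_ratio <- function(x, stride_time_s, fs = 100,
                           axis = c("vt", "ap", "ml"),
                           n_harmonics = 20, cap = 1e3) {
  axis <- match.arg(axis)
  if (stride_time_s <= 0) stop_gaitage("stride_time_s must be > 0", "parameter")
  win <- round(10 * stride_time_s * fs)
  if (length(x) < win) {
    stop_gaitage(sprintf(
      "segment of %d samples is shorter than ten strides (%d samples)",
      length(x), win), "harmonic_ratio")
  }
  if (1 + 10 * n_harmonics > floor(win / 2)) {
    stop_gaitage("ten-stride window too short for requested n_harmonics", "parameter")
  }
  n_win <- floor(length(x) / win)
  ratios <- vapply(seq_len(n_win), function(w) {
    seg <- x[((w - 1) * win + 1):(w * win)]
    amp <- Mod(fft(seg - mean(seg)))
    harm <- amp[1 + 10 * seq_len(n_harmonics)]  # bin of k * stride frequency
    even <- sum(harm[seq(2, n_harmonics, by = 2)])
    odd <- sum(harm[seq(1, n_harmonics, by = 2)])
    num <- if (axis == "ml") odd else even
    den <- if (axis == "ml") even else odd
    if (den <= num / cap) cap else num / den
  }, numeric(1))
  mean(ratios)
}

#' Approximate entropy (Pincus)
#'
#' `ApEn(m, r, N) = Phi^m(r) - Phi^(m+1)(r)`, with `Phi` the average log
#' fraction of embedded vectors within Chebyshev distance `r` (self-matches
#' included). Lower values indicate a more regular signal; a constant series
#' has entropy 0. Long records are split into consecutive epochs and the
#' per-epoch entropies averaged, bounding the quadratic cost.
#'
#' @param x numeric series of length >= 100.
#' @param m_embed embedding dimension (default 2).
#' @param r tolerance; default `0.2 * sd(x)`.
#' @param fs sampling rate in Hz (for epoching).
#' @param epoch_s epoch length in seconds; `Inf` processes the whole series
#'   at once.
#' @return Approximate entropy (>= 0 up to numerical noise).
#' @export
approximate_entropy <- function(x, m_embed = 2, r = NULL, fs = 100,
                                epoch_s = 30) {
  if (length(x) < 100) {
    stop_gaitage("series too short for approximate entropy (need >= 100 samples)",
                 "length")
  }
  if (is.null(r)) {
    s <- sd(x)
    if (s == 0) return(0)  # all embedded vectors identical for any r > 0
    r <- 0.2 * s
  }
  if (r <= 0) stop_gaitage("tolerance r must be > 0", "parameter")
  ep <- if (is.finite(epoch_s)) round(epoch_s * fs) else length(x)
  n_ep <- max(1L, floor(length(x) / ep))
  vals <- vapply(seq_len(n_ep), function(k) {
    seg <- if (n_ep == 1) x else x[((k - 1) * ep + 1):(k * ep)]
    apen_pincus(seg, m_embed, r)
  }, numeric(1))
  mean(vals)
}

#' Extract the 21 6MWT features
#'
#' Runs the full 6MWT feature chain on a recording: preprocessing, step
#' detection on vertical acceleration, gait parameters, step/stride
#' regularity and symmetry index on the vt/ap/resultant axes, harmonic ratio
#' and approximate entropy on the vt/ml/ap axes.
#'
#' @param rec a 6MWT [imu_recording()] (raw; preprocessing happens inside).
#' @param height_cm subject height in cm.
#' @param filter a [filter_spec()].
#' @param k_height stride-length-to-height ratio.
#' @param apen_epoch_s approximate-entropy epoch length in seconds.
#' @return Named numeric vector of exactly 21 features in schema order.
#' @export
extract_6mwt_features <- function(rec, height_cm, filter = sixmwt_filter_spec(),
                                  k_height = 0.83, apen_epoch_s = 30) {
  validate_imu_recording(rec)
  fs <- rec_fs(rec)
  prep <- preprocess_recording(rec, filter)
  duration_s <- rec_duration(rec)

  steps <- detect_steps(prep$acc_vt, fs)
  gp <- gait_parameters(steps, height_cm, duration_s, k_height)
  step_time <- unname(gp["6mwt.gp.step_time"])
  stride_time <- 2 * step_time

  max_lag <- min(nrow(prep) - 1L, ceiling(1.5 * stride_time * fs))
  gs_axes <- c(acc_vt = "acc_vt", acc_ap = "acc_ap", acc_res = "acc_res")
  reg <- lapply(gs_axes, function(ch) {
    regularity(unbiased_autocorr(prep[[ch]], max_lag), fs,
               step_window_s = step_time * c(0.7, 1.3),
               stride_window_s = step_time * c(1.6, 2.6))
  })
  sr <- vapply(reg, function(r) r$sr, numeric(1))
  str_ <- vapply(reg, function(r) r$str, numeric(1))
  si <- mapply(symmetry_index, sr, str_)

  ha_axes <- c(acc_vt = "vt", acc_ml = "ml", acc_ap = "ap")
  hr <- vapply(names(ha_axes), function(ch) {
    harmonic_ratio(prep[[ch]], stride_time, fs, axis = ha_axes[[ch]])
  }, numeric(1))
  apen <- vapply(names(ha_axes), function(ch) {
    approximate_entropy(prep[[ch]], fs = fs, epoch_s = apen_epoch_s)
  }, numeric(1))

  feats <- c(
    gp,
    setNames(sr, paste0("6mwt.sr.", names(gs_axes))),
    setNames(str_, paste0("6mwt.str.", names(gs_axes))),
    setNames(si, paste0("6mwt.si.", names(gs_axes))),
    setNames(hr, paste0("6mwt.hr.", names(ha_axes))),
    setNames(apen, paste0("6mwt.apen.", names(ha_axes)))
  )
  feats[sixmwt_feature_names()]
}
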