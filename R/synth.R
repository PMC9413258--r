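#' Gait-model parameters for the synthetic generator
#'
#' The synthetic signal model is a harmonic sum: vertical acceleration is a
#' step-frequency fundamental plus a stride-frequency component whose
#' relative amplitude `asymmetry` encodes left/right step asymmetry, plus a
#' high stride-harmonic whose relative amplitude `smoothness` encodes loss
#' of smoothness (it lowers the harmonic ratio), plus Gaussian noise. The
#' mediolateral axis is stride-periodic (sway alternates side each stride)
#' and the anterior-posterior axis mirrors the vertical structure. TUG
#' trials add half-sine pitch pulses for the two chair transfers and yaw
#' pulses for the two turns, with peak angular velocities that must exceed
#' the segmentation thresholds (25 and 32 deg/s) to be detectable.
#'
#' @param step_time step period in seconds (> 0).
#' @param gait_speed straight-line walking speed in m/s (sets the TUG gait
#'   phase durations over the 3 m course).
#' @param asymmetry relative stride-frequency amplitude, in `[0, 1)`.
#' @param smoothness relative high-harmonic amplitude (>= 0); higher means
#'   rougher acceleration.
#' @param noise_sd accelerometer noise SD in m/s^2 (gyroscope noise scales
#'   with it).
#' @param turn_peak_yaw peak yaw angular velocity of turn pulses in deg/s
#'   (> 32).
#' @param chair_peak_pitch peak pitch angular velocity of chair pulses in
#'   deg/s (> 25).
#' @param acc_amp_vt,acc_amp_ml,acc_amp_ap acceleration amplitudes in m/s^2.
#' @param chair_width_s,turn_width_s half-sine pulse widths in seconds.
#' @return A list of class `gait_params`.
#' @export
gait_params <- function(step_time = 0.55, gait_speed = 1.1, asymmetry = 0.1,
                        smoothness = 0.1, noise_sd = 0.1,
                        turn_peak_yaw = 85, chair_peak_pitch = 60,
                        acc_amp_vt = 1.6, acc_amp_ml = 0.8, acc_amp_ap = 1.1,
                        chair_width_s = 1.5, turn_width_s = 2.0) {
  if (step_time <= 0) stop_gaitage("step_time must be > 0", "parameter")
  if (gait_speed <= 0) stop_gaitage("gait_speed must be > 0", "parameter")
  if (asymmetry < 0 || asymmetry >= 1) {
    stop_gaitage("asymmetry must be in [0, 1)", "parameter")
  }
  if (smoothness < 0) stop_gaitage("smoothness must be >= 0", "parameter")
  if (noise_sd < 0) stop_gaitage("noise_sd must be >= 0", "parameter")
  if (turn_peak_yaw <= 32) {
    stop_gaitage("turn_peak_yaw must exceed the 32 deg/s detection threshold",
                 "parameter")
  }
  if (chair_peak_pitch <= 25) {
    stop_gaitage("chair_peak_pitch must exceed the 25 deg/s detection threshold",
                 "parameter")
  }
  structure(list(step_time = step_time, gait_speed = gait_speed,
                 asymmetry = asymmetry, smoothness = smoothness,
                 noise_sd = noise_sd, turn_peak_yaw = turn_peak_yaw,
                 chair_peak_pitch = chair_peak_pitch,
                 acc_amp_vt = acc_amp_vt, acc_amp_ml = acc_amp_ml,
                 acc_amp_ap = acc_amp_ap, chair_width_s = chair_width_s,
                 turn_width_s = turn_width_s),
            class = "gait_params")
}

#' Age couplings for the synthetic cohort
#'
#' `default_age_coupling()` maps age (years) linearly onto every gait-model
#' parameter in the direction reported for ageing gait: slower steps, slower
#' walking, more asymmetry, less smoothness, more noise, weaker turn and
#' chair transfer angular velocity, smaller acceleration amplitudes.
#' `planted_age_coupling()` couples age only to walking pace (step time and
#' gait speed) and to the turn yaw angular-velocity peak, leaving all
#' other parameters age-independent — a cohort in which the age signal is
#' deliberately split across the two tests (6MWT gait parameters and TUG
#' turn features), used for planted-signal recovery experiments.
#'
#' @param age age in years (scalar).
#' @return A [gait_params()] object.
#' @export
default_age_coupling <- function(age) {
  d <- age - 60
  gait_params(
    step_time = 0.50 + 0.005 * d,
    gait_speed = 1.25 - 0.012 * d,
    asymmetry = 0.05 + 0.005 * d,
    smoothness = 0.05 + 0.005 * d,
    noise_sd = 0.10 + 0.003 * d,
    turn_peak_yaw = 95 - 0.6 * d,
    chair_peak_pitch = 65 - 0.5 * d,
    acc_amp_vt = 1.8 - 0.015 * d,
    acc_amp_ml = 0.9 - 0.008 * d,
    acc_amp_ap = 1.2 - 0.010 * d
  )
}

#' @rdname default_age_coupling
#' @export
planted_age_coupling <- function(age) {
  d <- age - 60
  gait_params(
    step_time = 0.50 + 0.005 * d,
    gait_speed = 1.25 - 0.012 * d,
    asymmetry = 0.10,
    smoothness = 0.10,
    noise_sd = 0.15,
    turn_peak_yaw = 95 - 0.6 * d,
    chair_peak_pitch = 60,
    acc_amp_vt = 1.6, acc_amp_ml = 0.8, acc_amp_ap = 1.1
  )
}

# harmonic-sum gait acceleration model; t in seconds
gait_acc_model <- function(t, p) {
  f_step <- 1 / p$step_time
  f_str <- f_step / 2
  # roughness enters as the 3rd stride harmonic on vt/ap (odd -> lowers their
  # even/odd harmonic ratio) and the 2nd on ml (even -> lowers its odd/even
  # ratio); all lie inside the walk filter's passband so they survive
  # preprocessing
  vt <- p$acc_amp_vt * (sin(2 * pi * f_step * t) +
                          p$asymmetry * sin(2 * pi * f_str * t) +
                          p$smoothness * sin(2 * pi * 3 * f_str * t))
  ap <- p$acc_amp_ap * (sin(2 * pi * f_step * t + 0.3) +
                          p$asymmetry * sin(2 * pi * f_str * t + 0.2) +
                          p$smoothness * sin(2 * pi * 3 * f_str * t + 0.8))
  ml <- p$acc_amp_ml * (sin(2 * pi * f_str * t) +
                          p$smoothness * sin(2 * pi * 2 * f_str * t + 0.9))
  list(vt = vt, ml = ml, ap = ap)
}

half_sine_pulse <- function(t, t0, width, peak) {
  u <- (t - t0) / width
  ifelse(u >= 0 & u <= 1, peak * sin(pi * u), 0)
}

# time at which a half-sine pulse crosses `thresh` on the way up/down
pulse_crossings <- function(t0, width, peak, thresh) {
  dt <- (width / pi) * asin(thresh / peak)
  c(start = t0 + dt, end = t0 + width - dt)
}

#' Simulate a six-minute walk recording
#'
#' Generates a 6MWT trunk-IMU recording from the harmonic gait model, with
#' ground-truth step times at integer multiples of the step period.
#'
#' @param params a [gait_params()].
#' @param duration_s walk duration in seconds (> 10 step periods).
#' @param fs sampling rate in Hz.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param subject_id,trial_index recording metadata.
#' @return List with `recording` (an [imu_recording()]) and `truth` (list
#'   with `step_times`, `step_count` and the `params` used).
#' @export
simulate_6mwt <- function(params, duration_s = 360, fs = 100, seed = NULL,
                          subject_id = "synthetic", trial_index = 1L) {
  stopifnot(inherits(params, "gait_params"))
  if (duration_s <= 10 * params$step_time) {
    stop_gaitage("duration_s must exceed 10 step periods", "parameter")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  g <- gait_acc_model(t, params)
  noise <- function() if (params$noise_sd > 0) rnorm(n, 0, params$noise_sd) else 0
  gyro_sd <- 10 * params$noise_sd
  gnoise <- function() if (gyro_sd > 0) rnorm(n, 0, gyro_sd) else 0

  rec <- imu_recording(
    time_s = t,
    acc_vt = g$vt + noise(), acc_ml = g$ml + noise(), acc_ap = g$ap + noise(),
    yaw = gnoise(), pitch = gnoise(), roll = gnoise(),
    subject_id = subject_id, test = "SIXMWT", trial_index = trial_index, fs = fs
  )
  step_count <- floor(duration_s / params$step_time + 1e-9)
  truth <- list(step_times = params$step_time * seq_len(step_count),
                step_count = step_count, params = params)
  list(recording = rec, truth = truth)
}

#' Simulate a TUG trial recording
#'
#' Builds a TUG trial as two pitch half-sine pulses (chair transfers) and
#' two yaw half-sine pulses (turns) in chair-turn-turn-chair order, with
#' harmonic-model gait acceleration filling the two gait phases (3 m at the
#' model's gait speed each). Ground-truth sub-task intervals are the
#' analytic threshold crossings of the clean pulses at the default 25/32
#' deg/s thresholds, with the gait phases as the gaps between them.
#'
#' @inheritParams simulate_6mwt
#' @param thresholds a [threshold_spec()] defining the ground-truth crossing
#'   levels.
#' @return List with `recording` and `truth` (tibble of six labelled
#'   intervals plus the `params` used).
#' @export
simulate_tug_trial <- function(params, fs = 100, seed = NULL,
                               subject_id = "synthetic", trial_index = 1L,
                               thresholds = threshold_spec()) {
  stopifnot(inherits(params, "gait_params"))
  if (!is.null(seed)) set.seed(seed)
  wc <- params$chair_width_s
  wt <- params$turn_width_s
  gd <- 3 / params$gait_speed

  c1 <- 1.0
  y1 <- c1 + wc + gd
  y2 <- y1 + wt + gd
  c2 <- y2 + wt + 0.5
  total <- c2 + wc + 1.0
  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs

  sgn <- sample(c(-1, 1), 4, replace = TRUE)  # turn/rotation direction is free
  pitch <- sgn[1] * half_sine_pulse(t, c1, wc, params$chair_peak_pitch) +
    sgn[4] * half_sine_pulse(t, c2, wc, params$chair_peak_pitch)
  yaw <- sgn[2] * half_sine_pulse(t, y1, wt, params$turn_peak_yaw) +
    sgn[3] * half_sine_pulse(t, y2, wt, params$turn_peak_yaw)

  g <- gait_acc_model(t, params)
  gait_win <- (t >= c1 + wc & t < y1) | (t >= y1 + wt & t < y2)
  chair_win <- half_sine_pulse(t, c1, wc, 1) + half_sine_pulse(t, c2, wc, 1)
  turn_win <- half_sine_pulse(t, y1, wt, 1) + half_sine_pulse(t, y2, wt, 1)

  noise <- function(sdev) if (sdev > 0) rnorm(n, 0, sdev) else 0
  acc_vt <- g$vt * gait_win + 1.5 * params$acc_amp_vt * chair_win + noise(params$noise_sd)
  acc_ml <- g$ml * gait_win + 1.2 * params$acc_amp_ml * turn_win + noise(params$noise_sd)
  acc_ap <- g$ap * gait_win + 0.8 * params$acc_amp_ap * chair_win + noise(params$noise_sd)
  roll <- 5 * params$acc_amp_ml * sin(2 * pi * t / params$step_time / 2) * gait_win +
    noise(10 * params$noise_sd)

  rec <- imu_recording(
    time_s = t, acc_vt = acc_vt, acc_ml = acc_ml, acc_ap = acc_ap,
    yaw = yaw + noise(10 * params$noise_sd),
    pitch = pitch + noise(10 * params$noise_sd), roll = roll,
    subject_id = subject_id, test = "TUG", trial_index = trial_index, fs = fs
  )

  cc1 <- pulse_crossings(c1, wc, params$chair_peak_pitch, thresholds$pitch_thresh)
  cy1 <- pulse_crossings(y1, wt, params$turn_peak_yaw, thresholds$yaw_thresh)
  cy2 <- pulse_crossings(y2, wt, params$turn_peak_yaw, thresholds$yaw_thresh)
  cc2 <- pulse_crossings(c2, wc, params$chair_peak_pitch, thresholds$pitch_thresh)
  truth_seg <- tibble(
    subtask = tug_subtasks(),
    start_s = unname(c(cc1["start"], cc1["end"], cy1["start"],
                       cy1["end"], cy2["start"], cc2["start"])),
    end_s = unname(c(cc1["end"], cy1["start"], cy1["end"],
                     cy2["start"], cy2["end"], cc2["end"]))
  )
  list(recording = rec, truth = list(segmentation = truth_seg, params = params))
}

#' Cohort specification
#'
#' Defaults emulate the study cohort: 136 subjects aged 60-90 with 36/64/36
#' in their 60s/70s/80s, 33 male and 103 female, three TUG trials each.
#'
#' @param n_subjects cohort size.
#' @param age_group_counts named counts for the 60s/70s/80s decades (must sum
#'   to `n_subjects`).
#' @param sex_counts named counts for M/F (must sum to `n_subjects`).
#' @param tug_trials TUG trials per subject.
#' @param ages optional explicit age vector (overrides the decade draw; must
#'   have length `n_subjects`).
#' @param height_mean named mean heights in cm by sex.
#' @param height_sd height SD in cm (0 gives every subject the sex mean).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 136,
                        age_group_counts = c(`60s` = 36, `70s` = 64, `80s` = 36),
                        sex_counts = c(M = 33, F = 103),
                        tug_trials = 3, ages = NULL,
                        height_mean = c(M = 165, F = 152), height_sd = 6) {
  if (sum(age_group_counts) != n_subjects) {
    stop_gaitage("age_group_counts must sum to n_subjects", "parameter")
  }
  if (sum(sex_counts) != n_subjects) {
    stop_gaitage("sex_counts must sum to n_subjects", "parameter")
  }
  if (!is.null(ages) && length(ages) != n_subjects) {
    stop_gaitage("ages must have length n_subjects", "parameter")
  }
  structure(list(n_subjects = n_subjects, age_group_counts = age_group_counts,
                 sex_counts = sex_counts, tug_trials = tug_trials, ages = ages,
                 height_mean = height_mean, height_sd = height_sd),
            class = "cohort_spec")
}

#' Simulate a full cohort
#'
#' Draws subject metadata (ages uniform within each decade at the specified
#' counts, sexes at the specified counts, heights by sex), maps age to
#' gait-model parameters through `coupling`, applies multiplicative
#' log-normal subject-level jitter, and generates `tug_trials` TUG
#' recordings plus one 6MWT recording per subject. Identical `(spec, seed)`
#' give identical output.
#'
#' @param spec a [cohort_spec()].
#' @param coupling a function age -> [gait_params()].
#' @param seed integer seed.
#' @param duration_6mwt 6MWT duration in seconds.
#' @param fs sampling rate in Hz.
#' @param subject_sd SD of the multiplicative subject-level parameter jitter
#'   (0 makes parameters a deterministic function of age).
#' @return A list of class `gaitage_cohort` with `meta` (tibble:
#'   `subject_id`, `age`, `height_cm`, `sex`) and `recordings` (tibble:
#'   `subject_id`, `test`, `trial_index`, list-columns `recording`, `truth`).
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            coupling = default_age_coupling, seed = 1,
                            duration_6mwt = 360, fs = 100, subject_sd = 0.05) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- spec$n_subjects

  if (!is.null(spec$ages)) {
    ages <- spec$ages
  } else {
    lo <- c(`60s` = 60, `70s` = 70, `80s` = 80)
    ages <- unlist(lapply(names(spec$age_group_counts), function(g) {
      lo[[g]] + 10 * runif(spec$age_group_counts[[g]])
    }))
  }
  sex <- sample(rep(names(spec$sex_counts), spec$sex_counts))
  height <- spec$height_mean[sex] + if (spec$height_sd > 0) {
    rnorm(n, 0, spec$height_sd)
  } else 0

  meta <- tibble(subject_id = sprintf("S%03d", seq_len(n)),
                 age = as.numeric(ages), height_cm = as.numeric(height),
                 sex = sex)

  jitter_params <- function(p) {
    if (subject_sd == 0) return(p)
    jf <- function(v) v * exp(rnorm(1, 0, subject_sd))
    for (f in c("step_time", "gait_speed", "asymmetry", "smoothness",
                "noise_sd", "turn_peak_yaw", "chair_peak_pitch",
                "acc_amp_vt", "acc_amp_ml", "acc_amp_ap")) {
      p[[f]] <- jf(p[[f]])
    }
    do.call(gait_params, p)
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- jitter_params(coupling(meta$age[i]))
    sid <- meta$subject_id[i]
    tug <- lapply(seq_len(spec$tug_trials), function(k) {
      simulate_tug_trial(p, fs = fs, subject_id = sid, trial_index = k)
    })
    walk <- simulate_6mwt(p, duration_s = duration_6mwt, fs = fs,
                          subject_id = sid)
    rows[[i]] <- tibble(
      subject_id = sid,
      test = c(rep("TUG", spec$tug_trials), "SIXMWT"),
      trial_index = c(seq_len(spec$tug_trials), 1L),
      recording = c(lapply(tug, `[[`, "recording"), list(walk$recording)),
      truth = c(lapply(tug, `[[`, "truth"), list(walk$truth))
    )
  }
  structure(list(meta = meta, recordings = bind_rows(rows)),
            class = "gaitage_cohort")
}

#' @export
print.gaitage_cohort <- function(x, ...) {
  cat(sprintf("<gaitage_cohort> %d subjects, %d recordings\n",
              nrow(x$meta), nrow(x$recordings)))
  invisible(x)
}
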