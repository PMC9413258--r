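# Shared fixtures and independent brute-force oracles.

fast_params <- function(...) {
  args <- list(step_time = 0.55, gait_speed = 1.1, asymmetry = 0.1,
               smoothness = 0.1, noise_sd = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(gait_params, args)
}

quick_walk_features <- function(params, duration_s = 120, height_cm = 155) {
  extract_6mwt_features(simulate_6mwt(params, duration_s = duration_s)$recording,
                        height_cm = height_cm)
}

small_cohort_spec <- function(n = 12) {
  per <- n / 3
  cohort_spec(n_subjects = n,
              age_group_counts = c(`60s` = per, `70s` = per, `80s` = per),
              sex_counts = c(M = floor(n / 4), F = n - floor(n / 4)))
}

# a syntactically valid feature table with schema names; features are noise
# unless a generator function is supplied per column
random_feature_table <- function(n, seed = 1, age = NULL) {
  set.seed(seed)
  sch <- feature_schema()
  if (is.null(age)) age <- runif(n, 60, 90)
  tab <- tibble::tibble(subject_id = sprintf("T%03d", seq_len(n)), age = age)
  for (f in sch$feature) tab[[f]] <- rnorm(n)
  tab
}

# --- oracles ---------------------------------------------------------------

oracle_autocorr <- function(x, max_lag) {
  x <- x - mean(x)
  n <- length(x)
  a <- numeric(max_lag + 1)
  for (m in 0:max_lag) {
    s <- 0
    for (i in seq_len(n - m)) s <- s + x[i] * x[i + m]
    a[m + 1] <- s / (n - m)
  }
  a / a[1]
}

oracle_apen <- function(x, m, r) {
  phi <- function(mm) {
    n <- length(x)
    nv <- n - mm + 1
    cnt <- integer(nv)
    for (i in seq_len(nv)) {
      c_i <- 0L
      for (j in seq_len(nv)) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) c_i <- c_i + 1L
      }
      cnt[i] <- c_i
    }
    mean(log(cnt / nv))
  }
  phi(m) - phi(m + 1)
}

# harmonic amplitudes by direct correlation against complex exponentials,
# independent of fft()
oracle_harmonic_ratio <- function(x, stride_time_s, fs, axis, n_harmonics = 20) {
  win <- round(10 * stride_time_s * fs)
  n_win <- floor(length(x) / win)
  tt <- (seq_len(win) - 1) / fs
  f_str <- 1 / stride_time_s
  ratios <- vapply(seq_len(n_win), function(w) {
    seg <- x[((w - 1) * win + 1):(w * win)]
    seg <- seg - mean(seg)
    amp <- vapply(seq_len(n_harmonics), function(k) {
      Mod(sum(seg * exp(-2i * pi * k * f_str * tt)))
    }, numeric(1))
    even <- sum(amp[seq(2, n_harmonics, 2)])
    odd <- sum(amp[seq(1, n_harmonics, 2)])
    if (axis == "ml") odd / even else even / odd
  }, numeric(1))
  mean(ratios)
}

oracle_detect_events <- function(x, threshold, min_event_s, merge_gap_s, fs) {
  above <- which(x > threshold)
  if (length(above) == 0) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  runs <- split(above, cumsum(c(1, diff(above) != 1)))
  iv <- do.call(rbind, lapply(runs, function(r) c(min(r), max(r))))
  # merge
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) {
    for (k in 2:nrow(iv)) {
      gap <- (iv[k, 1] - merged[nrow(merged), 2] - 1) / fs
      if (gap < merge_gap_s) {
        merged[nrow(merged), 2] <- iv[k, 2]
      } else {
        merged <- rbind(merged, iv[k, ])
      }
    }
  }
  out <- data.frame(start_s = (merged[, 1] - 1) / fs, end_s = (merged[, 2] - 1) / fs)
  out[out$end_s - out$start_s >= min_event_s, , drop = FALSE]
}

oracle_mae_mape <- function(y, yhat) {
  mae <- 0; mape <- 0
  for (i in seq_along(y)) {
    mae <- mae + abs(yhat[i] - y[i])
    mape <- mape + abs(yhat[i] - y[i]) / y[i]
  }
  list(mae = mae / length(y), mape = 100 * mape / length(y))
}
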