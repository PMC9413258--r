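test_that("event detection matches a brute-force threshold scan", {
  fs <- 100
  expect_equal(nrow(detect_events(rep(0, 500), 25, fs = fs)), 0)

  # single rectangular pulse of 1 s
  x <- rep(0, 1000)
  x[301:400] <- 30
  ev <- detect_events(x, 25, fs = fs)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$end_s - ev$start_s, 0.99, tolerance = 1.5 / fs)

  # two pulses closer than the merge gap collapse into one
  y <- rep(0, 1000)
  y[101:200] <- 30
  y[216:300] <- 30  # 0.15 s gap < 0.3 s
  expect_equal(nrow(detect_events(y, 25, min_event_s = 0.3,
                                  merge_gap_s = 0.3, fs = fs)), 1)
  expect_equal(nrow(detect_events(y, 25, min_event_s = 0.3,
                                  merge_gap_s = 0.1, fs = fs)), 2)

  set.seed(21)
  for (k in 1:10) {
    z <- abs(rnorm(600, sd = 20))
    got <- as.data.frame(detect_events(z, 25, 0.05, 0.1, fs))
    want <- oracle_detect_events(z, 25, 0.05, 0.1, fs)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("noise-free synthetic trials are segmented within 0.1 s of truth", {
  set.seed(31)
  for (k in 1:5) {
    age <- runif(1, 60, 90)
    p <- default_age_coupling(age)
    p$noise_sd <- 0
    p <- do.call(gait_params, unclass(p))
    out <- simulate_tug_trial(p, seed = 1000 + k)
    seg <- segment_tug(out$recording)
    expect_equal(nrow(seg), 6)
    expect_equal(seg$subtask, out$truth$segmentation$subtask)
    err <- max(abs(c(seg$start_s - out$truth$segmentation$start_s,
                     seg$end_s - out$truth$segmentation$end_s)))
    expect_lt(err, 0.1)
  }
})

test_that("atypical trials raise a segmentation error with counts", {
  out <- simulate_tug_trial(fast_params(), seed = 77)
  rec <- out$recording
  # erase the second turn pulse
  mid <- out$truth$segmentation
  kill <- rec$time_s > mid$start_s[5] - 1
  rec$yaw[kill] <- 0
  expect_error(segment_tug(rec), "1 turn event", class = "gaitage_error_segmentation")
})

test_that("segmentation ignores sub-threshold noise outside events", {
  out <- simulate_tug_trial(fast_params(), seed = 55)
  rec <- out$recording
  seg0 <- segment_tug(rec)
  set.seed(99)
  noisy <- rec
  noisy$pitch <- noisy$pitch + runif(nrow(rec), -10, 10)
  noisy$yaw <- noisy$yaw + runif(nrow(rec), -10, 10)
  seg1 <- segment_tug(noisy)
  expect_lt(max(abs(seg1$start_s - seg0$start_s)), 0.1)
  expect_lt(max(abs(seg1$end_s - seg0$end_s)), 0.1)
})

test_that("timing features are interval arithmetic", {
  seg <- structure(tibble::tibble(
    subtask = c("sit_to_stand", "forward_gait", "mid_turn",
                "backward_gait", "end_turn", "stand_to_sit"),
    start_s = c(1, 2.5, 6.5, 8.5, 14.5, 17),
    end_s = c(2.5, 6.5, 8.5, 14.5, 16.5, 18.5)),
    class = c("tug_segmentation", class(tibble::tibble())))
  tf <- tug_time_features(seg)
  expect_equal(unname(tf["tug.time.gait"]), 5)  # mean of 4 s and 6 s
  expect_equal(unname(tf["tug.time.total"]), 17.5)
  expect_equal(unname(tf["tug.time.mid_turn"]), 2)

  out <- simulate_tug_trial(fast_params(), seed = 8)
  got <- tug_time_features(segment_tug(out$recording))
  want <- tug_time_features(
    structure(out$truth$segmentation,
              class = c("tug_segmentation", class(tibble::tibble()))))
  expect_lt(max(abs(got - want)), 0.2)
})
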