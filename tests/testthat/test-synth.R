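test_that("generators are deterministic in the seed and sensitive to it", {
  p <- gait_params(noise_sd = 0.1)
  a <- simulate_6mwt(p, duration_s = 30, seed = 4)$recording
  b <- simulate_6mwt(p, duration_s = 30, seed = 4)$recording
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- simulate_6mwt(p, duration_s = 30, seed = 5)$recording
  expect_false(isTRUE(all.equal(a$acc_vt, c_$acc_vt)))

  t1 <- simulate_tug_trial(p, seed = 4)$recording
  t2 <- simulate_tug_trial(p, seed = 4)$recording
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("walk ground truth counts steps as duration over step time", {
  p <- gait_params(step_time = 0.5, noise_sd = 0)
  out <- simulate_6mwt(p, duration_s = 360)
  expect_equal(out$truth$step_count, 720)
  expect_equal(out$truth$step_times, 0.5 * (1:720))
  expect_error(simulate_6mwt(p, duration_s = 4), class = "gaitage_error_parameter")
})

test_that("gait parameters reject sub-threshold pulse peaks", {
  expect_error(gait_params(turn_peak_yaw = 31), class = "gaitage_error_parameter")
  expect_error(gait_params(chair_peak_pitch = 24), class = "gaitage_error_parameter")
  expect_error(gait_params(step_time = 0), class = "gaitage_error_parameter")
  expect_error(gait_params(asymmetry = 1), class = "gaitage_error_parameter")
})

test_that("TUG trials carry six ordered ground-truth intervals", {
  out <- simulate_tug_trial(fast_params(), seed = 3)
  seg <- out$truth$segmentation
  expect_equal(nrow(seg), 6)
  expect_equal(seg$subtask,
               c("sit_to_stand", "forward_gait", "mid_turn",
                 "backward_gait", "end_turn", "stand_to_sit"))
  expect_true(all(seg$end_s > seg$start_s))
  expect_true(all(diff(seg$start_s) > 0))
  expect_true(all(seg$start_s[-1] >= seg$end_s[-6]))  # non-overlapping

  # pitch/yaw pulses exceed their thresholds twice each
  rec <- out$recording
  ev_p <- detect_events(rectify(rec$pitch), 25, fs = 100)
  ev_y <- detect_events(rectify(rec$yaw), 32, fs = 100)
  expect_equal(nrow(ev_p), 2)
  expect_equal(nrow(ev_y), 2)
})

test_that("cohort census matches the specification exactly", {
  spec <- small_cohort_spec(12)
  co <- simulate_cohort(spec, seed = 8, duration_6mwt = 20)
  expect_equal(nrow(co$meta), 12)
  expect_equal(sum(co$recordings$test == "TUG"), 36)
  expect_equal(sum(co$recordings$test == "SIXMWT"), 12)
  expect_equal(as.integer(table(co$meta$sex)[c("F", "M")]), c(9L, 3L))
  decade <- cut(co$meta$age, c(60, 70, 80, 90), right = FALSE)
  expect_equal(as.integer(table(decade)), c(4L, 4L, 4L))

  co2 <- simulate_cohort(spec, seed = 8, duration_6mwt = 20)
  expect_identical(co$meta, co2$meta)
  co3 <- simulate_cohort(spec, seed = 9, duration_6mwt = 20)
  expect_false(isTRUE(all.equal(co$meta$age, co3$meta$age)))
  expect_equal(nrow(co3$meta), 12)

  expect_error(cohort_spec(n_subjects = 10,
                           age_group_counts = c(`60s` = 5, `70s` = 4, `80s` = 2),
                           sex_counts = c(M = 5, F = 5)),
               class = "gaitage_error_parameter")
})

test_that("asymmetry suppresses step regularity, roughness suppresses HR", {
  sr_vals <- vapply(c(0, 0.15, 0.3), function(b) {
    quick_walk_features(fast_params(asymmetry = b))[["6mwt.sr.acc_vt"]]
  }, numeric(1))
  expect_true(all(diff(sr_vals) < 0))

  hr_vals <- vapply(c(0.05, 0.15, 0.3), function(g) {
    quick_walk_features(fast_params(smoothness = g))[["6mwt.hr.acc_vt"]]
  }, numeric(1))
  expect_true(all(diff(hr_vals) < 0))
})

test_that("age coupling with zero subject noise gives monotone gait speed", {
  spec <- cohort_spec(n_subjects = 10, ages = seq(61, 88, 3),
                      age_group_counts = c(`60s` = 4, `70s` = 3, `80s` = 3),
                      sex_counts = c(M = 5, F = 5), height_sd = 0,
                      height_mean = c(M = 158, F = 158))
  co <- simulate_cohort(spec, coupling = default_age_coupling, seed = 2,
                        duration_6mwt = 120, subject_sd = 0)
  tab <- extract_cohort_features(co)
  ord <- order(tab$age)
  speed <- tab[["6mwt.gp.average_gait_speed"]][ord]
  expect_true(all(diff(speed) < 0))
})
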