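test_that("step detection recovers the generated step train exactly", {
  p <- gait_params(step_time = 0.5, noise_sd = 0)
  out <- simulate_6mwt(p, duration_s = 360)
  prep <- preprocess_recording(out$recording)
  steps <- detect_steps(prep$acc_vt, 100)
  expect_length(steps, 720)
  # interior intervals (the first/last peaks sit on the zero-phase filter's
  # edge transient)
  interior <- diff(steps)[2:(length(steps) - 2)]
  expect_lt(max(abs(interior - 0.5)), 1 / 100 + 1e-9)

  expect_length(detect_steps(rep(1, 5000), 100), 0)
})

test_that("gait parameters follow their defining arithmetic", {
  steps <- seq(0.5, by = 0.5, length.out = 720)
  gp <- gait_parameters(steps, height_cm = 160, duration_s = 360,
                        k_height = 0.83)
  expect_equal(unname(gp["6mwt.gp.steps_per_s"]), 2)
  expect_equal(unname(gp["6mwt.gp.step_time"]), 0.5)
  expect_equal(unname(gp["6mwt.gp.stride_length"]), 1.328)
  expect_equal(unname(gp["6mwt.gp.gait_distance"]), 478.08)
  expect_equal(unname(gp["6mwt.gp.average_gait_speed"]), 1.328)

  expect_error(gait_parameters(c(1), 160, 360), class = "gaitage_error_gait_parameters")
  expect_error(gait_parameters(steps, 160, 0), class = "gaitage_error_parameter")
})

test_that("unbiased autocorrelation matches the double-loop oracle", {
  set.seed(12)
  for (k in 1:5) {
    x <- rnorm(120)
    got <- unbiased_autocorr(x, 60)
    expect_equal(got, oracle_autocorr(x, 60), tolerance = 1e-9)
    expect_equal(got[1], 1)
  }
  t <- (0:999) / 100
  s <- sin(2 * pi * 2 * t)  # period 0.5 s = lag 50
  a <- unbiased_autocorr(s, 200)
  expect_gt(a[51], 0.99)
  expect_error(unbiased_autocorr(rnorm(10), 10), class = "gaitage_error_lag")
})

test_that("regularity peaks behave as symmetry dictates", {
  t <- (0:5999) / 100
  sym <- sin(2 * pi * 2 * t)  # perfectly symmetric steps at 0.5 s
  a <- unbiased_autocorr(sym, 150)
  r <- regularity(a, 100, step_window_s = c(0.35, 0.65),
                  stride_window_s = c(0.8, 1.2))
  expect_equal(r$sr, r$str, tolerance = 1e-6)
  expect_gt(r$sr, 0.99)

  asym <- sin(2 * pi * 2 * t) + 0.4 * sin(pi * 2 * t)
  a2 <- unbiased_autocorr(asym, 150)
  r2 <- regularity(a2, 100, step_window_s = c(0.35, 0.65),
                   stride_window_s = c(0.8, 1.2))
  expect_lt(r2$sr, r2$str)
  expect_true(abs(r2$sr) <= 1 && abs(r2$str) <= 1)

  # brute-force scan oracle: highest local max in each window
  brute_peak <- function(a, fs, w) {
    best <- -Inf; arg <- NA
    for (i in 2:(length(a) - 1)) {
      lag <- (i - 1) / fs
      if (lag >= w[1] && lag <= w[2] && a[i] > a[i - 1] && a[i] >= a[i + 1] &&
          a[i] > best) {
        best <- a[i]; arg <- lag
      }
    }
    c(best, arg)
  }
  expect_equal(r2$sr, brute_peak(a2, 100, c(0.35, 0.65))[1], tolerance = 1e-12)
  expect_equal(r2$str, brute_peak(a2, 100, c(0.8, 1.2))[1], tolerance = 1e-12)

  expect_error(regularity(a, 100, step_window_s = c(0.01, 0.02)),
               class = "gaitage_error_regularity")
})

test_that("symmetry index is the normalized SR-STR gap", {
  expect_equal(symmetry_index(0.9, 0.9), 0)
  expect_equal(symmetry_index(0.6, 0.8), -0.25)
  expect_equal(symmetry_index(0.8, 0.6), 0.25)
  expect_error(symmetry_index(0, 0), class = "gaitage_error_value")
})

test_that("harmonic ratio obeys its even/odd definition", {
  fs <- 100
  stride <- 1
  t <- (0:11999) / fs

  # pure stride-frequency sinusoid: only odd harmonic content -> HR_vt = 0
  odd_only <- sin(2 * pi * t / stride)
  expect_equal(harmonic_ratio(odd_only, stride, fs, "vt"), 0, tolerance = 1e-6)

  # pure second harmonic: odd sum vanishes -> capped sentinel
  even_only <- sin(2 * pi * 2 * t / stride)
  expect_equal(harmonic_ratio(even_only, stride, fs, "vt", cap = 1e3), 1e3)
  # and on the ml axis the same signal gives HR -> 0
  expect_equal(harmonic_ratio(even_only, stride, fs, "ml"), 0, tolerance = 1e-6)

  # adding even energy to a mixed signal strictly raises HR_vt
  mixed <- function(a) sin(2 * pi * t / stride) + a * sin(2 * pi * 2 * t / stride)
  hrs <- vapply(c(0.2, 0.5, 1), function(a) harmonic_ratio(mixed(a), stride, fs, "vt"),
                numeric(1))
  expect_true(all(diff(hrs) > 0))

  # agreement with a direct-correlation oracle
  set.seed(4)
  x <- mixed(0.7) + 0.1 * rnorm(length(t))
  expect_equal(harmonic_ratio(x, stride, fs, "vt"),
               oracle_harmonic_ratio(x, stride, fs, "vt"), tolerance = 1e-6)
  expect_equal(harmonic_ratio(x, stride, fs, "ml"),
               oracle_harmonic_ratio(x, stride, fs, "ml"), tolerance = 1e-6)

  expect_error(harmonic_ratio(x[1:500], stride, fs, "vt"),
               class = "gaitage_error_harmonic_ratio")
})

test_that("approximate entropy matches Pincus' construction", {
  expect_equal(approximate_entropy(rep(3, 500)), 0)

  set.seed(6)
  x <- rnorm(300)
  r <- 0.2 * sd(x)
  expect_equal(approximate_entropy(x, m_embed = 2, r = r, epoch_s = Inf),
               oracle_apen(x, 2, r), tolerance = 1e-9)

  # periodicity lowers entropy relative to same-variance noise
  t <- (0:599) / 100
  wins <- vapply(1:10, function(s) {
    set.seed(s)
    per <- sin(2 * pi * 2 * t)
    noi <- rnorm(length(t), sd = sd(per))
    approximate_entropy(per, epoch_s = Inf) < approximate_entropy(noi, epoch_s = Inf)
  }, logical(1))
  expect_true(all(wins))

  expect_error(approximate_entropy(rnorm(300), r = -1),
               class = "gaitage_error_parameter")
  expect_error(approximate_entropy(rnorm(50)), class = "gaitage_error_length")
})

test_that("the 6MWT extractor produces the 21 schema features", {
  feats <- quick_walk_features(fast_params(noise_sd = 0.1))
  expect_length(feats, 21)
  expect_identical(names(feats), sixmwt_feature_names())
  expect_false(anyNA(feats))
  expect_true(all(abs(feats[grep("^6mwt\\.(sr|str)\\.", names(feats))]) <= 1))
  expect_true(all(feats[grep("^6mwt\\.apen\\.", names(feats))] >= 0))
})

test_that("a symmetric generator yields near-zero symmetry indices", {
  feats <- quick_walk_features(fast_params(asymmetry = 0, noise_sd = 0))
  si <- feats[grep("^6mwt\\.si\\.", names(feats))]
  expect_true(all(abs(si) < 0.05))
})
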