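test_that("the 70/10/20 split uses largest-remainder sizes deterministically", {
  tab <- random_feature_table(136, seed = 1)
  sp <- split_dataset(tab, seed = 42)
  expect_equal(nrow(sp$train), 95)
  expect_equal(nrow(sp$val), 14)
  expect_equal(nrow(sp$test), 27)

  ids <- c(sp$train$subject_id, sp$val$subject_id, sp$test$subject_id)
  expect_setequal(ids, tab$subject_id)
  expect_equal(anyDuplicated(ids), 0)

  sp2 <- split_dataset(tab, seed = 42)
  expect_identical(sp$test$subject_id, sp2$test$subject_id)
  sp3 <- split_dataset(tab, seed = 43)
  expect_false(identical(sp$test$subject_id, sp3$test$subject_id))

  expect_error(split_dataset(tab, 0.7, 0.2, 0.2), class = "gaitage_error_split_spec")
  expect_error(split_dataset(tab[1:5, ]), class = "gaitage_error_split_spec")

  # other sizes also partition exactly
  for (n in c(10, 57, 101)) {
    sp_n <- split_dataset(random_feature_table(n, seed = n), seed = 1)
    expect_equal(nrow(sp_n$train) + nrow(sp_n$val) + nrow(sp_n$test), n)
  }
})

test_that("MAE and MAPE match hand arithmetic and a loop oracle", {
  e <- regression_errors(c(80, 70), c(75, 72))
  expect_equal(e$mae, 3.5)
  expect_equal(e$mape, 100 * (5 / 80 + 2 / 70) / 2)

  expect_equal(regression_errors(c(70, 80), c(70, 80)), list(mae = 0, mape = 0))

  set.seed(2)
  for (k in 1:5) {
    y <- runif(40, 60, 90)
    yhat <- y + rnorm(40, sd = 4)
    expect_equal(regression_errors(y, yhat), oracle_mae_mape(y, yhat),
                 tolerance = 1e-12)
  }
  expect_error(regression_errors(c(0, 70), c(1, 2)), class = "gaitage_error_value")
  expect_error(regression_errors(1:3, 1:2), class = "gaitage_error_shape")
})

test_that("a strong linear age signal is learned almost perfectly", {
  n <- 60
  age <- seq(60, 90, length.out = n)
  tab <- random_feature_table(n, seed = 5, age = age)
  # plant noiseless signal in two features, one per test
  tab[["6mwt.gp.average_gait_speed"]] <- 1.4 - 0.012 * (age - 60)
  tab[["tug.end_turn.yaw.rms"]] <- 80 - 0.7 * (age - 60)

  fit <- fit_age_model(tab, "AG", seed = 9, n_trials = 10)
  # training MAE below one year on the noiseless planted signal
  sp <- split_dataset(tab, seed = 9)
  tr_err <- evaluate_age_model(fit, sp$train)
  expect_lt(tr_err$mae, 1)

  # planted features dominate the importance ranking
  top <- head(tidy(fit)$feature, 3)
  expect_true("6mwt.gp.average_gait_speed" %in% top ||
                "tug.end_turn.yaw.rms" %in% top)
})

test_that("tuning is deterministic and never worse than the defaults", {
  tab <- random_feature_table(40, seed = 6)
  tab[["6mwt.gp.step_time"]] <- 0.5 + 0.005 * (tab$age - 60) + rnorm(40, sd = 0.01)

  f1 <- fit_age_model(tab, "OS", seed = 4, n_trials = 6)
  f2 <- fit_age_model(tab, "OS", seed = 4, n_trials = 6)
  expect_identical(f1$best_params, f2$best_params)
  expect_equal(f1$mae, f2$mae)

  # the default hyperparameters are part of the searched set
  sp <- split_dataset(tab, seed = 4)
  default_fit <- fit_age_model(tab, "OS", seed = 4, tune_method = "none")
  val_default <- evaluate_age_model(default_fit, sp$val)
  expect_lte(f1$val_mae, val_default$mae + 1e-9)
})

test_that("feature importances are a probability vector over the inputs", {
  tab <- random_feature_table(50, seed = 7)
  tab[["6mwt.gp.average_gait_speed"]] <- 1.4 - 0.012 * (tab$age - 60)
  tab[["6mwt.gp.number_of_steps"]] <- 7  # zero variance
  fit <- fit_age_model(tab, "OS", seed = 2, n_trials = 4)

  fis <- tidy(fit)
  expect_equal(sum(fis$score), 1, tolerance = 1e-6)
  expect_true(all(fis$score >= 0 & fis$score <= 1))
  expect_equal(fis$score[fis$feature == "6mwt.gp.number_of_steps"], 0)
  expect_true("6mwt.gp.average_gait_speed" %in% head(fis$feature, 3))

  expect_error(feature_importance(structure(list(model = NULL), class = "gaitage_fit")),
               class = "gaitage_error_state")
})

test_that("constant labels cannot be fit", {
  tab <- random_feature_table(20, seed = 8, age = rep(70, 20))
  expect_error(fit_age_model(tab, "AG", seed = 1), class = "gaitage_error_training")
})

test_that("feature-set comparison trains OT, OS and AG under one protocol", {
  tab <- random_feature_table(40, seed = 10)
  tab[["6mwt.gp.average_gait_speed"]] <- 1.4 - 0.012 * (tab$age - 60) + rnorm(40, sd = 0.02)
  tab[["tug.mid_turn.yaw.rms"]] <- 80 - 0.7 * (tab$age - 60) + rnorm(40, sd = 2)

  cmp <- compare_feature_sets(tab, seed = 3, n_trials = 4)
  expect_equal(tidy(cmp)$feature_set, c("OT", "OS", "AG"))
  expect_equal(tidy(cmp)$n_features, c(111, 21, 132))
  g <- glance(cmp)
  expect_equal(g$mae_mean, mean(tidy(cmp)$mae))
  expect_equal(g$mae_sd, sd(tidy(cmp)$mae))

  # identical split: each fit holds out the same subjects
  ids <- lapply(cmp$fits, function(f) sort(f$predictions$subject_id))
  expect_identical(ids$OT, ids$OS)
  expect_identical(ids$OT, ids$AG)

  expect_error(compare_feature_sets(tab[c("subject_id", "age",
                                          tug_feature_names())], seed = 1),
               class = "gaitage_error_schema")
})

test_that("tidiers and plots expose the fit", {
  tab <- random_feature_table(30, seed = 12)
  tab[["6mwt.gp.step_time"]] <- 0.5 + 0.005 * (tab$age - 60)
  fit <- fit_age_model(tab, "OS", seed = 5, n_trials = 3)

  expect_s3_class(glance(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1)
  aug <- augment(fit)
  expect_equal(aug$residual, aug$predicted - aug$age)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_feature_importance(fit), "ggplot")

  out <- simulate_tug_trial(fast_params(), seed = 3)
  expect_s3_class(plot_tug_segmentation(out$recording), "ggplot")
})
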