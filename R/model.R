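#' Split a feature table into train/validation/test sets
#'
#' Subject-level random partition with sizes given by largest-remainder
#' rounding of the fractions (so 136 subjects at 0.70/0.10/0.20 give
#' 95/14/27). The partition is deterministic given the seed. The training
#' and validation sets are for model fitting and hyperparameter tuning; the
#' test set must only be touched by the final evaluation — its fingerprint
#' is stored and re-checked there.
#'
#' @param table a feature table (one row per subject).
#' @param train_frac,val_frac,test_frac fractions summing to 1.
#' @param seed integer seed.
#' @return Named list `train`, `val`, `test` of disjoint row subsets, with a
#'   `test_fingerprint` attribute.
#' @export
split_dataset <- function(table, train_frac = 0.70, val_frac = 0.10,
                          test_frac = 0.20, seed = 1) {
  fracs <- c(train_frac, val_frac, test_frac)
  if (abs(sum(fracs) - 1) > 1e-8) {
    stop_gaitage("split fractions must sum to 1", "split_spec")
  }
  n <- nrow(table)
  if (n < 10) stop_gaitage("need at least 10 rows to split", "split_spec")
  sizes <- largest_remainder(n, fracs)
  set.seed(seed)
  perm <- sample.int(n)
  idx <- split(perm, rep(c("train", "val", "test"), sizes))
  out <- list(train = table[sort(idx$train), ],
              val = table[sort(idx$val), ],
              test = table[sort(idx$test), ])
  attr(out, "test_fingerprint") <- fingerprint_rows(out$test)
  out
}

largest_remainder <- function(n, fracs) {
  raw <- n * fracs
  sizes <- floor(raw)
  short <- n - sum(sizes)
  if (short > 0) {
    take <- order(raw - sizes, decreasing = TRUE)[seq_len(short)]
    sizes[take] <- sizes[take] + 1
  }
  as.integer(sizes)
}

fingerprint_rows <- function(df) {
  paste0(paste(df$subject_id, collapse = ","), "|",
         format(sum(df$age), digits = 17))
}

#' Mean absolute error and mean absolute percentage error
#'
#' `MAE = mean(|yhat - y|)` in the units of the label (years here);
#' `MAPE = 100 * mean(|yhat - y| / y)` in percent.
#'
#' @param y true values (none may be zero for MAPE).
#' @param yhat predicted values.
#' @return Named list `mae`, `mape`.
#' @export
regression_errors <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) == 0) {
    stop_gaitage("y and yhat must be non-empty and of equal length", "shape")
  }
  if (any(y == 0)) stop_gaitage("MAPE undefined: zero true value", "value")
  list(mae = mean(abs(yhat - y)), mape = 100 * mean(abs(yhat - y) / y))
}

feature_cols_for_set <- function(table, feature_set) {
  cols <- switch(feature_set,
    OT = tug_feature_names(),
    OS = sixmwt_feature_names(),
    AG = feature_schema()$feature
  )
  present <- intersect(cols, names(table))
  if (length(present) == 0) {
    stop_gaitage(paste0("no ", feature_set, " feature columns in table"), "schema")
  }
  present
}

as_xgb_matrix <- function(df, cols) {
  m <- as.matrix(df[cols])
  storage.mode(m) <- "double"
  m
}

fit_xgb <- function(x, y, params, seed) {
  set.seed(seed)
  xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = params$eta,
                  max_depth = params$max_depth, subsample = params$subsample,
                  colsample_bytree = params$colsample_bytree,
                  lambda = params$lambda, nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
    nrounds = params$nrounds, verbose = 0
  )
}

#' Fit the boosted-tree age regression
#'
#' Splits the table at subject level, tunes the XGBoost hyperparameters by
#' sequential model-based (Bayesian) search minimizing validation MAE — the
#' test rows are never touched during tuning — refits on the training set
#' with the tuned hyperparameters, and evaluates MAE/MAPE on the held-out
#' test set.
#'
#' @param table a feature table with `subject_id`, `age` and feature columns.
#' @param feature_set `"AG"` (all 132), `"OT"` (111 TUG) or `"OS"` (21 6MWT).
#' @param seed integer seed driving the split, the search and the fits.
#' @param n_trials tuning budget (2 disables all but the default + 1 draw).
#' @param tune_method `"bayes"`, `"random"`, or `"none"` for library-default
#'   hyperparameters.
#' @param train_frac,val_frac,test_frac split fractions.
#' @param search_space see [default_search_space()].
#' @return An object of class `gaitage_fit`: the trained model handle,
#'   `mae`/`mape` (years, percent), normalized feature importances, tuned
#'   hyperparameters, per-subject test predictions and split sizes.
#' @export
fit_age_model <- function(table, feature_set = c("AG", "OT", "OS"), seed = 1,
                          n_trials = 50, tune_method = c("bayes", "random", "none"),
                          train_frac = 0.70, val_frac = 0.10, test_frac = 0.20,
                          search_space = default_search_space()) {
  feature_set <- match.arg(feature_set)
  tune_method <- match.arg(tune_method)
  cols <- feature_cols_for_set(table, feature_set)
  if (var(table$age) == 0) {
    stop_gaitage("age label is constant; nothing to learn", "training")
  }

  splits <- split_dataset(table, train_frac, val_frac, test_frac, seed = seed)
  x_tr <- as_xgb_matrix(splits$train, cols)
  y_tr <- splits$train$age
  x_va <- as_xgb_matrix(splits$val, cols)
  y_va <- splits$val$age

  if (tune_method == "none") {
    best <- default_xgb_params()
    val_mae <- NA_real_
  } else {
    objective <- function(p) {
      fit <- fit_xgb(x_tr, y_tr, p, seed = seed)
      regression_errors(y_va, predict(fit, x_va))$mae
    }
    search <- bayes_search(objective, search_space, n_trials = n_trials,
                           seed = seed, method = tune_method)
    best <- search$best_params
    val_mae <- search$best_value
  }

  model <- fit_xgb(x_tr, y_tr, best, seed = seed)

  if (!identical(fingerprint_rows(splits$test), attr(splits, "test_fingerprint"))) {
    stop_gaitage("test set was modified between split and evaluation", "leakage")
  }
  x_te <- as_xgb_matrix(splits$test, cols)
  pred <- predict(model, x_te)
  err <- regression_errors(splits$test$age, pred)

  fit <- structure(list(
    model = model, feature_set = feature_set, features = cols,
    mae = err$mae, mape = err$mape, val_mae = val_mae,
    best_params = best, seed = seed,
    predictions = tibble(subject_id = splits$test$subject_id,
                         age = splits$test$age, predicted = pred),
    n_train = nrow(splits$train), n_val = nrow(splits$val),
    n_test = nrow(splits$test)
  ), class = "gaitage_fit")
  fit$fis <- feature_importance(fit)
  fit
}

#' Evaluate a fitted age model on new data
#'
#' @param fit a `gaitage_fit`.
#' @param newdata a feature table containing the fit's feature columns and
#'   an `age` label.
#' @return Named list `mae`, `mape`.
#' @export
evaluate_age_model <- function(fit, newdata) {
  stopifnot(inherits(fit, "gaitage_fit"))
  if (nrow(newdata) == 0) stop_gaitage("newdata is empty", "value")
  pred <- predict(fit$model, as_xgb_matrix(newdata, fit$features))
  regression_errors(newdata$age, pred)
}

#' Normalized feature importance scores
#'
#' Gain-based importance of every input feature, normalized to sum to 1;
#' features the trees never split on (including zero-variance features)
#' score 0.
#'
#' @param fit a `gaitage_fit`.
#' @return A tibble `feature`, `score` sorted by decreasing score.
#' @export
feature_importance <- function(fit) {
  if (!inherits(fit, "gaitage_fit") || is.null(fit$model)) {
    stop_gaitage("feature importance requires a trained model", "state")
  }
  imp <- xgboost::xgb.importance(model = fit$model)
  scores <- setNames(rep(0, length(fit$features)), fit$features)
  scores[imp$Feature] <- imp$Gain
  total <- sum(scores)
  if (total > 0) scores <- scores / total
  tibble(feature = names(scores), score = unname(scores)) %>%
    arrange(desc(.data$score))
}

#' Compare the OT, OS and AG feature-set models
#'
#' Fits the age regression three times under an identical split and tuning
#' protocol: TUG features only (OT), 6MWT features only (OS) and all 132
#' features (AG).
#'
#' @inheritParams fit_age_model
#' @return An object of class `gaitage_comparison`: the three fits, a
#'   per-set summary tibble and the across-set mean and SD of MAE and MAPE.
#' @export
compare_feature_sets <- function(table, seed = 1, n_trials = 50,
                                 tune_method = c("bayes", "random", "none"),
                                 ...) {
  tune_method <- match.arg(tune_method)
  for (set in c("OT", "OS")) feature_cols_for_set(table, set)  # both groups present?
  sets <- c("OT", "OS", "AG")
  fits <- lapply(sets, function(s) {
    fit_age_model(table, feature_set = s, seed = seed, n_trials = n_trials,
                  tune_method = tune_method, ...)
  })
  names(fits) <- sets
  summary <- tibble(
    feature_set = sets,
    n_features = unname(vapply(fits, function(f) length(f$features), numeric(1))),
    mae = unname(vapply(fits, function(f) f$mae, numeric(1))),
    mape = unname(vapply(fits, function(f) f$mape, numeric(1)))
  )
  structure(list(fits = fits, summary = summary,
                 mae_mean = mean(summary$mae), mae_sd = sd(summary$mae),
                 mape_mean = mean(summary$mape), mape_sd = sd(summary$mape),
                 seed = seed),
            class = "gaitage_comparison")
}

#' @export
print.gaitage_fit <- function(x, ...) {
  cat(sprintf("<gaitage_fit> %s (%d features): test MAE %.2f y, MAPE %.2f%%\n",
              x$feature_set, length(x$features), x$mae, x$mape))
  top <- head(x$fis, 5)
  cat("top features:\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-35s %.3f\n", top$feature[i], top$score[i]))
  }
  invisible(x)
}

#' @export
print.gaitage_comparison <- function(x, ...) {
  cat("<gaitage_comparison>\n")
  print(x$summary)
  cat(sprintf("mean MAE %.2f +/- %.2f y; mean MAPE %.2f +/- %.2f%%\n",
              x$mae_mean, x$mae_sd, x$mape_mean, x$mape_sd))
  invisible(x)
}
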