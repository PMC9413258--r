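#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a fitted age model
#'
#' @param x a `gaitage_fit`.
#' @param ... unused.
#' @return Feature importances as a tibble (`feature`, `score`), sorted.
#' @export
tidy.gaitage_fit <- function(x, ...) x$fis

#' @rdname tidy.gaitage_fit
#' @return For `glance()`: a one-row tibble with the feature set, test
#'   MAE/MAPE and split sizes.
#' @export
glance.gaitage_fit <- function(x, ...) {
  tibble(feature_set = x$feature_set, n_features = length(x$features),
         mae = x$mae, mape = x$mape, val_mae = x$val_mae,
         n_train = x$n_train, n_val = x$n_val, n_test = x$n_test)
}

#' @rdname tidy.gaitage_fit
#' @return For `augment()`: the per-subject test predictions with residuals.
#' @export
augment.gaitage_fit <- function(x, ...) {
  x$predictions %>% mutate(residual = .data$predicted - .data$age)
}

#' Tidy a feature-set comparison
#'
#' @param x a `gaitage_comparison`.
#' @param ... unused.
#' @return The per-set summary tibble (`feature_set`, `n_features`, `mae`,
#'   `mape`).
#' @export
tidy.gaitage_comparison <- function(x, ...) x$summary

#' @rdname tidy.gaitage_comparison
#' @return For `glance()`: one row with the across-set mean and SD of MAE
#'   and MAPE.
#' @export
glance.gaitage_comparison <- function(x, ...) {
  tibble(mae_mean = x$mae_mean, mae_sd = x$mae_sd,
         mape_mean = x$mape_mean, mape_sd = x$mape_sd)
}
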