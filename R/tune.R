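#' Hyperparameter search space for the boosted-tree regressor
#'
#' Learning rate on a log scale in \[0.01, 0.3\], tree depth 2-8, 50-600
#' boosting rounds, row and column subsampling in \[0.5, 1\] and L2
#' regularization in \[0, 10\].
#'
#' @return A named list describing each dimension (`type`, `lo`, `hi`).
#' @export
default_search_space <- function() {
  list(
    eta = list(type = "log", lo = 0.01, hi = 0.3),
    max_depth = list(type = "int", lo = 2, hi = 8),
    nrounds = list(type = "int", lo = 50, hi = 600),
    subsample = list(type = "num", lo = 0.5, hi = 1),
    colsample_bytree = list(type = "num", lo = 0.5, hi = 1),
    lambda = list(type = "num", lo = 0, hi = 10)
  )
}

default_xgb_params <- function() {
  list(eta = 0.3, max_depth = 6, nrounds = 100,
       subsample = 1, colsample_bytree = 1, lambda = 1)
}

decode_unit <- function(u, space) {
  out <- list()
  for (i in seq_along(space)) {
    dim <- space[[i]]
    v <- switch(dim$type,
      log = exp(log(dim$lo) + u[i] * (log(dim$hi) - log(dim$lo))),
      int = as.integer(round(dim$lo + u[i] * (dim$hi - dim$lo))),
      num = dim$lo + u[i] * (dim$hi - dim$lo)
    )
    out[[names(space)[i]]] <- v
  }
  out
}

encode_unit <- function(params, space) {
  vapply(seq_along(space), function(i) {
    dim <- space[[i]]
    v <- params[[names(space)[i]]]
    u <- switch(dim$type,
      log = (log(v) - log(dim$lo)) / (log(dim$hi) - log(dim$lo)),
      (v - dim$lo) / (dim$hi - dim$lo)
    )
    min(max(u, 0), 1)
  }, numeric(1))
}

# Gaussian-process surrogate with squared-exponential kernel on the unit
# hypercube; returns posterior mean and sd at the candidate points.
gp_posterior <- function(X, y, Xc, lengthscale = 0.3, nugget = 1e-6) {
  mu_y <- mean(y)
  sd_y <- sd(y)
  if (sd_y == 0) sd_y <- 1
  ys <- (y - mu_y) / sd_y
  sqdist <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    outer(an, bn, "+") - 2 * tcrossprod(A, B)
  }
  K <- exp(-sqdist(X, X) / (2 * lengthscale^2)) + diag(nugget, nrow(X))
  Ks <- exp(-sqdist(Xc, X) / (2 * lengthscale^2))
  Kinv_y <- solve(K, ys)
  mu <- as.vector(Ks %*% Kinv_y)
  v <- pmax(1 - rowSums((Ks %*% solve(K)) * Ks), 1e-12)
  list(mean = mu * sd_y + mu_y, sd = sqrt(v) * sd_y)
}

expected_improvement <- function(mu, s, best) {
  z <- (best - mu) / s
  s * (z * stats::pnorm(z) + stats::dnorm(z))
}

#' Sequential model-based (Bayesian) hyperparameter search
#'
#' Minimizes `objective` over the search space: an initial Latin-hypercube
#' design (always including the library-default hyperparameters, so the
#' tuned result can never be worse than the default on the tuning
#' objective), then expected-improvement acquisition under a Gaussian
#' process surrogate. `method = "random"` replaces the acquisition loop
#' with pure random search over the same budget.
#'
#' @param objective function taking a named hyperparameter list, returning
#'   the validation loss to minimize.
#' @param space a search space as from [default_search_space()].
#' @param n_trials total evaluation budget (>= 2).
#' @param seed integer seed; the search is deterministic given it.
#' @param method `"bayes"` or `"random"`.
#' @param n_init size of the initial design (bayes only).
#' @return List with `best_params`, `best_value` and a `history` tibble.
#' @export
bayes_search <- function(objective, space = default_search_space(),
                         n_trials = 50, seed = 1,
                         method = c("bayes", "random"), n_init = 10) {
  method <- match.arg(method)
  set.seed(seed)
  d <- length(space)
  n_init <- min(max(2, n_init), n_trials - 1)

  U <- rbind(encode_unit(default_xgb_params(), space),
             lhs::randomLHS(if (method == "bayes") n_init else n_trials - 1, d))
  vals <- numeric(0)
  evals <- list()
  for (i in seq_len(nrow(U))) {
    p <- decode_unit(U[i, ], space)
    vals[i] <- objective(p)
    evals[[i]] <- p
  }

  if (method == "bayes") {
    while (length(vals) < n_trials) {
      cand <- lhs::randomLHS(256, d)
      post <- gp_posterior(U, vals, cand)
      ei <- expected_improvement(post$mean, post$sd, min(vals))
      u_next <- cand[which.max(ei), , drop = TRUE]
      p <- decode_unit(u_next, space)
      U <- rbind(U, u_next)
      vals <- c(vals, objective(p))
      evals[[length(vals)]] <- p
    }
  }

  best <- which.min(vals)
  history <- bind_cols(
    tibble(trial = seq_along(vals), value = vals),
    bind_rows(lapply(evals, as_tibble))
  )
  list(best_params = evals[[best]], best_value = vals[best], history = history)
}
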