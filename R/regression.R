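#' Prediction hyperplanes
#'
#' A fitted prediction function `eta(x) = b + sum_d w(d) * value(d, x)` over
#' a set of descriptor keys: the multi-linear model all fits in this package
#' produce. Weights with `|w| <= 1e-6` are snapped to exactly 0 when fitted
#' by lasso.
#'
#' @param keys a `descriptor_keys` tibble (the descriptor set, ordered).
#' @param weights numeric vector aligned with `keys`.
#' @param intercept scalar intercept `b`.
#' @return An object of class `hyperplane`.
#' @export
hyperplane <- function(keys, weights, intercept) {
  keys <- as_descriptor_keys(keys)
  stopifnot(length(weights) == nrow(keys), length(intercept) == 1L)
  structure(
    list(keys = keys, weights = as.numeric(weights), intercept = as.numeric(intercept)),
    class = "hyperplane"
  )
}

#' @export
print.hyperplane <- function(x, ...) {
  nz <- sum(x$weights != 0)
  cat("<hyperplane> ", nrow(x$keys), " descriptors (", nz, " nonzero), intercept ",
      format(x$intercept, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Support of a hyperplane
#'
#' The descriptor keys with nonzero weight.
#'
#' @param fit a `hyperplane`.
#' @return A `descriptor_keys` tibble.
#' @export
support_keys <- function(fit) {
  stopifnot(inherits(fit, "hyperplane"))
  fit$keys[fit$weights != 0, , drop = FALSE]
}

#' Predict from a hyperplane
#'
#' @param object a `hyperplane`.
#' @param newdata a normalized descriptor table (tibble with the linear
#'   descriptor columns) or a numeric matrix of normalized linear
#'   descriptors.
#' @param params optional `minmax_params`; when given, `newdata` holds raw
#'   values and predictions are returned on the original property scale.
#' @param ... unused.
#' @return Numeric vector of predictions (normalized scale unless `params`
#'   is supplied).
#' @export
predict.hyperplane <- function(object, newdata, params = NULL, ...) {
  X <- descriptor_matrix(newdata, params)
  Z <- evaluate_keys(X, object$keys)
  eta <- drop(object$intercept + Z %*% object$weights)
  if (!is.null(params)) eta <- denormalize_property(eta, params)
  eta
}

descriptor_matrix <- function(newdata, params = NULL) {
  if (is.matrix(newdata)) {
    X <- newdata
  } else if (!is.null(params)) {
    X <- as.matrix(apply_minmax(newdata, params, normalize_property = FALSE)[params$columns])
  } else {
    X <- as.matrix(newdata[vapply(newdata, is.numeric, logical(1))])
  }
  X
}

# Design matrix + response for a normalized table and a key set.
model_inputs <- function(df, keys, property = "property", id = "compound_id") {
  keys <- as_descriptor_keys(keys)
  desc_cols <- descriptor_columns(df, property, id)
  X <- as.matrix(df[desc_cols])
  list(Z = evaluate_keys(X, keys), y = df[[property]], keys = keys)
}

#' Lasso fit over a descriptor set
#'
#' L1-penalized least squares on the evaluated descriptor columns, with the
#' common `1/(2n)` objective scaling (the glmnet/scikit-learn convention):
#' `(1/2n) ||y - b - Z w||^2 + lambda ||w||_1`. Fitted weights with
#' `|w(d)| <= 1e-6` are set to exactly 0. `lambda = 0` falls back to the
#' (minimum-norm) ordinary least-squares fit; a single-column input uses the
#' closed-form soft-threshold solution.
#'
#' @param df a *normalized* descriptor table.
#' @param keys the descriptor set to evaluate (a `descriptor_keys` tibble).
#' @param lambda non-negative penalty.
#' @param property,id column names.
#' @return A `hyperplane` over `keys`.
#' @export
fit_lasso <- function(df, keys, lambda, property = "property", id = "compound_id") {
  if (nrow(df) < 2L) stop("need at least 2 compounds to fit")
  stopifnot(lambda >= 0)
  mi <- model_inputs(df, keys, property, id)
  if (nrow(mi$keys) == 0L) {
    return(hyperplane(mi$keys, numeric(0), mean(mi$y)))
  }
  if (lambda == 0) {
    return(fit_mlr(df, keys, property = property, id = id))
  }
  if (ncol(mi$Z) == 1L) {
    w <- lasso_univariate(mi$Z[, 1], mi$y, lambda)
    b <- mean(mi$y) - w * mean(mi$Z[, 1])
  } else {
    gfit <- glmnet::glmnet(
      mi$Z, mi$y,
      family = "gaussian", alpha = 1, standardize = FALSE,
      lambda = lasso_lambda_path(lambda, mi$Z, mi$y),
      thresh = 1e-9, maxit = 5e5
    )
    cf <- stats::coef(gfit, s = lambda)
    b <- cf[1]
    w <- as.numeric(cf[-1])
  }
  w[abs(w) <= 1e-6] <- 0
  hyperplane(mi$keys, w, b)
}

# A descending geometric path from the data's full-shrinkage penalty down to
# the target: glmnet's coordinate descent warm-starts along the path, which
# is far more reliable than a cold one-point fit at a tiny penalty.
lasso_lambda_path <- function(lambda, Z, y) {
  n <- length(y)
  lambda_top <- max(abs(crossprod(scale(Z, scale = FALSE),
                                  y - mean(y)))) / n
  lambda_top <- max(lambda_top, lambda * 4, 1e-3)
  n_steps <- 30L
  path <- exp(seq(log(lambda_top), log(lambda), length.out = n_steps))
  path[n_steps] <- lambda              # exact endpoint, no float drift
  sort(unique(path), decreasing = TRUE)
}

# minimize (1/2n) sum (y - b - w z)^2 + lambda |w|
lasso_univariate <- function(z, y, lambda) {
  zc <- z - mean(z)
  yc <- y - mean(y)
  v <- mean(zc^2)
  if (v == 0) return(0)
  rho <- mean(zc * yc)
  sign(rho) * max(abs(rho) - lambda, 0) / v
}

#' Lasso support selection (Des-set-LLR)
#'
#' Fits the lasso at penalty `lambda` and returns the surviving descriptor
#' subset — the support `{d : w(d) != 0}` of the fitted hyperplane —
#' together with the hyperplane itself.
#'
#' @inheritParams fit_lasso
#' @return A list with elements `support` (a `descriptor_keys` tibble) and
#'   `fit` (the `hyperplane`).
#' @export
des_set_llr <- function(df, keys, lambda, property = "property", id = "compound_id") {
  fit <- fit_lasso(df, keys, lambda, property = property, id = id)
  list(support = support_keys(fit), fit = fit)
}

#' Multi-linear regression over a descriptor set
#'
#' Ordinary least squares on the evaluated descriptor columns. Rank-deficient
#' systems (frequent after quadratic expansion) are solved by the
#' minimum-norm least-squares solution.
#'
#' @inheritParams fit_lasso
#' @return A `hyperplane` over `keys`.
#' @export
fit_mlr <- function(df, keys, property = "property", id = "compound_id") {
  mi <- model_inputs(df, keys, property, id)
  if (nrow(mi$keys) == 0L) {
    return(hyperplane(mi$keys, numeric(0), mean(mi$y)))
  }
  coef <- ls_coef_cpp(mi$Z, mi$y)
  hyperplane(mi$keys, coef[-1], coef[1])
}

#' Seeded cross-validation fold assignments
#'
#' Uniformly random partitions into `n_folds` near-equal folds, one column
#' per round; round `r` is seeded deterministically from `(seed, r)` so
#' every evaluation of a descriptor subset under the same protocol sees the
#' same splits.
#'
#' @param n number of compounds.
#' @param p number of rounds.
#' @param seed base seed.
#' @param n_folds folds per round (default 5).
#' @return An `n x p` integer matrix of fold labels in `1..n_folds`.
#' @export
cv_folds <- function(n, p, seed, n_folds = 5L) {
  folds <- matrix(0L, n, p)
  base <- rep_len(seq_len(n_folds), n)
  for (r in seq_len(p)) {
    folds[, r] <- withr::with_seed(
      fold_seed(seed, r),
      base[sample.int(n)]
    )
  }
  folds
}

fold_seed <- function(seed, round) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(round)
}

#' Median cross-validated test R^2 of an MLR fit (the g_p score)
#'
#' Runs `p` independent seeded rounds of 5-fold cross-validation: on each
#' training fold an ordinary least-squares model over `keys` is fitted and
#' scored by the coefficient of determination on the held-out fold (test-fold
#' mean in the denominator). Returns the median of the `5 p` test scores.
#'
#' @inheritParams fit_lasso
#' @param p number of cross-validation rounds (default 5).
#' @param seed base seed for the fold assignments.
#' @return The median test R^2 (a scalar `<= 1`).
#' @export
r2_cv_median <- function(df, keys, p = 5L, seed = 1L,
                         property = "property", id = "compound_id") {
  if (nrow(df) < 10L) stop("need at least 10 compounds for 5-fold cross-validation")
  mi <- model_inputs(df, keys, property, id)
  folds <- cv_folds(length(mi$y), p, seed)
  scores <- cv_r2_scores_cpp(mi$Z, mi$y, folds, 5L)
  stats::median(scores[is.finite(scores)])
}

#' Final-model evaluation: 10 rounds of 5-fold cross-validation
#'
#' The reporting protocol for finished models: the median of the 50 test R^2
#' scores from 10 seeded rounds of 5-fold cross-validation, i.e.
#' `r2_cv_median(..., p = 10)`.
#'
#' @inheritParams r2_cv_median
#' @export
final_evaluation <- function(df, keys, seed = 1L,
                             property = "property", id = "compound_id") {
  r2_cv_median(df, keys, p = 10L, seed = seed, property = property, id = id)
}
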