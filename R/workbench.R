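#' Train a quadratic-descriptor prediction model end to end
#'
#' The full reduce-then-regress pipeline: fit min-max normalization on the
#' table; expand the non-degenerate linear descriptors into the quadratic
#' universe (`K1 + (3 K1^2 + K1)/2` candidates); if the universe exceeds
#' `K_tilde` (5000 by default), shrink it with the randomized lasso
#' reduction [llr_reduce()], otherwise use it whole; run the penalty-tuned
#' selection [select_des_set()]; fit the final multi-linear model on the
#' selected set `D*`; and score it with [final_evaluation()] (median test
#' R^2 over 10 rounds of 5-fold cross-validation).
#'
#' @param df a raw descriptor table (one row per compound, count-valued
#'   descriptor columns, a property column, optionally an id column).
#' @param config a [reduction_config()]; its seed drives every random draw.
#' @param property,id column names.
#' @return An object of class `qsar_model`: the fitted `hyperplane`, the
#'   `minmax_params`, the `reduction_result`, and `final_score`.
#' @export
run_train <- function(df, config = reduction_config(),
                      property = "property", id = "compound_id") {
  params <- fit_minmax(df, property = property, id = id)
  norm <- apply_minmax(df, params)
  live <- which(!params$degenerate)
  if (length(live) == 0L) stop("every descriptor column is constant")
  lin <- descriptor_keys(rep("linear", length(live)), i = live)
  universe <- sort_keys(dplyr::bind_rows(lin, expand_quadratic(lin)))
  candidates <- if (nrow(universe) > config$K_tilde) {
    llr_reduce(norm, universe, config, property = property, id = id)
  } else {
    universe
  }
  reduction <- select_des_set(norm, candidates, config,
                              property = property, id = id)
  fit <- fit_mlr(norm, reduction$selected, property = property, id = id)
  final_score <- final_evaluation(norm, reduction$selected, seed = config$seed,
                                  property = property, id = id)
  structure(
    list(fit = fit, params = params, reduction = reduction,
         final_score = final_score, config = config,
         universe_size = nrow(universe),
         llr_reduced = nrow(universe) > config$K_tilde,
         property = property),
    class = "qsar_model"
  )
}

#' @export
print.qsar_model <- function(x, ...) {
  cat("<qsar_model> ", nrow(x$reduction$selected), " descriptors (K1* = ",
      x$reduction$K1_star, ", K2* = ", x$reduction$K2_star,
      "), median CV test R^2 = ", format(x$final_score, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Predict from a trained model on the original scales
#'
#' @param object a `qsar_model`.
#' @param newdata a raw descriptor table.
#' @param ... unused.
#' @return Predicted property values on the original scale.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  predict(object$fit, newdata, params = object$params)
}

#' Infer descriptor vectors attaining a target property range
#'
#' Builds and solves the inverse MILP for a trained model and a target
#' range `[y_lo, y_hi]` on the original property scale, optionally followed
#' by the neighbor grid search.
#'
#' @param model a `qsar_model` from [run_train()].
#' @param y_lo,y_hi target property bounds (original scale).
#' @param box,integral,side_constraints see [inverse_spec()].
#' @param neighbors optional [neighbor_grid_spec()]; when given, the
#'   neighbor search runs around the inferred solution.
#' @param neighbor_table normalized training table used to scale the
#'   neighbor grid (required with `neighbors`).
#' @param p gadget bit-count.
#' @param time_limit_s solver time limit.
#' @return A list report: `status`, the solved quantities of
#'   [solve_inverse()], and (with `neighbors`) the `neighbor_result`.
#' @export
run_infer <- function(model, y_lo, y_hi, box = NULL, integral = integer(0),
                      side_constraints = list(), neighbors = NULL,
                      neighbor_table = NULL, p = 6L, time_limit_s = 300) {
  stopifnot(inherits(model, "qsar_model"))
  spec <- inverse_spec(model$fit, model$params, y_lo, y_hi, box = box,
                       integral = integral, side_constraints = side_constraints,
                       time_limit_s = time_limit_s)
  milp <- build_inverse_milp(spec, p = p)
  sol <- solve_inverse(milp)
  report <- c(list(y_lo = y_lo, y_hi = y_hi), sol)
  if (!is.null(neighbors) && sol$status == "feasible") {
    if (is.null(neighbor_table)) {
      stop("neighbor search needs `neighbor_table` to scale the grid")
    }
    ranges <- theta_ranges(neighbor_table, neighbors, property = model$property)
    report$neighbors <- neighbor_search(spec, sol$x_star, neighbors, ranges, p = p)
  }
  report
}

#' Write / read a trained model as JSON
#'
#' The file records the selected descriptor keys, weights, intercept,
#' normalization parameters, the final CV score and the training seed, so
#' a model can be reloaded for inference without retraining.
#'
#' @param model a `qsar_model`.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "qsar_model"))
  obj <- list(
    keys = as.data.frame(model$fit$keys),
    weights = model$fit$weights,
    intercept = model$fit$intercept,
    normalization = unclass(model$params),
    final_score = model$final_score,
    K1_star = model$reduction$K1_star,
    K2_star = model$reduction$K2_star,
    seed = model$config$seed,
    universe_size = model$universe_size,
    llr_reduced = model$llr_reduced,
    property = model$property
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  keys <- descriptor_keys(obj$keys$form, obj$keys$i, obj$keys$j)
  fit <- hyperplane(keys, obj$weights, obj$intercept)
  params <- obj$normalization
  params$degenerate <- as.logical(params$degenerate)
  params <- structure(params, class = "minmax_params")
  reduction <- new_reduction_result(
    keys, obj$final_score,
    tibble::tibble(stage = "loaded", lambda = NA_real_,
                   size = nrow(keys), score = obj$final_score),
    reduction_config(seed = obj$seed)
  )
  structure(
    list(fit = fit, params = params, reduction = reduction,
         final_score = obj$final_score,
         config = reduction_config(seed = obj$seed),
         universe_size = obj$universe_size,
         llr_reduced = obj$llr_reduced,
         property = obj$property),
    class = "qsar_model"
  )
}
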