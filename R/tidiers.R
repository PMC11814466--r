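#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted hyperplane
#'
#' @param x a `hyperplane`.
#' @param ... unused.
#' @return A tibble with one row per descriptor: `term` (label), `form`,
#'   `i`, `j`, `estimate`.
#' @export
tidy.hyperplane <- function(x, ...) {
  tibble::tibble(
    term = key_labels(x$keys),
    form = x$keys$form,
    i = x$keys$i,
    j = x$keys$j,
    estimate = x$weights
  )
}

#' @rdname tidy.hyperplane
#' @export
glance.hyperplane <- function(x, ...) {
  tibble::tibble(
    n_terms = nrow(x$keys),
    n_nonzero = sum(x$weights != 0),
    n_linear = sum(x$keys$form == "linear" & x$weights != 0),
    n_quadratic = sum(x$keys$form != "linear" & x$weights != 0),
    intercept = x$intercept
  )
}

#' Tidy normalization parameters
#'
#' @param x a `minmax_params`.
#' @param ... unused.
#' @return A tibble with one row per descriptor column plus one for the
#'   property: `column`, `min`, `max`, `degenerate`.
#' @export
tidy.minmax_params <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(column = x$columns, min = x$min, max = x$max,
                   degenerate = x$degenerate, role = "descriptor"),
    tibble::tibble(column = x$property, min = x$property_min,
                   max = x$property_max,
                   degenerate = x$property_min == x$property_max,
                   role = "property")
  )
}

#' Tidy a reduction result
#'
#' @param x a `reduction_result`.
#' @param ... unused.
#' @return `tidy()`: the per-stage score trace (`stage`, `lambda`, `size`,
#'   `score`). `glance()`: one row with the selected-set summary.
#' @export
tidy.reduction_result <- function(x, ...) {
  x$score_trace
}

#' @rdname tidy.reduction_result
#' @export
glance.reduction_result <- function(x, ...) {
  tibble::tibble(
    n_selected = nrow(x$selected),
    K1_star = x$K1_star,
    K2_star = x$K2_star,
    score = x$score
  )
}

#' Tidy a trained model
#'
#' @param x a `qsar_model`.
#' @param ... unused.
#' @return `tidy()`: the fitted terms (see [tidy.hyperplane()]).
#'   `glance()`: one row with the selection summary and the final median
#'   cross-validated test R^2.
#' @export
tidy.qsar_model <- function(x, ...) {
  tidy(x$fit)
}

#' @rdname tidy.qsar_model
#' @export
glance.qsar_model <- function(x, ...) {
  tibble::tibble(
    n_selected = nrow(x$reduction$selected),
    K1_star = x$reduction$K1_star,
    K2_star = x$reduction$K2_star,
    universe_size = x$universe_size,
    llr_reduced = x$llr_reduced,
    final_score = x$final_score
  )
}
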