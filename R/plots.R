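#' Plot the selection score trace
#'
#' One panel per stage: the penalty scan (score of each lasso support
#' against its penalty) and the refinement pass (score of each
#' backward-stepwise candidate).
#'
#' @param object a `reduction_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.reduction_result <- function(object, ...) {
  trace <- object$score_trace
  trace <- trace[is.finite(trace$score), , drop = FALSE]
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$lambda, y = .data$score)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_x_continuous(
      trans = scales_pseudo_log(),
      name = expression(lambda)
    ) +
    ggplot2::facet_wrap(~stage, scales = "free_x") +
    ggplot2::labs(y = "median CV test R²",
                  title = "Descriptor selection score trace") +
    ggplot2::theme_minimal()
}

# pseudo-log keeps lambda = 0 plottable alongside the log-spaced grid
scales_pseudo_log <- function() {
  scales::pseudo_log_trans(sigma = 1e-6, base = 10)
}

#' Plot a neighbor-search grid
#'
#' Tile map of the 48 neighbor cells around the origin, coloured by status.
#'
#' @param object a `neighbor_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.neighbor_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$g1, y = .data$g2,
                                   fill = .data$status)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::annotate("point", x = 0, y = 0, shape = 4, size = 3) +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_manual(values = c(
      solution = "#2c7fb8", infeasible = "#d95f02",
      ignored = "grey80", timeout = "#fdd0a2")) +
    ggplot2::labs(title = "Neighbor-cell feasibility",
                  x = expression(g[1]), y = expression(g[2])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
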