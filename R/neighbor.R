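#' Two-dimensional neighbor-grid specification
#'
#' The neighbor search perturbs a solved inverse problem along two
#' auxiliary prediction functions `theta_1`, `theta_2` (trained hyperplanes
#' over the same descriptor space): the solution `x-dagger` is mapped to
#' the origin of a two-dimensional grid with cell size `delta` (in units of
#' each theta's observed training range), and the feasibility of the 48
#' neighboring cells within radius 3 — `(2*3+1)^2 - 1` offsets — is checked
#' in order of increasing Euclidean distance.
#'
#' @param theta1,theta2 `hyperplane` objects.
#' @param delta grid step as a fraction of each theta's observed range
#'   (0.1 or 0.05 in the reference experiments).
#' @param radius grid radius (default 3, giving 48 neighbors).
#' @param time_limit_s per-neighbor solver time limit (default 300).
#' @return An object of class `neighbor_grid_spec`.
#' @export
neighbor_grid_spec <- function(theta1, theta2, delta = 0.1, radius = 3L,
                               time_limit_s = 300) {
  stopifnot(inherits(theta1, "hyperplane"), inherits(theta2, "hyperplane"),
            delta > 0, radius >= 1)
  structure(
    list(theta = list(theta1, theta2), delta = delta,
         radius = as.integer(radius), time_limit_s = time_limit_s),
    class = "neighbor_grid_spec"
  )
}

#' Grid offsets in increasing distance
#'
#' All offsets `(g1, g2)` in `{-radius..radius}^2` except the origin,
#' ordered by Euclidean distance from the origin with lexicographic
#' tie-breaking.
#'
#' @param radius grid radius.
#' @return A tibble with columns `g1`, `g2`, `distance`, `rank`.
#' @export
neighbor_offsets <- function(radius = 3L) {
  g <- expand.grid(g2 = -radius:radius, g1 = -radius:radius)[, c("g1", "g2")]
  g <- g[!(g$g1 == 0 & g$g2 == 0), , drop = FALSE]
  g$distance <- sqrt(g$g1^2 + g$g2^2)
  g <- g[order(g$distance, g$g1, g$g2), , drop = FALSE]
  g$rank <- seq_len(nrow(g))
  tibble::as_tibble(g)
}

#' Grid search for neighbor solutions of a solved inverse problem
#'
#' For each offset `g` (in increasing distance), the inverse MILP is
#' re-solved with the two cell constraints
#' `theta_k(x) - theta_k(x-dagger) in [(g_k - 1/2) delta R_k,
#' (g_k + 1/2) delta R_k]`, where `R_k` is the observed range of `theta_k`
#' on the training table. A neighbor is *ignored* (not checked) when a
#' strictly closer neighbor on the same ray from the origin — an infeasible
#' `g'` with `g = c g'` for an integer `c >= 2` — has already proved
#' infeasible. Every run accounts for exactly `(2 radius + 1)^2 - 1`
#' offsets as solution / infeasible / ignored / timeout.
#'
#' @param spec the [inverse_spec()] of the solved base problem.
#' @param x_dagger the base solution (normalized descriptor vector).
#' @param grid a [neighbor_grid_spec()].
#' @param theta_ranges numeric length-2 vector `R_k`: the observed range of
#'   each theta on the training table (see [theta_ranges()]).
#' @param p gadget bit-count.
#' @param batch solve all cells in one solver subprocess (default); the
#'   ignore rule is applied afterwards in distance order, which yields the
#'   same statuses as checking sequentially.
#' @return A tibble of class `neighbor_result`: `g1`, `g2`, `distance`,
#'   `rank`, `status` (`"solution"`, `"infeasible"`, `"ignored"`,
#'   `"timeout"`); feasible descriptor vectors are in `attr(, "solutions")`.
#' @export
neighbor_search <- function(spec, x_dagger, grid, theta_ranges,
                            p = 6L, batch = TRUE) {
  stopifnot(inherits(spec, "inverse_spec"), inherits(grid, "neighbor_grid_spec"))
  if (length(grid$theta) != 2L) stop("only p_dim = 2 is supported")
  stopifnot(length(theta_ranges) == 2L, all(theta_ranges > 0))
  offs <- neighbor_offsets(grid$radius)
  centers <- vapply(grid$theta, function(th)
    unname(predict(th, matrix(x_dagger, nrow = 1))), numeric(1))

  cell_milp <- function(g1, g2) {
    er <- purrr::map(1:2, function(k) {
      gk <- if (k == 1) g1 else g2
      step <- grid$delta * theta_ranges[k]
      list(hyperplane = grid$theta[[k]],
           lb = centers[k] + (gk - 0.5) * step,
           ub = centers[k] + (gk + 0.5) * step)
    })
    build_inverse_milp(spec, p = p, extra_ranges = er)
  }

  milps <- purrr::map2(offs$g1, offs$g2, cell_milp)
  if (batch) {
    answers <- solve_milp_batch(milps, time_limit_s = grid$time_limit_s)
  } else {
    answers <- purrr::map(milps, solve_milp, time_limit_s = grid$time_limit_s)
  }

  status <- character(nrow(offs))
  solutions <- vector("list", nrow(offs))
  infeasible <- list()
  for (k in seq_len(nrow(offs))) {
    g <- c(offs$g1[k], offs$g2[k])
    ignored <- any(vapply(infeasible, function(gp) on_same_ray(g, gp), logical(1)))
    if (ignored) {
      status[k] <- "ignored"
      next
    }
    st <- answers[[k]]$status
    if (st == "feasible") {
      status[k] <- "solution"
      map <- attr(milps[[k]], "map")
      solutions[[k]] <- answers[[k]]$x[map$x_cols]
    } else if (st == "infeasible") {
      status[k] <- "infeasible"
      infeasible[[length(infeasible) + 1L]] <- g
    } else {
      status[k] <- "timeout"
    }
  }
  out <- dplyr::mutate(offs, status = status)
  class(out) <- c("neighbor_result", class(out))
  attr(out, "solutions") <- solutions
  attr(out, "delta") <- grid$delta
  out
}

# g lies farther out on the ray through g_prime: g = c * g_prime, integer c >= 2
on_same_ray <- function(g, g_prime) {
  for (c_mul in 2:6) {
    if (all(g == c_mul * g_prime)) return(TRUE)
  }
  FALSE
}

#' Status counts of a neighbor search
#'
#' @param object a `neighbor_result`.
#' @param ... unused.
#' @return A one-row tibble with `n_solution`, `n_infeasible`, `n_ignored`,
#'   `n_timeout`, `n_total`.
#' @export
summary.neighbor_result <- function(object, ...) {
  tibble::tibble(
    n_solution = sum(object$status == "solution"),
    n_infeasible = sum(object$status == "infeasible"),
    n_ignored = sum(object$status == "ignored"),
    n_timeout = sum(object$status == "timeout"),
    n_total = nrow(object)
  )
}

#' Observed ranges of the neighbor-grid prediction functions
#'
#' `R_k`: the spread of each theta's predictions over the (normalized)
#' training table, used to convert grid steps into constraint widths.
#'
#' @param df a normalized descriptor table.
#' @param grid a [neighbor_grid_spec()].
#' @param property,id column names.
#' @return Numeric length-2 vector.
#' @export
theta_ranges <- function(df, grid, property = "property", id = "compound_id") {
  desc_cols <- descriptor_columns(df, property, id)
  X <- as.matrix(df[desc_cols])
  vapply(grid$theta, function(th) {
    pr <- predict(th, X)
    max(pr) - min(pr)
  }, numeric(1))
}
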