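#' Configuration for the descriptor-reduction pipeline
#'
#' Defaults follow the reduction protocol: compound-subsample cap
#' `c_max = 200` and descriptor-partition cap `d_max = 200` for the
#' randomized lasso reduction, target size `K_tilde = 5000`, a fixed grid
#' `A` of 17 penalty values, 16 refinement penalties around the best one,
#' `p1 = p2 = p3 = 5` cross-validation rounds for scoring, and the
#' backward-stepwise size cap `s_max = floor(150 + 1e4 / (n + 200))` as a
#' function of the number of compounds `n`.
#'
#' @param c_max compound-subsample cap inside [llr_reduce()].
#' @param d_max descriptor-partition cap inside [llr_reduce()].
#' @param K_tilde target descriptor count of [llr_reduce()].
#' @param lambda_grid the penalty grid `A` (17 values by default).
#' @param B_size number of refinement penalties around the best grid value.
#' @param p1,p2,p3 cross-validation rounds for the penalty scan, the
#'   backward-stepwise scoring, and the final candidate scoring.
#' @param llr_lambda the fixed penalty used by the lasso calls inside
#'   [llr_reduce()] (default: the smallest positive grid value).
#' @param seed base seed for every random draw in the pipeline.
#' @return A list of class `reduction_config`.
#' @export
reduction_config <- function(c_max = 200L, d_max = 200L, K_tilde = 5000L,
                             lambda_grid = c(0, 1e-6, 1e-5, 1e-4, 1e-3, 0.01,
                                             0.05, 0.1, 0.5, 0.75, 1, 2, 5,
                                             10, 25, 50, 100),
                             B_size = 16L, p1 = 5L, p2 = 5L, p3 = 5L,
                             llr_lambda = NULL, seed = 1L) {
  stopifnot(c_max > 0, d_max > 0, K_tilde > 0, B_size > 0,
            p1 >= 1, p2 >= 1, p3 >= 1, all(lambda_grid >= 0))
  if (is.null(llr_lambda)) {
    pos <- lambda_grid[lambda_grid > 0]
    llr_lambda <- if (length(pos)) min(pos) else 1e-6
  }
  structure(
    list(c_max = as.integer(c_max), d_max = as.integer(d_max),
         K_tilde = as.integer(K_tilde), lambda_grid = lambda_grid,
         B_size = as.integer(B_size), p1 = as.integer(p1),
         p2 = as.integer(p2), p3 = as.integer(p3),
         llr_lambda = llr_lambda, seed = as.integer(seed)),
    class = "reduction_config"
  )
}

#' Backward-stepwise size cap
#'
#' `s_max = floor(150 + 1e4 / (n + 200))` for `n` compounds.
#'
#' @param n number of compounds.
#' @export
s_max_cap <- function(n) {
  as.integer(floor(150 + 1e4 / (n + 200)))
}

#' Randomized lasso descriptor reduction (LLR-Reduce)
#'
#' Shrinks a descriptor set to `K_tilde` members by repeated randomized
#' lasso passes: while the set is larger than `K_tilde`, partition it into
#' random blocks of at most `d_max` keys, fit a lasso on a random subset of
#' at most `c_max` compounds per block, and keep the union of the supports.
#' If the final pass undershoots, the set is padded back to `K_tilde` from
#' the previous iterate using a K-best filter (largest absolute Pearson
#' correlation of the descriptor column with the property on the full
#' table).
#'
#' @param df a *normalized* descriptor table.
#' @param keys candidate `descriptor_keys`.
#' @param config a [reduction_config()].
#' @param property,id column names.
#' @return A `descriptor_keys` tibble of size `min(K_tilde, nrow(keys))`.
#' @export
llr_reduce <- function(df, keys, config = reduction_config(),
                       property = "property", id = "compound_id") {
  keys <- as_descriptor_keys(keys)
  K_tilde <- config$K_tilde
  if (nrow(keys) <= K_tilde) return(keys)
  withr::with_seed(config$seed, {
    current <- keys
    repeat {
      if (nrow(current) <= K_tilde) break
      previous <- current
      n_blocks <- ceiling(nrow(current) / config$d_max)
      block <- sample(rep_len(seq_len(n_blocks), nrow(current)))
      survivors <- vector("list", n_blocks)
      for (bi in seq_len(n_blocks)) {
        block_keys <- current[block == bi, , drop = FALSE]
        rows <- sample.int(nrow(df), min(config$c_max, nrow(df)))
        survivors[[bi]] <- des_set_llr(df[rows, , drop = FALSE], block_keys,
                                       lambda = config$llr_lambda,
                                       property = property, id = id)$support
      }
      current <- sort_keys(dplyr::bind_rows(survivors))
      if (nrow(current) >= nrow(previous)) {
        warning("llr_reduce: no shrinkage in a full pass; truncating by K-best")
        current <- k_best_keys(df, previous, K_tilde, property = property, id = id)
        break
      }
      if (nrow(current) < K_tilde) {
        pad <- k_best_keys(df, keys_setdiff(previous, current),
                           K_tilde - nrow(current), property = property, id = id)
        current <- sort_keys(dplyr::bind_rows(current, pad))
        break
      }
    }
    current
  })
}

# Top-m keys by |Pearson correlation| of the evaluated column with the
# property on the full table; deterministic tie-break by canonical order.
k_best_keys <- function(df, keys, m, property = "property", id = "compound_id") {
  keys <- sort_keys(keys)
  m <- min(m, nrow(keys))
  if (m <= 0L) return(keys[0, , drop = FALSE])
  mi <- model_inputs(df, keys, property, id)
  sds <- apply(mi$Z, 2, stats::sd)
  cors <- rep(0, ncol(mi$Z))
  ok <- sds > 0 & stats::sd(mi$y) > 0
  if (any(ok)) cors[ok] <- abs(stats::cor(mi$Z[, ok, drop = FALSE], mi$y))
  keys[order(-cors, seq_len(nrow(keys)))[seq_len(m)], , drop = FALSE]
}

#' Backward-stepwise descriptor elimination (BS-Reduce)
#'
#' Starting from the full set, repeatedly removes the single descriptor
#' whose removal maximizes the cross-validated score `g_p` (the median test
#' R^2 of an MLR over `p` seeded rounds of 5-fold cross-validation), and
#' returns the best-scoring set observed anywhere along the elimination
#' path. Every `g_p` evaluation uses the same seeded folds, so scores of
#' different subsets are comparable; ties break on the first candidate in
#' canonical order.
#'
#' @inheritParams llr_reduce
#' @param p cross-validation rounds for `g_p`.
#' @param seed fold seed for `g_p`.
#' @param cache optional environment memoising `g_p` values across calls.
#' @return A `descriptor_keys` tibble with attributes `score` (its `g_p`)
#'   and `trace` (a tibble of the elimination path).
#' @export
bs_reduce <- function(df, keys, p = 5L, seed = 1L,
                      property = "property", id = "compound_id",
                      cache = NULL) {
  keys <- sort_keys(keys)
  stopifnot(nrow(keys) >= 1L)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  labels <- key_labels(keys)
  memo_id <- paste0("BS", p, ":", paste(labels, collapse = ";"))
  hit <- cache[[memo_id]]
  if (!is.null(hit)) return(hit)

  mi <- model_inputs(df, keys, property, id)
  folds <- cv_folds(length(mi$y), p, seed)
  # the compiled kernel walks the whole elimination path, maintaining each
  # fold's inverse Gram matrix across removals
  path <- bs_path_cpp(mi$Z, mi$y, folds, 5L)

  l_best <- path$full_score
  best <- seq_len(nrow(keys))
  active <- seq_len(nrow(keys))
  trace <- list(tibble::tibble(size = nrow(keys), score = l_best,
                               removed = NA_character_))
  for (step in seq_along(path$order)) {
    removed <- path$order[step]
    active <- setdiff(active, removed)
    trace[[step + 1L]] <- tibble::tibble(
      size = length(active), score = path$chosen_scores[step],
      removed = labels[removed])
    if (path$chosen_scores[step] > l_best) {
      l_best <- path$chosen_scores[step]
      best <- active
    }
  }
  out <- keys[best, , drop = FALSE]
  attr(out, "score") <- l_best
  attr(out, "trace") <- dplyr::bind_rows(trace)
  cache[[memo_id]] <- out
  out
}

# Refinement grid B(lambda) around the best penalty: 16 values geometrically
# spaced in [lambda/4, 4*lambda]; around 0, linearly spaced in [0, smallest
# positive grid value].
refine_lambda_grid <- function(lambda_best, lambda_grid, size = 16L) {
  if (lambda_best <= 0) {
    pos <- lambda_grid[lambda_grid > 0]
    hi <- if (length(pos)) min(pos) else 1e-6
    return(seq(0, hi, length.out = size))
  }
  exp(seq(log(lambda_best / 4), log(4 * lambda_best), length.out = size))
}

#' Penalty-tuned descriptor selection (Select-Des-set)
#'
#' The full selection procedure over a candidate descriptor set: (1) for
#' each penalty in the grid `A`, compute the lasso support and score it with
#' `g_p1`; (2) take the best-scoring penalty; (3) for each of the 16
#' refinement penalties around it, recompute the support, cap it at `s_max`
#' keys by largest `|w(d)|` if needed, run [bs_reduce()] with `p2` rounds,
#' and score the result with `g_p3`; (4) return the best-scoring candidate
#' with its linear/quadratic split `(K1*, K2*)`.
#'
#' @inheritParams llr_reduce
#' @return An object of class `reduction_result`: `selected` keys,
#'   `K1_star`, `K2_star`, the winning score, and a `score_trace` tibble of
#'   every stage. `tidy()` returns the trace, `glance()` the summary row.
#' @export
select_des_set <- function(df, keys, config = reduction_config(),
                           property = "property", id = "compound_id") {
  keys <- sort_keys(keys)
  stopifnot(nrow(keys) >= 1L)
  cache <- new.env(parent = emptyenv())
  smax <- s_max_cap(nrow(df))

  scan <- purrr::map(config$lambda_grid, function(lam) {
    sel <- des_set_llr(df, keys, lambda = lam, property = property, id = id)
    score <- if (nrow(sel$support) == 0L) -Inf else
      r2_cv_median(df, sel$support, p = config$p1, seed = config$seed,
                   property = property, id = id)
    list(lambda = lam, support = sel$support, score = score)
  })
  scan_trace <- tibble::tibble(
    stage = "lambda_scan",
    lambda = vapply(scan, `[[`, numeric(1), "lambda"),
    size = vapply(scan, function(s) nrow(s$support), integer(1)),
    score = vapply(scan, `[[`, numeric(1), "score")
  )
  if (all(!is.finite(scan_trace$score))) {
    warning("select_des_set: every lasso support is empty")
    return(new_reduction_result(keys[0, , drop = FALSE], -Inf, scan_trace, config))
  }
  lambda_best <- scan_trace$lambda[which.max(scan_trace$score)]

  refine <- purrr::map(
    refine_lambda_grid(lambda_best, config$lambda_grid, config$B_size),
    function(lam) {
      sel <- des_set_llr(df, keys, lambda = lam, property = property, id = id)
      supp <- sel$support
      if (nrow(supp) == 0L) {
        return(list(lambda = lam, size = 0L, keys = supp, score = -Inf))
      }
      if (nrow(supp) > smax) {
        w <- sel$fit$weights[sel$fit$weights != 0]
        supp <- supp[order(-abs(w), seq_along(w))[seq_len(smax)], , drop = FALSE]
      }
      reduced <- bs_reduce(df, supp, p = config$p2, seed = config$seed,
                           property = property, id = id, cache = cache)
      score <- r2_cv_median(df, reduced, p = config$p3, seed = config$seed,
                            property = property, id = id)
      list(lambda = lam, size = nrow(reduced), keys = reduced, score = score)
    })
  refine_trace <- tibble::tibble(
    stage = "refine",
    lambda = vapply(refine, `[[`, numeric(1), "lambda"),
    size = vapply(refine, `[[`, integer(1), "size"),
    score = vapply(refine, `[[`, numeric(1), "score")
  )
  trace <- dplyr::bind_rows(scan_trace, refine_trace)
  if (all(!is.finite(refine_trace$score))) {
    warning("select_des_set: every refined support is empty")
    return(new_reduction_result(keys[0, , drop = FALSE], -Inf, trace, config))
  }
  winner <- refine[[which.max(refine_trace$score)]]
  new_reduction_result(winner$keys, winner$score, trace, config)
}

new_reduction_result <- function(selected, score, trace, config) {
  selected <- as_descriptor_keys(tibble::as_tibble(selected))
  structure(
    list(
      selected = selected,
      K1_star = sum(selected$form == "linear"),
      K2_star = sum(selected$form != "linear"),
      score = score,
      score_trace = trace,
      config = config
    ),
    class = "reduction_result"
  )
}

#' @export
print.reduction_result <- function(x, ...) {
  cat("<reduction_result> ", nrow(x$selected), " descriptors selected (K1* = ",
      x$K1_star, ", K2* = ", x$K2_star, "), score = ",
      format(x$score, digits = 4), "\n", sep = "")
  invisible(x)
}
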