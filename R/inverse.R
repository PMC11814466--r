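#' Specify a feature-space inverse problem
#'
#' Bundles a trained prediction hyperplane with its normalization
#' parameters, a target property range on the original scale, and the
#' admissible descriptor region: per-descriptor box bounds (raw scale),
#' descriptors required to take integer raw values, and optional linear
#' side constraints over the normalized linear descriptors. Solving the
#' resulting mixed-integer program yields a normalized descriptor vector
#' `x*` whose predicted property lies in the target range; reconstructing a
#' molecule from `x*` is outside this package's scope.
#'
#' @param model a `hyperplane` over linear/quadratic descriptor keys.
#' @param params the `minmax_params` the model was trained with.
#' @param y_lo,y_hi target property bounds on the original scale.
#' @param box optional tibble with columns `i`, `lo`, `hi`: raw-scale bounds
#'   per linear descriptor (defaults to the training range, i.e. the full
#'   normalized unit box).
#' @param integral integer vector of linear-descriptor indices whose raw
#'   value must be an integer (count-valued descriptors).
#' @param side_constraints list of `list(coefs =, lb =, ub =)` rows, each a
#'   linear constraint over the `K1` normalized descriptors.
#' @param time_limit_s solver time limit, seconds (default 300).
#' @return An object of class `inverse_spec`.
#' @export
inverse_spec <- function(model, params, y_lo, y_hi, box = NULL,
                         integral = integer(0), side_constraints = list(),
                         time_limit_s = 300) {
  stopifnot(inherits(model, "hyperplane"), inherits(params, "minmax_params"))
  if (y_lo > y_hi) stop("empty target range: y_lo > y_hi")
  structure(
    list(model = model, params = params, y_lo = y_lo, y_hi = y_hi,
         box = box, integral = as.integer(integral),
         side_constraints = side_constraints, time_limit_s = time_limit_s),
    class = "inverse_spec"
  )
}

#' Build the inverse-inference MILP
#'
#' Emits one variable per normalized linear descriptor (`x in [0,1]^K1`,
#' linked to an integer raw variable when the descriptor is count-valued),
#' one product gadget (see [emit_product_gadget()]) per quadratic key in
#' the model support — `m` quadratic keys contribute exactly `m (p+1)`
#' binaries — and the prediction row
#' `y_lo' <= b + sum w(d) v_d <= y_hi'` on the normalized property scale,
#' where `v_d` is the descriptor variable for linear keys and the gadget
#' output for quadratic keys. The objective is constant (pure feasibility)
#' unless a `reference` vector is given, in which case the L1 distance to
#' it is minimized.
#'
#' @param spec an [inverse_spec()].
#' @param p gadget bit-count (default 6).
#' @param reference optional normalized descriptor vector to stay close to.
#' @param extra_ranges optional list of `list(hyperplane =, lb =, ub =)`
#'   rows: additional prediction functions constrained to a range on the
#'   normalized scale (used by [neighbor_search()]); their quadratic keys
#'   receive gadgets too, shared with the model's where they coincide.
#' @return A `milp_model` carrying the variable map needed by
#'   [solve_inverse()] as attributes.
#' @export
build_inverse_milp <- function(spec, p = 6L, reference = NULL,
                               extra_ranges = list()) {
  stopifnot(inherits(spec, "inverse_spec"))
  params <- spec$params
  K1 <- length(params$columns)
  y_lo_n <- normalize_property(spec$y_lo, params)
  y_hi_n <- normalize_property(spec$y_hi, params)
  if (y_lo_n > y_hi_n) stop("empty target range after normalization")

  mb <- milp_builder()
  xcol <- integer(K1)
  for (i in seq_len(K1)) {
    b <- box_bounds(spec$box, i, params)
    xcol[i] <- mb_add_var(mb, paste0("x", i), b[1], b[2])
  }
  for (i in spec$integral) {
    if (params$degenerate[i]) next
    rng <- params$max[i] - params$min[i]
    rlo <- ceiling(params$min[i] + rng * mb$lb[xcol[i]] - 1e-9)
    rhi <- floor(params$min[i] + rng * mb$ub[xcol[i]] + 1e-9)
    r <- mb_add_var(mb, paste0("raw", i), rlo, rhi, integer = TRUE)
    # raw = min + (max - min) x
    mb_add_row(mb, c(xcol[i], r), c(rng, -1), -params$min[i], -params$min[i])
  }

  gadgets <- new.env(parent = emptyenv())   # key label -> z column
  z_col_for <- function(key) {
    lab <- key_labels(key)
    hit <- gadgets[[lab]]
    if (!is.null(hit)) return(hit)
    a0 <- if (key$form == "complement") 1 else 0
    a1 <- if (key$form == "complement") -1 else 1
    z <- add_gadget_rows(mb, xcol[key$i], xcol[key$j], a0, a1, p, prefix = lab)
    gadgets[[lab]] <- z
    z
  }

  add_eta_row <- function(fit, lb, ub) {
    supp <- fit$weights != 0
    keys <- fit$keys[supp, , drop = FALSE]
    w <- fit$weights[supp]
    cols <- integer(nrow(keys))
    for (r in seq_len(nrow(keys))) {
      cols[r] <- if (keys$form[r] == "linear") xcol[keys$i[r]]
                 else z_col_for(keys[r, , drop = FALSE])
    }
    mb_add_row(mb, cols, w, lb - fit$intercept, ub - fit$intercept)
  }

  add_eta_row(spec$model, y_lo_n, y_hi_n)
  for (er in extra_ranges) add_eta_row(er$hyperplane, er$lb, er$ub)

  for (sc in spec$side_constraints) {
    nz <- which(sc$coefs != 0)
    mb_add_row(mb, xcol[nz], sc$coefs[nz],
               sc$lb %||% -Inf, sc$ub %||% Inf)
  }

  if (!is.null(reference)) {
    stopifnot(length(reference) == K1)
    for (i in seq_len(K1)) {
      t_i <- mb_add_var(mb, paste0("l1dist", i), 0, Inf, obj = 1)
      mb_add_row(mb, c(t_i, xcol[i]), c(1, -1), -reference[i], Inf)
      mb_add_row(mb, c(t_i, xcol[i]), c(1, 1), reference[i], Inf)
    }
  }

  milp <- mb_build(mb)
  z_labels <- ls(gadgets)
  attr(milp, "map") <- list(
    spec = spec, p = p, x_cols = xcol,
    z_cols = stats::setNames(vapply(z_labels, function(l) gadgets[[l]], integer(1)),
                             z_labels)
  )
  milp
}

box_bounds <- function(box, i, params) {
  if (params$degenerate[i]) return(c(0, 0))
  lo <- 0; hi <- 1
  if (!is.null(box)) {
    row <- box[box$i == i, , drop = FALSE]
    if (nrow(row) == 1L) {
      rng <- params$max[i] - params$min[i]
      lo <- max(0, (row$lo - params$min[i]) / rng)
      hi <- min(1, (row$hi - params$min[i]) / rng)
      if (lo > hi) stop("empty box for descriptor ", i, " after normalization")
    }
  }
  c(lo, hi)
}

#' Solve the inverse-inference MILP
#'
#' Hands the model to the solver bridge and, when feasible, reports the
#' inferred normalized descriptor vector `x*`, the model's internal
#' prediction `eta_milp` (using the gadget outputs; guaranteed inside the
#' normalized target range), and the exact re-evaluation `eta_exact` of the
#' prediction function at `x*`. Because each gadget over-approximates its
#' product by at most `1/(2^(p+1)-1)`, `eta_exact` can undershoot the lower
#' target by at most `sum_q max(w_q, 0) / (2^(p+1)-1)` and overshoot the
#' upper by at most `sum_q max(-w_q, 0) / (2^(p+1)-1)`; both slacks are
#' returned.
#'
#' @param milp a model from [build_inverse_milp()].
#' @param time_limit_s solver time limit (defaults to the spec's).
#' @return A list with `status`, `x_star` (normalized), `x_raw` (original
#'   scale), `eta_milp`, `eta_exact` (normalized scale), `y_milp`, `y_exact`
#'   (original scale), and `slack_lo` / `slack_hi`.
#' @export
solve_inverse <- function(milp, time_limit_s = NULL) {
  map <- attr(milp, "map")
  if (is.null(map)) stop("not an inverse-inference model: build with build_inverse_milp()")
  spec <- map$spec
  tl <- time_limit_s %||% spec$time_limit_s
  ans <- solve_milp(milp, time_limit_s = tl)
  bound <- gadget_error_bound(map$p)
  wq <- spec$model$weights[spec$model$keys$form != "linear"]
  slack_lo <- sum(pmax(wq, 0)) * bound
  slack_hi <- sum(pmax(-wq, 0)) * bound
  out <- list(status = ans$status, x_star = NULL, x_raw = NULL,
              eta_milp = NA_real_, eta_exact = NA_real_,
              y_milp = NA_real_, y_exact = NA_real_,
              slack_lo = slack_lo, slack_hi = slack_hi)
  if (ans$status != "feasible") return(out)
  x_star <- ans$x[map$x_cols]
  names(x_star) <- spec$params$columns
  fit <- spec$model
  supp <- fit$weights != 0
  keys <- fit$keys[supp, , drop = FALSE]
  w <- fit$weights[supp]
  vals <- vapply(seq_len(nrow(keys)), function(r) {
    if (keys$form[r] == "linear") x_star[keys$i[r]]
    else ans$x[map$z_cols[[key_labels(keys[r, , drop = FALSE])]]]
  }, numeric(1))
  out$x_star <- unname(x_star)
  raw <- spec$params$min + (spec$params$max - spec$params$min) * x_star
  out$x_raw <- unname(raw)
  out$eta_milp <- fit$intercept + sum(w * vals)
  out$eta_exact <- unname(predict(fit, matrix(x_star, nrow = 1)))
  out$y_milp <- denormalize_property(out$eta_milp, spec$params)
  out$y_exact <- denormalize_property(out$eta_exact, spec$params)
  out
}
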