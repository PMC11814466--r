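#' The p-bit binary-expansion product gadget
#'
#' A quadratic descriptor `x * y` cannot appear directly in a linear
#' program. The gadget quantizes the first factor: `(2^(p+1) - 1) x` is
#' bracketed by a `p+1`-bit binary number `sum_j 2^j chi_j` (binary
#' variables `chi_j`, `j = 0..p`), each bit is multiplied by the continuous
#' factor `y` through the big-M pair
#' `y - (1 - chi_j) <= z_j <= y + (1 - chi_j)` with `z_j <= chi_j`, and the
#' output is `z = sum_j 2^j z_j / (2^(p+1) - 1)`. For every feasible
#' assignment, `x y <= z <= x y + 1 / (2^(p+1) - 1)`; at the default
#' `p = 6` the deviation is at most `1/127`, about 0.8%.
#'
#' `emit_product_gadget()` builds the gadget for one quadratic descriptor
#' key as a standalone constraint block over named variables; inside
#' [build_inverse_milp()] the same rows are emitted per quadratic key of the
#' model support. For a complement key `x(i) (1 - x(j))` the quantized
#' factor is `x(i)` and the continuous factor is the affine `1 - x(j)`.
#'
#' @param key a single quadratic (`product` or `complement`) descriptor key.
#' @param p bit-count parameter (default 6).
#' @return A `milp_model` (see [milp_builder()]) whose variables are the two
#'   normalized descriptors, the `p+1` bits `chi_j`, the `p+1` bit products
#'   `z_j`, and the output `z`; attribute `z_var` names the output variable.
#' @examples
#' g <- emit_product_gadget(descriptor_keys("product", 1, 2), p = 6)
#' g$var_names
#' @export
emit_product_gadget <- function(key, p = 6L) {
  key <- as_descriptor_keys(key)
  stopifnot(nrow(key) == 1L, p >= 1L)
  if (key$form == "linear") stop("gadget needs a quadratic key")
  mb <- milp_builder()
  xi <- mb_add_var(mb, paste0("x", key$i), 0, 1)
  xj <- if (key$j == key$i) xi else mb_add_var(mb, paste0("x", key$j), 0, 1)
  # continuous factor y = a0 + a1 * x(j)
  a0 <- if (key$form == "complement") 1 else 0
  a1 <- if (key$form == "complement") -1 else 1
  z <- add_gadget_rows(mb, xi, xj, a0, a1, p, prefix = key_labels(key))
  out <- mb_build(mb)
  attr(out, "z_var") <- out$var_names[z]
  attr(out, "p") <- p
  out
}

# Emits the gadget rows into an existing builder. xi/xj are column indices of
# the quantized factor x and of the linear descriptor carrying the continuous
# factor y = a0 + a1 * x(j). Returns the column index of the output z.
add_gadget_rows <- function(mb, xi, xj, a0, a1, p, prefix) {
  M <- 2^(p + 1) - 1
  bits <- 0:p
  chi <- vapply(bits, function(b)
    mb_add_var(mb, paste0(prefix, ".chi", b), 0, 1, integer = TRUE), integer(1))
  zb <- vapply(bits, function(b)
    mb_add_var(mb, paste0(prefix, ".zb", b), 0, 1), integer(1))
  z <- mb_add_var(mb, paste0(prefix, ".z"), 0, 1)
  # sum 2^j chi_j - 1 <= M x <= sum 2^j chi_j
  mb_add_row(mb, c(chi, xi), c(2^bits, -M), 0, 1)
  for (b in seq_along(bits)) {
    # z_j <= chi_j
    mb_add_row(mb, c(zb[b], chi[b]), c(1, -1), -Inf, 0)
    # z_j <= y + (1 - chi_j)  ->  z_j - a1 x(j) + chi_j <= 1 + a0
    mb_add_row(mb, c(zb[b], xj, chi[b]), c(1, -a1, 1), -Inf, 1 + a0)
    # z_j >= y - (1 - chi_j)  ->  z_j - a1 x(j) - chi_j >= a0 - 1
    mb_add_row(mb, c(zb[b], xj, chi[b]), c(1, -a1, -1), a0 - 1, Inf)
  }
  # z = sum 2^j z_j / M
  mb_add_row(mb, c(z, zb), c(1, -2^bits / M), 0, 0)
  z
}

#' Gadget error bound
#'
#' `1 / (2^(p+1) - 1)`: the worst-case deviation of the gadget output from
#' the exact product; `1/127` at `p = 6`.
#'
#' @param p bit-count parameter.
#' @export
gadget_error_bound <- function(p = 6L) {
  1 / (2^(p + 1) - 1)
}

#' Enumerate the feasible gadget outputs at fixed factors
#'
#' Brute-forces all `2^(p+1)` bit assignments of a gadget's binary variables
#' against the emitted constraint rows with the two factors fixed at
#' `(x, y)`, and reports, for each feasible bit pattern, the interval of
#' output values `z` the continuous variables allow. Used to verify the
#' gadget's soundness (`x y <= z <= x y + 1/(2^(p+1)-1)`) without a solver.
#'
#' @param x,y factor values in `[0, 1]`.
#' @param p bit-count parameter.
#' @return A tibble with one row per feasible bit pattern: `bits` (the
#'   binary expansion value `sum 2^j chi_j`), `z_min`, `z_max`.
#' @export
gadget_feasible_z <- function(x, y, p = 6L) {
  stopifnot(x >= 0, x <= 1, y >= 0, y <= 1)
  g <- cached_gadget(p)
  nm <- g$var_names
  xi <- which(nm == "x1"); xj <- which(nm == "x2")
  chi <- grep("\\.chi", nm); zb <- grep("\\.zb", nm)
  A <- attr(g, "dense")
  n_bits <- length(chi)
  all_bits <- attr(g, "bits")
  sums <- attr(g, "bit_sums")
  M0 <- 2^(p + 1) - 1
  candidates <- which(sums - M0 * x >= -1e-9 & sums - M0 * x <= 1 + 1e-9)
  res <- list()
  for (code_row in candidates) {
    bits <- all_bits[code_row, ]
    # fix x, y and the bit pattern; zb_j and z stay free in [0, 1]
    lo <- g$lb; hi <- g$ub
    lo[xi] <- hi[xi] <- x
    lo[xj] <- hi[xj] <- y
    lo[chi] <- hi[chi] <- bits
    fixed <- lo >= hi
    # tighten each free zb_j using the rows in which it is the only free
    # variable (the three per-bit rows); then check every row by interval
    # arithmetic — after tightening, only the z-definition equality couples
    # free variables, and it *defines* z, so the check is exact.
    feas <- TRUE
    for (v in zb) {
      for (r in seq_along(g$rlb)) {
        cv <- A[r, v]
        if (cv == 0) next
        row_free <- which(A[r, ] != 0 & !fixed)
        if (!identical(row_free, v)) next
        others <- sum(A[r, fixed] * lo[fixed] * (A[r, fixed] != 0))
        bnds <- sort(c((g$rlb[r] - others) / cv, (g$rub[r] - others) / cv))
        lo[v] <- max(lo[v], bnds[1])
        hi[v] <- min(hi[v], bnds[2])
      }
      if (lo[v] > hi[v] + 1e-9) { feas <- FALSE; break }
    }
    if (feas) {
      for (r in seq_along(g$rlb)) {
        coefs <- A[r, ]
        row_min <- sum(pmin(coefs * lo, coefs * hi))
        row_max <- sum(pmax(coefs * lo, coefs * hi))
        if (row_min > g$rub[r] + 1e-9 || row_max < g$rlb[r] - 1e-9) {
          feas <- FALSE
          break
        }
      }
    }
    if (!feas) next
    M <- 2^(p + 1) - 1
    w <- 2^(0:p) / M
    res[[length(res) + 1L]] <- tibble::tibble(
      bits = sum(2^(0:p) * bits),
      z_min = sum(w * lo[zb]),
      z_max = sum(w * hi[zb])
    )
  }
  if (length(res) == 0L) return(tibble::tibble(bits = numeric(0), z_min = numeric(0), z_max = numeric(0)))
  dplyr::bind_rows(res)
}

.gadget_cache <- new.env(parent = emptyenv())

cached_gadget <- function(p) {
  key <- as.character(p)
  g <- .gadget_cache[[key]]
  if (is.null(g)) {
    g <- emit_product_gadget(descriptor_keys("product", 1L, 2L), p = p)
    attr(g, "dense") <- milp_dense_matrix(g)
    # all bit patterns of the p+1 binaries, with their expansion values:
    # the bracketing row involves only fixed variables, so it prunes the
    # candidate patterns exactly before the full row check.
    n_bits <- p + 1
    bits <- t(vapply(0:(2^n_bits - 1),
                     function(code) as.integer(intToBits(code))[seq_len(n_bits)],
                     integer(n_bits)))
    attr(g, "bits") <- bits
    attr(g, "bit_sums") <- drop(bits %*% 2^(0:p))
    .gadget_cache[[key]] <- g
  }
  g
}
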