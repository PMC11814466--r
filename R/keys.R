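#' Descriptor keys
#'
#' A descriptor key identifies one feature column of the quadratic-descriptor
#' model: a *linear* descriptor `x(i)`, a *product* `x(i) x(j)` with
#' `i <= j`, or a *complement product* `x(i) (1 - x(j))` where the pair is
#' ordered and `i = j` is allowed. Keys are stored as a tibble with columns
#' `form` (`"linear"`, `"product"` or `"complement"`), `i` and `j` (`j` is
#' `NA` for linear keys). Product keys are canonicalised so that `i <= j`.
#'
#' @param form character vector of key forms.
#' @param i,j 1-based linear-descriptor indices; `j` is ignored (set to `NA`)
#'   for linear keys.
#' @return A tibble of class `descriptor_keys` with columns `form`, `i`, `j`.
#' @examples
#' descriptor_keys(c("linear", "product", "complement"), i = c(1, 2, 1), j = c(NA, 1, 1))
#' @export
descriptor_keys <- function(form, i, j = NA_integer_) {
  form <- as.character(form)
  ok <- form %in% c("linear", "product", "complement")
  if (!all(ok)) {
    stop("unknown key form(s): ", paste(unique(form[!ok]), collapse = ", "))
  }
  n <- max(length(form), length(i), length(j))
  keys <- tibble::tibble(
    form = rep_len(form, n),
    i = as.integer(rep_len(i, n)),
    j = as.integer(rep_len(j, n))
  )
  keys$j[keys$form == "linear"] <- NA_integer_
  if (any(keys$form != "linear" & is.na(keys$j))) {
    stop("quadratic keys need both indices i and j")
  }
  if (any(keys$i < 1L, na.rm = TRUE) || any(keys$j < 1L, na.rm = TRUE)) {
    stop("descriptor indices are 1-based and must be positive")
  }
  # canonical storage of the unordered product pair
  swap <- keys$form == "product" & !is.na(keys$j) & keys$i > keys$j
  if (any(swap)) {
    tmp <- keys$i[swap]
    keys$i[swap] <- keys$j[swap]
    keys$j[swap] <- tmp
  }
  class(keys) <- c("descriptor_keys", class(keys))
  keys
}

as_descriptor_keys <- function(keys) {
  if (inherits(keys, "descriptor_keys")) return(keys)
  descriptor_keys(keys$form, keys$i, keys$j %||% NA_integer_)
}

#' Linear descriptor keys over K1 columns
#'
#' @param K1 number of linear descriptors.
#' @return A `descriptor_keys` tibble of the `K1` linear keys.
#' @export
linear_keys <- function(K1) {
  K1 <- as.integer(K1)
  stopifnot(K1 >= 0)
  descriptor_keys(rep("linear", K1), i = seq_len(K1))
}

#' Expand linear keys into the quadratic descriptor universe
#'
#' Given a set of linear keys over columns `i1 < i2 < ...`, returns every
#' product key `x(i) x(j)` with `i <= j` and every complement-product key
#' `x(i) (1 - x(j))` over all ordered pairs (including `i = j`). For `K1`
#' linear keys the result has `(3 K1^2 + K1) / 2` rows.
#'
#' @param keys a `descriptor_keys` tibble of linear keys.
#' @return A `descriptor_keys` tibble of the quadratic keys, in canonical
#'   order (products by `(i, j)`, then complements by `(i, j)`).
#' @examples
#' expand_quadratic(linear_keys(2))
#' @export
expand_quadratic <- function(keys) {
  keys <- as_descriptor_keys(keys)
  if (any(keys$form != "linear")) {
    stop("expand_quadratic() expects linear keys only")
  }
  idx <- sort(unique(keys$i))
  if (length(idx) == 0L) {
    return(descriptor_keys(character(0), integer(0), integer(0)))
  }
  prod_pairs <- expand.grid(i = idx, j = idx)
  prod_pairs <- prod_pairs[prod_pairs$i <= prod_pairs$j, , drop = FALSE]
  prod_pairs <- prod_pairs[order(prod_pairs$i, prod_pairs$j), , drop = FALSE]
  comp_pairs <- expand.grid(j = idx, i = idx)[, c("i", "j")]
  comp_pairs <- comp_pairs[order(comp_pairs$i, comp_pairs$j), , drop = FALSE]
  descriptor_keys(
    form = c(rep("product", nrow(prod_pairs)), rep("complement", nrow(comp_pairs))),
    i = c(prod_pairs$i, comp_pairs$i),
    j = c(prod_pairs$j, comp_pairs$j)
  )
}

#' Full descriptor universe over K1 columns
#'
#' Linear keys followed by the quadratic expansion; the total size is
#' `K1 + (3 K1^2 + K1) / 2`.
#'
#' @inheritParams linear_keys
#' @return A `descriptor_keys` tibble.
#' @export
descriptor_universe <- function(K1) {
  lin <- linear_keys(K1)
  dplyr::bind_rows(lin, expand_quadratic(lin)) |> as_descriptor_keys()
}

#' Human-readable labels for descriptor keys
#'
#' Labels are `"x3"`, `"x1*x2"` and `"x1*(1-x2)"` for linear, product and
#' complement keys; they double as the canonical identity used for set
#' operations and caching.
#'
#' @param keys a `descriptor_keys` tibble.
#' @return Character vector of labels.
#' @export
key_labels <- function(keys) {
  keys <- as_descriptor_keys(keys)
  out <- character(nrow(keys))
  lin <- keys$form == "linear"
  pro <- keys$form == "product"
  com <- keys$form == "complement"
  out[lin] <- paste0("x", keys$i[lin])
  out[pro] <- paste0("x", keys$i[pro], "*x", keys$j[pro])
  out[com] <- paste0("x", keys$i[com], "*(1-x", keys$j[com], ")")
  out
}

#' Canonical ordering of descriptor keys
#'
#' Linear keys by `i`, then product keys by `(i, j)`, then complement keys by
#' `(i, j)`; duplicates (after product canonicalisation) are dropped.
#'
#' @param keys a `descriptor_keys` tibble.
#' @return The sorted, de-duplicated `descriptor_keys` tibble.
#' @export
sort_keys <- function(keys) {
  keys <- as_descriptor_keys(keys)
  rank <- match(keys$form, c("linear", "product", "complement"))
  ord <- order(rank, keys$i, keys$j, na.last = FALSE)
  keys <- keys[ord, , drop = FALSE]
  keys[!duplicated(key_labels(keys)), , drop = FALSE]
}

#' Evaluate descriptor keys on a matrix of normalized linear descriptors
#'
#' @param X numeric matrix (rows = compounds, columns = linear descriptors,
#'   assumed min-max normalized so quadratic values stay in `[0, 1]`).
#' @param keys a `descriptor_keys` tibble.
#' @return Numeric matrix with one column per key, labelled by [key_labels()].
#' @export
evaluate_keys <- function(X, keys) {
  keys <- as_descriptor_keys(keys)
  X <- as.matrix(X)
  K1 <- ncol(X)
  if (max(c(0L, keys$i, keys$j), na.rm = TRUE) > K1) {
    stop("descriptor index out of range: table has ", K1, " linear descriptors")
  }
  Z <- matrix(0, nrow(X), nrow(keys))
  for (r in seq_len(nrow(keys))) {
    Z[, r] <- switch(keys$form[r],
      linear     = X[, keys$i[r]],
      product    = X[, keys$i[r]] * X[, keys$j[r]],
      complement = X[, keys$i[r]] * (1 - X[, keys$j[r]])
    )
  }
  colnames(Z) <- key_labels(keys)
  Z
}

#' Evaluate one descriptor key at a descriptor vector
#'
#' @param key a single-row `descriptor_keys` tibble.
#' @param x numeric vector of normalized linear-descriptor values.
#' @return The scalar descriptor value; lies in `[0, 1]` whenever `x` does.
#' @export
evaluate_key <- function(key, x) {
  key <- as_descriptor_keys(key)
  stopifnot(nrow(key) == 1L)
  unname(drop(evaluate_keys(matrix(x, nrow = 1), key)))
}

keys_setdiff <- function(a, b) {
  a[!(key_labels(a) %in% key_labels(b)), , drop = FALSE]
}

keys_union <- function(a, b) {
  sort_keys(dplyr::bind_rows(as_descriptor_keys(a), as_descriptor_keys(b)))
}
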