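#' Fit min-max normalization parameters
#'
#' Records the per-column minimum and maximum of every descriptor column and
#' of the property column, from the *training* table only. Constant columns
#' (`min == max`) are flagged degenerate; they normalize to 0 and are
#' excluded from the quadratic expansion downstream.
#'
#' @param df a descriptor table: one row per compound, numeric descriptor
#'   columns, one numeric property column, optionally an id column.
#' @param property name of the property column. Default `"property"`.
#' @param id name of the id column to ignore, if present. Default
#'   `"compound_id"`.
#' @return An object of class `minmax_params`: descriptor column names in
#'   table order with their `(min, max)`, the property range, and the
#'   degenerate-column flags. `tidy()` returns it as a tibble.
#' @export
fit_minmax <- function(df, property = "property", id = "compound_id") {
  if (nrow(df) < 1L) stop("empty dataset")
  if (!property %in% names(df)) stop("no property column '", property, "'")
  desc_cols <- descriptor_columns(df, property, id)
  mins <- vapply(df[desc_cols], min, numeric(1))
  maxs <- vapply(df[desc_cols], max, numeric(1))
  structure(
    list(
      columns = desc_cols,
      min = unname(mins),
      max = unname(maxs),
      degenerate = unname(mins == maxs),
      property = property,
      property_min = min(df[[property]]),
      property_max = max(df[[property]]),
      id = if (id %in% names(df)) id else NULL
    ),
    class = "minmax_params"
  )
}

descriptor_columns <- function(df, property, id) {
  cols <- setdiff(names(df), c(property, id))
  numeric_cols <- cols[vapply(df[cols], is.numeric, logical(1))]
  if (length(numeric_cols) == 0L) stop("no numeric descriptor columns found")
  numeric_cols
}

#' @export
print.minmax_params <- function(x, ...) {
  cat("<minmax_params> ", length(x$columns), " descriptor columns (",
      sum(x$degenerate), " degenerate), property '", x$property, "' in [",
      format(x$property_min), ", ", format(x$property_max), "]\n", sep = "")
  invisible(x)
}

#' Apply min-max normalization
#'
#' Maps each descriptor value `v` to `(v - min) / (max - min)` using
#' parameters fitted on the training table; degenerate columns map to 0.
#' The property column is normalized by its training range. Values of a test
#' table that fall outside the training range are kept as-is (they land
#' outside `[0, 1]`); clipping would silently distort downstream R^2.
#'
#' @param df a descriptor table with the same descriptor columns as the
#'   table `params` was fitted on.
#' @param params a [fit_minmax()] object.
#' @param normalize_property normalize the property column too (default
#'   `TRUE`; set `FALSE` for tables without a property column).
#' @return The normalized tibble, same shape as `df`.
#' @export
apply_minmax <- function(df, params, normalize_property = TRUE) {
  stopifnot(inherits(params, "minmax_params"))
  missing <- setdiff(params$columns, names(df))
  if (length(missing) > 0L) {
    stop("descriptor column(s) missing from table: ", paste(missing, collapse = ", "))
  }
  out <- tibble::as_tibble(df)
  for (k in seq_along(params$columns)) {
    col <- params$columns[k]
    if (params$degenerate[k]) {
      out[[col]] <- rep(0, nrow(out))
    } else {
      out[[col]] <- (out[[col]] - params$min[k]) / (params$max[k] - params$min[k])
    }
  }
  if (normalize_property) {
    if (!params$property %in% names(out)) {
      stop("no property column '", params$property, "'")
    }
    out[[params$property]] <- normalize_property(out[[params$property]], params)
  }
  out
}

#' Undo min-max normalization of descriptor columns
#'
#' Inverse of [apply_minmax()] on non-degenerate columns; degenerate columns
#' are restored to their constant training value.
#'
#' @inheritParams apply_minmax
#' @export
invert_minmax <- function(df, params, normalize_property = TRUE) {
  stopifnot(inherits(params, "minmax_params"))
  out <- tibble::as_tibble(df)
  for (k in seq_along(params$columns)) {
    col <- params$columns[k]
    if (!col %in% names(out)) next
    if (params$degenerate[k]) {
      out[[col]] <- rep(params$min[k], nrow(out))
    } else {
      out[[col]] <- out[[col]] * (params$max[k] - params$min[k]) + params$min[k]
    }
  }
  if (normalize_property && params$property %in% names(out)) {
    out[[params$property]] <- denormalize_property(out[[params$property]], params)
  }
  out
}

#' Normalize / denormalize property values
#'
#' @param y numeric property values.
#' @param params a [fit_minmax()] object.
#' @return Numeric vector on the other scale.
#' @export
normalize_property <- function(y, params) {
  rng <- params$property_max - params$property_min
  if (rng == 0) return(rep(0, length(y)))
  (y - params$property_min) / rng
}

#' @rdname normalize_property
#' @export
denormalize_property <- function(y, params) {
  y * (params$property_max - params$property_min) + params$property_min
}

#' Read / write a descriptor table as CSV
#'
#' The on-disk dialect is a plain CSV with a header: one id column, the
#' descriptor columns, and one property column.
#'
#' @param path file path.
#' @param property,id column names.
#' @return A tibble.
#' @export
read_descriptor_table <- function(path, property = "property", id = "compound_id") {
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  if (!property %in% names(df)) stop("no property column '", property, "' in ", path)
  df
}

#' @rdname read_descriptor_table
#' @param df the table to write.
#' @export
write_descriptor_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read normalization parameters as a JSON sidecar
#'
#' @param params a [fit_minmax()] object.
#' @param path file path.
#' @export
write_minmax <- function(params, path) {
  stopifnot(inherits(params, "minmax_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_minmax
#' @export
read_minmax <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$degenerate <- as.logical(obj$degenerate)
  structure(obj, class = "minmax_params")
}
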