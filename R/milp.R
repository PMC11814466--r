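#' Mixed-integer model builder
#'
#' A small environment-backed builder for mixed-integer linear programs:
#' variables with bounds and integrality, rows as sparse triplets with
#' two-sided bounds, and a linear objective (minimized). `mb_build()`
#' freezes it into a `milp_model` list with fields `n_var`, `var_names`,
#' `obj`, triplets `A_i`/`A_j`/`A_x`, row bounds `rlb`/`rub`, variable
#' bounds `lb`/`ub`, and `integer` flags.
#'
#' @return `milp_builder()` returns a builder environment; `mb_add_var()`
#'   the new variable's column index; `mb_add_row()` the new row index;
#'   `mb_build()` the frozen `milp_model`.
#' @keywords internal
#' @export
milp_builder <- function() {
  mb <- new.env(parent = emptyenv())
  mb$names <- character(0)
  mb$lb <- numeric(0); mb$ub <- numeric(0)
  mb$int <- logical(0); mb$obj <- numeric(0)
  mb$rows <- list()
  mb$rlb <- numeric(0); mb$rub <- numeric(0)
  mb
}

#' @rdname milp_builder
#' @param mb a builder.
#' @param name variable name (must be unique).
#' @param lb,ub bounds.
#' @param integer integrality flag.
#' @param obj objective coefficient.
#' @export
mb_add_var <- function(mb, name, lb = -Inf, ub = Inf, integer = FALSE, obj = 0) {
  if (name %in% mb$names) stop("duplicate variable name: ", name)
  mb$names <- c(mb$names, name)
  mb$lb <- c(mb$lb, lb); mb$ub <- c(mb$ub, ub)
  mb$int <- c(mb$int, integer); mb$obj <- c(mb$obj, obj)
  length(mb$names)
}

#' @rdname milp_builder
#' @param cols column indices of the row's nonzeros.
#' @param coefs their coefficients.
#' @param rlb,rub row bounds (`rlb = rub` for an equality).
#' @export
mb_add_row <- function(mb, cols, coefs, rlb, rub) {
  stopifnot(length(cols) == length(coefs))
  mb$rows[[length(mb$rows) + 1L]] <- list(cols = as.integer(cols), coefs = as.numeric(coefs))
  mb$rlb <- c(mb$rlb, rlb); mb$rub <- c(mb$rub, rub)
  length(mb$rows)
}

#' @rdname milp_builder
#' @export
mb_build <- function(mb) {
  n_row <- length(mb$rows)
  lens <- vapply(mb$rows, function(r) length(r$cols), integer(1))
  structure(
    list(
      n_var = length(mb$names),
      var_names = mb$names,
      obj = mb$obj,
      A_i = rep(seq_len(n_row), lens),
      A_j = unlist(lapply(mb$rows, `[[`, "cols"), use.names = FALSE) %||% integer(0),
      A_x = unlist(lapply(mb$rows, `[[`, "coefs"), use.names = FALSE) %||% numeric(0),
      rlb = mb$rlb,
      rub = mb$rub,
      lb = mb$lb,
      ub = mb$ub,
      integer = mb$int
    ),
    class = "milp_model"
  )
}

#' @export
print.milp_model <- function(x, ...) {
  cat("<milp_model> ", x$n_var, " variables (", sum(x$integer), " integer), ",
      length(x$rlb), " rows\n", sep = "")
  invisible(x)
}

milp_dense_matrix <- function(milp) {
  A <- matrix(0, length(milp$rlb), milp$n_var)
  A[cbind(milp$A_i, milp$A_j)] <- milp$A_x
  A
}

#' Write a model in CPLEX-LP format
#'
#' @param milp a `milp_model`.
#' @param path output file.
#' @export
write_lp <- function(milp, path) {
  nm <- gsub("[^A-Za-z0-9_]", "_", milp$var_names)
  nm <- make.unique(nm, sep = "_")
  term <- function(coefs, cols) {
    paste(sprintf("%+.17g %s", coefs, nm[cols]), collapse = " ")
  }
  lines <- c("Minimize", paste(" obj:",
    if (any(milp$obj != 0)) term(milp$obj[milp$obj != 0], which(milp$obj != 0)) else "0"))
  lines <- c(lines, "Subject To")
  for (r in seq_along(milp$rlb)) {
    sel <- milp$A_i == r
    expr <- term(milp$A_x[sel], milp$A_j[sel])
    if (is.finite(milp$rlb[r]) && milp$rlb[r] == milp$rub[r]) {
      lines <- c(lines, sprintf(" c%d: %s = %.17g", r, expr, milp$rlb[r]))
    } else {
      if (is.finite(milp$rlb[r])) {
        lines <- c(lines, sprintf(" c%dl: %s >= %.17g", r, expr, milp$rlb[r]))
      }
      if (is.finite(milp$rub[r])) {
        lines <- c(lines, sprintf(" c%du: %s <= %.17g", r, expr, milp$rub[r]))
      }
    }
  }
  lines <- c(lines, "Bounds")
  for (v in seq_len(milp$n_var)) {
    lo <- if (is.finite(milp$lb[v])) sprintf("%.17g", milp$lb[v]) else "-inf"
    hi <- if (is.finite(milp$ub[v])) sprintf("%.17g", milp$ub[v]) else "+inf"
    lines <- c(lines, sprintf(" %s <= %s <= %s", lo, nm[v], hi))
  }
  if (any(milp$integer)) {
    lines <- c(lines, "General", paste("", paste(nm[milp$integer], collapse = " ")))
  }
  lines <- c(lines, "End")
  writeLines(lines, path)
  invisible(path)
}

#' Solve mixed-integer models through the bundled solver bridge
#'
#' Models are serialised to JSON and handed to a branch-and-bound solver in
#' a subprocess (the bundled `inst/python/milp_solve.py`, which uses the
#' HiGHS solver behind `scipy.optimize.milp`); variable assignments are
#' parsed back from the solver's JSON answer. Several models can be solved
#' in one subprocess call with `solve_milp_batch()`.
#'
#' The python interpreter is located via `getOption("quadqsar.python")`,
#' then the `QUADQSAR_PYTHON` environment variable, then `python` /
#' `python3` on the PATH.
#'
#' @param milp a `milp_model`.
#' @param time_limit_s solver time limit per model, seconds.
#' @return A list with `status` (`"feasible"`, `"infeasible"`, `"timeout"`
#'   or `"unbounded"`), `x` (variable assignment, named; `NULL` unless
#'   feasible) and `objective`.
#' @export
solve_milp <- function(milp, time_limit_s = 300) {
  solve_milp_batch(list(milp), time_limit_s)[[1]]
}

#' @rdname solve_milp
#' @param milps a list of `milp_model`s.
#' @export
solve_milp_batch <- function(milps, time_limit_s = 300) {
  stopifnot(length(milps) >= 1L)
  time_limit_s <- rep_len(time_limit_s, length(milps))
  payload <- purrr::map2(milps, time_limit_s, function(m, tl) {
    list(
      n_var = m$n_var,
      obj = as.list(m$obj),
      A_i = as.list(m$A_i), A_j = as.list(m$A_j), A_x = as.list(m$A_x),
      rlb = as.list(encode_inf(m$rlb)), rub = as.list(encode_inf(m$rub)),
      lb = as.list(encode_inf(m$lb)), ub = as.list(encode_inf(m$ub)),
      integrality = as.list(as.integer(m$integer)),
      time_limit = tl
    )
  })
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA)
  script <- system.file("python", "milp_solve.py", package = "quadqsar")
  if (!nzchar(script)) stop("bundled solver script not found")
  status <- system2(find_python(), c(script, infile, outfile),
                    stdout = FALSE, stderr = "")
  if (status != 0 || !file.exists(outfile)) {
    stop("MILP solver bridge failed (exit ", status, "); the contract needs a ",
         "python with scipy >= 1.9 (scipy.optimize.milp)")
  }
  ans <- jsonlite::read_json(outfile, simplifyVector = FALSE)
  purrr::map2(milps, seq_along(milps), function(m, k) {
    st <- ans$status[[k]]
    feasible <- identical(st, "feasible")
    x <- if (feasible) {
      stats::setNames(vapply(ans$x[[k]], as.numeric, numeric(1)), m$var_names)
    } else NULL
    list(status = st, x = x,
         objective = if (feasible) as.numeric(ans$objective[[k]]) else NA_real_)
  })
}

encode_inf <- function(v) {
  v[v == Inf] <- 1e30
  v[v == -Inf] <- -1e30
  v
}

find_python <- function() {
  opt <- getOption("quadqsar.python", "")
  if (nzchar(opt)) return(opt)
  env <- Sys.getenv("QUADQSAR_PYTHON", "")
  if (nzchar(env)) return(env)
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("no python interpreter found for the MILP solver bridge; set ",
       "options(quadqsar.python = ...) or QUADQSAR_PYTHON")
}
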