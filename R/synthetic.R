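#' Planted sparse linear + quadratic response model
#'
#' Defines the generative model for synthetic descriptor tables: `K1`
#' count-valued linear descriptors drawn uniformly from an integer range,
#' and a property equal to an intercept plus a sparse combination of
#' *normalized* descriptor values over a planted support of linear and/or
#' quadratic keys, plus homoscedastic Gaussian noise. This mirrors the
#' statistical structure the modelling pipeline assumes (frequency-type
#' descriptors, a response driven by a few linear and interaction terms)
#' without emulating any specific chemical dataset.
#'
#' @param K1 number of linear descriptors.
#' @param support a `descriptor_keys` tibble with an extra `weight` column:
#'   the true model terms.
#' @param intercept true intercept.
#' @param noise_sd Gaussian noise standard deviation (on the property scale).
#' @param n number of compounds.
#' @param seed generation seed.
#' @param count_range integer range `c(lo, hi)` of the raw descriptor counts.
#' @return An object of class `planted_model`.
#' @export
planted_model <- function(K1, support, intercept = 0, noise_sd = 0.01,
                          n = 300L, seed = 1L, count_range = c(0L, 20L)) {
  keys <- as_descriptor_keys(support[c("form", "i", "j")])
  stopifnot("weight" %in% names(support), noise_sd >= 0, n >= 10,
            length(count_range) == 2L, count_range[1] <= count_range[2])
  if (max(c(0L, keys$i, keys$j), na.rm = TRUE) > K1) {
    stop("planted support references descriptors beyond K1")
  }
  structure(
    list(K1 = as.integer(K1), support = keys,
         weights = as.numeric(support$weight), intercept = intercept,
         noise_sd = noise_sd, n = as.integer(n), seed = as.integer(seed),
         count_range = as.integer(count_range)),
    class = "planted_model"
  )
}

#' Generate a descriptor table from a planted model
#'
#' Draws the raw integer descriptor counts, min-max normalizes them
#' internally (per the generated table's own ranges) to evaluate the
#' planted response, adds noise, and returns the *raw* table — exactly what
#' the pipeline expects as input. The generating model is attached as
#' attribute `ground_truth`. Generation is deterministic in the model seed.
#'
#' @param model a [planted_model()].
#' @return A tibble with `compound_id`, descriptor columns `X1..XK1` (raw
#'   counts) and `property`.
#' @export
gen_table <- function(model) {
  stopifnot(inherits(model, "planted_model"))
  if (nrow(model$support) == 0L) {
    warning("empty planted support: property is pure noise")
  }
  withr::with_seed(model$seed, {
    counts <- matrix(
      sample(seq(model$count_range[1], model$count_range[2]),
             model$n * model$K1, replace = TRUE),
      nrow = model$n, ncol = model$K1
    )
    colnames(counts) <- paste0("X", seq_len(model$K1))
    mins <- apply(counts, 2, min)
    maxs <- apply(counts, 2, max)
    rngs <- ifelse(maxs > mins, maxs - mins, 1)
    Xn <- sweep(sweep(counts, 2, mins), 2, rngs, "/")
    y <- rep(model$intercept, model$n)
    if (nrow(model$support) > 0L) {
      Z <- evaluate_keys(Xn, model$support)
      y <- y + drop(Z %*% model$weights)
    }
    y <- y + stats::rnorm(model$n, sd = model$noise_sd)
    out <- tibble::as_tibble(counts)
    out <- tibble::add_column(out,
      compound_id = sprintf("cpd%04d", seq_len(model$n)), .before = 1)
    out$property <- y
    attr(out, "ground_truth") <- model
    out
  })
}

#' Write a generated table with its ground-truth sidecar
#'
#' The table goes to `path` as CSV and the planted model (support keys,
#' weights, intercept, noise level, seed) to `paste0(path, ".truth.json")`.
#'
#' @param df a table from [gen_table()].
#' @param path CSV output path.
#' @export
write_gen_table <- function(df, path) {
  write_descriptor_table(df, path)
  model <- attr(df, "ground_truth")
  if (!is.null(model)) {
    truth <- list(
      K1 = model$K1, intercept = model$intercept, noise_sd = model$noise_sd,
      n = model$n, seed = model$seed, count_range = model$count_range,
      support = as.data.frame(model$support), weights = model$weights
    )
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Toy molecules
#'
#' A minimal element-labelled multigraph representation: a character vector
#' of heavy-atom element symbols (hydrogens implicit) and a bond table with
#' 1-based endpoints and bond orders 1-3.
#'
#' @param atoms character vector of element symbols (e.g. `"C"`, `"O"`).
#' @param bonds tibble/data frame with columns `from`, `to`, `order`.
#' @return An object of class `toy_molecule`.
#' @examples
#' propane <- toy_molecule(c("C", "C", "C"),
#'                         data.frame(from = c(1, 2), to = c(2, 3), order = 1))
#' @export
toy_molecule <- function(atoms, bonds = NULL) {
  atoms <- as.character(atoms)
  if (is.null(bonds)) {
    bonds <- data.frame(from = integer(0), to = integer(0), order = integer(0))
  }
  bonds <- tibble::as_tibble(bonds)
  stopifnot(all(c("from", "to", "order") %in% names(bonds)))
  if (nrow(bonds) > 0) {
    if (any(bonds$order < 1)) stop("bond orders must be positive")
    if (any(bonds$from < 1 | bonds$from > length(atoms) |
            bonds$to < 1 | bonds$to > length(atoms))) {
      stop("bond endpoint out of range")
    }
  }
  structure(list(atoms = atoms, bonds = bonds), class = "toy_molecule")
}

#' @export
print.toy_molecule <- function(x, ...) {
  cat("<toy_molecule> ", length(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

mol_graph <- function(mol) {
  igraph::graph_from_data_frame(
    mol$bonds[c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = seq_along(mol$atoms))
  )
}

mol_eligible <- function(mol) {
  if (length(mol$atoms) == 0L) return(FALSE)
  g <- mol_graph(mol)
  connected <- igraph::components(g)$no == 1L
  enough_carbon <- sum(mol$atoms == "C") >= 4L
  # neighbors = distinct non-hydrogen neighbors (multi-bonds count once)
  degree_ok <- all(igraph::degree(igraph::simplify(g)) <= 4L)
  connected && enough_carbon && degree_ok
}

#' Eligibility filter for molecule lists
#'
#' Keeps the molecules that satisfy all three dataset-eligibility rules:
#' the (heavy-atom) graph is connected, there are at least four carbon
#' atoms, and no atom has more than four non-hydrogen neighbors.
#' Records that are not valid `toy_molecule` objects are dropped with a
#' warning and counted in `attr(, "n_dropped")`. The filter is idempotent.
#'
#' @param mols a list of [toy_molecule()] objects.
#' @return The filtered list, with attribute `n_dropped` counting
#'   unparsable records.
#' @export
eligibility_filter <- function(mols) {
  valid <- vapply(mols, inherits, logical(1), what = "toy_molecule")
  if (any(!valid)) {
    warning(sum(!valid), " unparsable molecule record(s) dropped")
  }
  mols <- mols[valid]
  kept <- mols[vapply(mols, mol_eligible, logical(1))]
  attr(kept, "n_dropped") <- sum(!valid)
  kept
}

#' Read molecules from a SMILES file
#'
#' One SMILES string per line (optionally followed by a name). Parsing goes
#' through ChemmineR/ChemmineOB; records that fail to parse are dropped
#' with a warning. Hydrogens are suppressed into the implicit-H toy
#' representation.
#'
#' @param path SMILES file path.
#' @return A list of [toy_molecule()] objects.
#' @export
read_molecules_smiles <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("reading SMILES requires the ChemmineR package")
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  smiles <- vapply(strsplit(lines, "[ \t]+"), `[[`, character(1), 1)
  out <- vector("list", length(smiles))
  for (k in seq_along(smiles)) {
    mol <- tryCatch({
      sdf <- ChemmineR::smiles2sdf(smiles[k])
      sdf_to_toy(sdf[[1]])
    }, error = function(e) NULL)
    if (is.null(mol)) {
      warning("could not parse SMILES record ", k, ": ", smiles[k])
      out[[k]] <- NA
    } else {
      out[[k]] <- mol
    }
  }
  out
}

sdf_to_toy <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- gsub("_.*$", "", rownames(ab))
  heavy <- which(elements != "H")
  remap <- match(seq_along(elements), heavy)
  bonds <- tibble::tibble(
    from = remap[as.integer(bb[, 1])],
    to = remap[as.integer(bb[, 2])],
    order = as.integer(bb[, 3])
  )
  bonds <- bonds[!is.na(bonds$from) & !is.na(bonds$to), , drop = FALSE]
  toy_molecule(elements[heavy], bonds)
}

#' Span recovery of a planted support
#'
#' The quadratic descriptor universe carries exact linear dependencies
#' (`x(i) = x(i)x(j) + x(i)(1 - x(j))` for every `j`), so a planted sparse
#' model has many exact sparse representations and selection procedures may
#' legitimately return an equivalent one. Recovery is therefore judged by
#' *span*: every planted descriptor column must lie in the column span of
#' the selected descriptors plus intercept, measured by the relative
#' projection residual.
#'
#' @param df a *normalized* descriptor table.
#' @param selected the selected `descriptor_keys`.
#' @param planted the planted `descriptor_keys`.
#' @param tol relative residual tolerance (default 1e-6).
#' @param property,id column names.
#' @return `TRUE` when every planted column is spanned.
#' @export
support_spanned <- function(df, selected, planted, tol = 1e-6,
                            property = "property", id = "compound_id") {
  desc_cols <- descriptor_columns(df, property, id)
  X <- as.matrix(df[desc_cols])
  S <- cbind(1, evaluate_keys(X, selected))
  P <- evaluate_keys(X, planted)
  Q <- qr.Q(qr(S))
  resid <- P - Q %*% (t(Q) %*% P)
  scale <- pmax(sqrt(colSums(P^2)), 1e-12)
  all(sqrt(colSums(resid^2)) / scale < tol)
}
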