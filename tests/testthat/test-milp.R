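make_params <- function(K1, prop_range = c(0, 1)) {
  structure(list(
    columns = paste0("X", seq_len(K1)), min = rep(0, K1), max = rep(10, K1),
    degenerate = rep(FALSE, K1), property = "property",
    property_min = prop_range[1], property_max = prop_range[2], id = NULL),
    class = "minmax_params")
}

test_that("a linear-only model builds a pure LP", {
  fit <- hyperplane(linear_keys(3), c(0.2, 0.3, 0.5), 0)
  milp <- build_inverse_milp(inverse_spec(fit, make_params(3), 0.4, 0.6))
  expect_equal(sum(milp$integer), 0)
  expect_equal(milp$n_var, 3)
  sol <- solve_inverse(milp, time_limit_s = 30)
  expect_equal(sol$status, "feasible")
  expect_gte(sol$eta_milp, 0.4 - 1e-9)
  expect_lte(sol$eta_milp, 0.6 + 1e-9)
  expect_equal(sol$eta_exact, sol$eta_milp, tolerance = 1e-9)
})

test_that("each quadratic key contributes p+1 binaries and p+2 gadget reals", {
  keys <- descriptor_keys(c("linear", "product", "complement", "product"),
                          i = c(1, 1, 2, 3), j = c(NA, 2, 3, 3))
  fit <- hyperplane(keys, c(0.1, 0.4, 0.3, 0.2), 0)
  for (p in c(3L, 6L)) {
    milp <- build_inverse_milp(inverse_spec(fit, make_params(3), 0.2, 0.8), p = p)
    m <- 3                                    # quadratic keys in the support
    expect_equal(sum(milp$integer), m * (p + 1))
    expect_equal(milp$n_var, 3 + m * (2 * (p + 1) + 1))
  }
})

test_that("infeasibility is detected above the brute-force maximum", {
  keys <- descriptor_keys(c("linear", "product"), i = c(1, 1), j = c(NA, 2))
  fit <- hyperplane(keys, c(0.5, 0.8), 0.2)
  # brute-force maximum of eta over the unit box on a fine grid (K1 = 2)
  xs <- seq(0, 1, length.out = 101)
  eta_max <- max(outer(xs, xs, function(a, b) 0.2 + 0.5 * a + 0.8 * a * b))
  expect_equal(eta_max, 1.5)
  spec <- inverse_spec(fit, make_params(2), eta_max + 0.05, eta_max + 0.1)
  sol <- solve_inverse(build_inverse_milp(spec), time_limit_s = 30)
  expect_equal(sol$status, "infeasible")
  # and feasible just below it (the gadget overshoots, never undershoots)
  spec2 <- inverse_spec(fit, make_params(2), eta_max - 0.05, eta_max)
  sol2 <- solve_inverse(build_inverse_milp(spec2), time_limit_s = 30)
  expect_equal(sol2$status, "feasible")
})

test_that("solved descriptor vectors satisfy box and side constraints", {
  fit <- hyperplane(linear_keys(3), c(0.5, 0.3, 0.2), 0)
  spec <- inverse_spec(
    fit, make_params(3), 0.3, 0.7,
    box = tibble::tibble(i = 1:2, lo = c(2, 0), hi = c(8, 5)),
    side_constraints = list(list(coefs = c(1, 1, 0), lb = 0.4, ub = 1.2)))
  sol <- solve_inverse(build_inverse_milp(spec), time_limit_s = 30)
  expect_equal(sol$status, "feasible")
  expect_gte(sol$x_raw[1], 2 - 1e-9); expect_lte(sol$x_raw[1], 8 + 1e-9)
  expect_lte(sol$x_raw[2], 5 + 1e-9)
  s <- sol$x_star[1] + sol$x_star[2]
  expect_gte(s, 0.4 - 1e-9); expect_lte(s, 1.2 + 1e-9)
})

test_that("integral descriptors come back as integer raw counts", {
  fit <- hyperplane(linear_keys(2), c(0.6, 0.4), 0)
  spec <- inverse_spec(fit, make_params(2), 0.33, 0.37, integral = 1:2)
  sol <- solve_inverse(build_inverse_milp(spec), time_limit_s = 30)
  expect_equal(sol$status, "feasible")
  expect_equal(sol$x_raw, round(sol$x_raw), tolerance = 1e-6)
})

test_that("a reference vector turns feasibility into L1 projection", {
  fit <- hyperplane(linear_keys(2), c(1, 0), 0)
  spec <- inverse_spec(fit, make_params(2), 0.5, 0.5)
  ref <- c(0.9, 0.35)
  sol <- solve_milp(build_inverse_milp(spec, reference = ref), 30)
  expect_equal(sol$status, "feasible")
  # x1 pinned at 0.5 by the target; x2 free, so it sits on the reference
  expect_equal(unname(sol$x[1:2]), c(0.5, 0.35), tolerance = 1e-6)
  expect_equal(sol$objective, 0.4, tolerance = 1e-6)
})

test_that("inverse round trips stay within the gadget slack", {
  withr::with_seed(51, {
    for (rep in 1:5) {
      K1 <- sample(3:6, 1)
      universe <- descriptor_universe(K1)
      m <- sample(3:8, 1)
      pick <- sort(sample(seq_len(nrow(universe)), m))
      keys <- universe[pick, , drop = FALSE]
      fit <- hyperplane(keys, runif(m, -1, 1), runif(1, -0.2, 0.2))
      x0 <- runif(K1)
      eta0 <- unname(predict(fit, matrix(x0, nrow = 1)))
      spec <- inverse_spec(fit, make_params(K1), eta0 - 0.01, eta0 + 0.01)
      sol <- solve_inverse(build_inverse_milp(spec), time_limit_s = 60)
      expect_equal(sol$status, "feasible")
      expect_gte(sol$eta_exact, eta0 - 0.01 - sol$slack_lo - 1e-9)
      expect_lte(sol$eta_exact, eta0 + 0.01 + sol$slack_hi + 1e-9)
    }
  })
})

test_that("LP export writes a parseable CPLEX-LP file", {
  keys <- descriptor_keys(c("linear", "product"), i = c(1, 1), j = c(NA, 2))
  fit <- hyperplane(keys, c(0.5, 0.8), 0.2)
  milp <- build_inverse_milp(inverse_spec(fit, make_params(2), 0.5, 0.6))
  lp <- withr::local_tempfile(fileext = ".lp")
  write_lp(milp, lp)
  txt <- readLines(lp)
  expect_true(any(grepl("^Minimize", txt)))
  expect_true(any(grepl("^Subject To", txt)))
  expect_true(any(grepl("^General", txt)))
  expect_true(any(grepl("^End", txt)))
  # every integer variable is declared
  general <- txt[grep("^General", txt) + 1]
  expect_equal(length(strsplit(trimws(general), " +")[[1]]), sum(milp$integer))
})

test_that("degenerate target ranges are rejected", {
  fit <- hyperplane(linear_keys(2), c(1, 1), 0)
  expect_error(inverse_spec(fit, make_params(2), 0.7, 0.3), "empty target")
})
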