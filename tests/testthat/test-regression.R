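test_that("full shrinkage at huge lambda leaves only the intercept", {
  nb <- normalized_table(K1 = 6, n = 60, noise_sd = 0.05, seed = 2)
  keys <- descriptor_universe(6)
  fit <- fit_lasso(nb, keys, lambda = 1e3)
  expect_true(all(fit$weights == 0))
  expect_equal(fit$intercept, mean(nb$property))
  expect_equal(nrow(des_set_llr(nb, keys, lambda = 1e3)$support), 0)
})

test_that("unpenalized fit recovers a planted linear model", {
  withr::with_seed(10, {
    x <- runif(50)
    df <- tibble::tibble(X1 = x, property = 0.7 * x + 0.1)
  })
  fit <- fit_lasso(df, linear_keys(1), lambda = 0)
  expect_equal(fit$weights, 0.7, tolerance = 1e-8)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-8)
})

test_that("near-zero lasso weights are snapped to exactly zero", {
  nb <- normalized_table(K1 = 6, n = 80, noise_sd = 0.01, seed = 4)
  fit <- fit_lasso(nb, descriptor_universe(6), lambda = 0.01)
  expect_true(all(fit$weights == 0 | abs(fit$weights) > 1e-6))
  # support and weights are consistent
  expect_equal(nrow(support_keys(fit)), sum(fit$weights != 0))
  expect_lte(nrow(support_keys(fit)), nrow(fit$keys))
})

test_that("lasso at moderate penalty finds a planted sparse support", {
  supp <- tibble::tibble(form = c("linear", "product"), i = c(1L, 2L),
                         j = c(NA, 3L), weight = c(1.0, 1.5))
  nb <- normalized_table(K1 = 5, n = 150, noise_sd = 0.005, seed = 6,
                         support = supp)
  sel <- des_set_llr(nb, descriptor_universe(5), lambda = 0.02)
  labs <- key_labels(sel$support)
  expect_true("x2*x3" %in% labs || "x2*(1-x3)" %in% labs)
  expect_lte(nrow(sel$support), 12)
})

test_that("least-squares fit interpolates exact data and handles collinearity", {
  df <- tibble::tibble(X1 = c(0, 0.25, 0.5, 1), property = c(-1, -0.5, 0, 1))
  fit <- fit_mlr(df, linear_keys(1))
  expect_equal(fit$weights, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, -1, tolerance = 1e-10)
  # duplicated descriptor columns: finite weights, identical fitted values
  nb <- normalized_table(K1 = 4, n = 40, noise_sd = 0.02, seed = 8)
  dup <- descriptor_keys(c("linear", "linear", "linear"), i = c(1, 1, 2))
  fit_dup <- fit_mlr(nb, dup)
  fit_one <- fit_mlr(nb, descriptor_keys(c("linear", "linear"), i = c(1, 2)))
  X <- as.matrix(nb[paste0("X", 1:4)])
  expect_true(all(is.finite(fit_dup$weights)))
  expect_equal(predict(fit_dup, X), predict(fit_one, X), tolerance = 1e-8)
})

test_that("least-squares solver matches the normal-equations oracle", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      n <- 30; k <- sample(2:8, 1)
      Z <- matrix(runif(n * k), n, k)
      y <- runif(n)
      Z1 <- cbind(1, Z)
      oracle <- solve(crossprod(Z1), crossprod(Z1, y))
      df <- tibble::as_tibble(as.data.frame(Z))
      names(df) <- paste0("X", seq_len(k))
      df$property <- y
      fit <- fit_mlr(df, linear_keys(k))
      expect_equal(unname(c(fit$intercept, fit$weights)), drop(oracle),
                   tolerance = 1e-8)
    }
  })
})

test_that("cross-validated scores match an independent lm-based oracle", {
  nb <- normalized_table(K1 = 5, n = 60, noise_sd = 0.1, seed = 12)
  keys <- descriptor_keys(c("linear", "linear", "product"),
                          i = c(1, 2, 3), j = c(NA, NA, 4))
  got <- r2_cv_median(nb, keys, p = 3, seed = 9)
  want <- r2_cv_median_oracle(nb, keys, p = 3, seed = 9)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("cross-validation scoring behaves at the extremes", {
  supp <- make_planted_support(10)
  nb <- normalized_table(K1 = 10, n = 100, noise_sd = 0, seed = 13)
  true_keys <- descriptor_keys(supp$form, supp$i, supp$j)
  # noiseless planted response generalizes perfectly
  expect_gte(r2_cv_median(nb, true_keys, p = 1, seed = 1), 0.999)
  expect_gte(final_evaluation(nb, true_keys, seed = 1), 0.999)
  # a constant (degenerate -> all zero) descriptor predicts at chance
  nb0 <- nb
  nb0$X1 <- 0
  expect_lte(r2_cv_median(nb0, linear_keys(1), p = 1, seed = 1), 0)
  # scores never exceed 1
  expect_lte(r2_cv_median(nb, descriptor_universe(3), p = 2, seed = 2), 1)
  expect_error(r2_cv_median(nb[1:8, ], true_keys, p = 1, seed = 1),
               "at least 10")
})

test_that("pure-noise responses score near zero under the final protocol", {
  withr::with_seed(14, {
    df <- tibble::as_tibble(matrix(runif(500 * 5), 500, 5,
                                   dimnames = list(NULL, paste0("X", 1:5))))
    df$property <- runif(500)
  })
  expect_lt(final_evaluation(df, descriptor_universe(5), seed = 3), 0.2)
})

test_that("final evaluation is the 10-round protocol", {
  nb <- normalized_table(K1 = 5, n = 60, noise_sd = 0.05, seed = 15)
  keys <- linear_keys(5)
  expect_equal(final_evaluation(nb, keys, seed = 4),
               r2_cv_median(nb, keys, p = 10, seed = 4))
})

test_that("fold assignments are deterministic, balanced and round-varying", {
  f1 <- cv_folds(103, p = 4, seed = 42)
  f2 <- cv_folds(103, p = 4, seed = 42)
  expect_identical(f1, f2)
  expect_false(identical(f1[, 1], f1[, 2]))
  counts <- table(f1[, 1])
  expect_true(max(counts) - min(counts) <= 1)
  expect_setequal(as.integer(names(counts)), 1:5)
})

test_that("hyperplane tidiers expose terms and summary", {
  nb <- normalized_table(K1 = 4, n = 40, seed = 16)
  fit <- fit_mlr(nb, descriptor_universe(2))
  td <- tidy(fit)
  expect_equal(nrow(td), 9)
  expect_named(td, c("term", "form", "i", "j", "estimate"))
  gl <- glance(fit)
  expect_equal(gl$n_terms, 9)
})
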