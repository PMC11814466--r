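test_that("llr_reduce is the identity when the set already fits", {
  nb <- normalized_table(K1 = 5, n = 60, seed = 21)
  keys <- descriptor_universe(5)
  cfg <- reduction_config(K_tilde = 100, seed = 1)
  expect_identical(key_labels(llr_reduce(nb, keys, cfg)), key_labels(keys))
})

test_that("llr_reduce shrinks to the target size with surviving keys only", {
  nb <- normalized_table(K1 = 12, n = 80, noise_sd = 0.02, seed = 22)
  keys <- descriptor_universe(12)             # 12 + 222 = 234 keys
  cfg <- reduction_config(K_tilde = 60, d_max = 50, c_max = 40, seed = 7,
                          llr_lambda = 0.005)
  out <- llr_reduce(nb, keys, cfg)
  expect_equal(nrow(out), 60)
  expect_true(all(key_labels(out) %in% key_labels(keys)))
  # deterministic given the seed
  out2 <- llr_reduce(nb, keys, cfg)
  expect_identical(key_labels(out), key_labels(out2))
})

test_that("llr_reduce falls back to K-best when the lasso stops shrinking", {
  # with an essentially unpenalized lasso every per-block support is nearly
  # full, so a pass removes (almost) nothing and the fallback must engage
  nb <- normalized_table(K1 = 12, n = 80, noise_sd = 0.02, seed = 22)
  keys <- descriptor_universe(12)
  cfg <- reduction_config(K_tilde = 20, d_max = 300, c_max = 80, seed = 7,
                          llr_lambda = 1e-9)
  w <- capture_warnings(out <- llr_reduce(nb, keys, cfg))
  expect_true(any(grepl("K-best", w)))
  expect_equal(nrow(out), 20)
  expect_true(all(key_labels(out) %in% key_labels(keys)))
})

test_that("bs_reduce never scores below the full input set", {
  nb <- normalized_table(K1 = 8, n = 80, noise_sd = 0.05, seed = 23)
  keys <- descriptor_keys(c("linear", "linear", "linear", "product", "complement"),
                          i = c(1, 2, 3, 4, 5), j = c(NA, NA, NA, 5, 6))
  out <- bs_reduce(nb, keys, p = 2, seed = 3)
  full_score <- r2_cv_median(nb, keys, p = 2, seed = 3)
  expect_gte(attr(out, "score"), full_score)
  expect_lte(nrow(out), nrow(keys))
})

test_that("bs_reduce agrees with the exhaustive greedy oracle on small sets", {
  for (seed in c(31, 32, 33)) {
    supp <- tibble::tibble(form = c("linear", "linear"), i = c(1L, 2L),
                           j = c(NA, NA), weight = c(1, 0.8))
    nb <- normalized_table(K1 = 6, n = 60, noise_sd = 0.05, seed = seed,
                           support = supp)
    keys <- descriptor_keys(
      c("linear", "linear", "linear", "product", "complement"),
      i = c(1, 2, 3, 4, 2), j = c(NA, NA, NA, 5, 6))
    got <- bs_reduce(nb, keys, p = 2, seed = seed)
    want <- suppressWarnings(greedy_oracle(nb, keys, p = 2, seed = seed))
    expect_identical(key_labels(got), key_labels(want))
  }
})

test_that("bs_reduce keeps the planted pair on noiseless data", {
  supp <- tibble::tibble(form = c("linear", "linear"), i = c(1L, 2L),
                         j = c(NA, NA), weight = c(1, 1))
  nb <- normalized_table(K1 = 4, n = 60, noise_sd = 0, seed = 34,
                         support = supp)
  keys <- descriptor_keys(c("linear", "linear", "linear", "linear"), i = 1:4)
  out <- bs_reduce(nb, keys, p = 2, seed = 5)
  expect_true(all(c("x1", "x2") %in% key_labels(out)))
})

test_that("the stepwise size cap follows the compound count", {
  expect_equal(s_max_cap(200), 175)           # 150 + 1e4/400
  expect_equal(s_max_cap(0), 200)
  expect_equal(s_max_cap(1800), 155)
})

test_that("select_des_set scans 17 penalties and returns a scored subset", {
  supp <- tibble::tibble(form = c("linear", "product"), i = c(1L, 2L),
                         j = c(NA, 3L), weight = c(1.0, 1.4))
  nb <- normalized_table(K1 = 5, n = 120, noise_sd = 0.01, seed = 35,
                         support = supp)
  cfg <- reduction_config(seed = 35)
  expect_length(cfg$lambda_grid, 17)
  res <- select_des_set(nb, descriptor_universe(5), cfg)
  trace <- tidy(res)
  expect_equal(sum(trace$stage == "lambda_scan"), 17)
  expect_equal(sum(trace$stage == "refine"), 16)
  expect_equal(res$K1_star + res$K2_star, nrow(res$selected))
  expect_gte(res$score, 0.95)
  # the selected set carries the planted signal
  planted <- descriptor_keys(supp$form, supp$i, supp$j)
  expect_true(support_spanned(nb, res$selected, planted))
  # deterministic given (table, keys, seed)
  res2 <- select_des_set(nb, descriptor_universe(5), cfg)
  expect_identical(key_labels(res$selected), key_labels(res2$selected))
  expect_equal(res$score, res2$score)
})

test_that("refinement grids bracket the winning penalty", {
  g <- quadqsar:::refine_lambda_grid(0.1, c(0, 1e-6, 0.1, 1), size = 16)
  expect_length(g, 16)
  expect_equal(g[1], 0.1 / 4)
  expect_equal(g[16], 0.4)
  g0 <- quadqsar:::refine_lambda_grid(0, c(0, 1e-6, 0.1), size = 16)
  expect_equal(g0[1], 0)
  expect_equal(g0[16], 1e-6)
})
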