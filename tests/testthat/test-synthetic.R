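test_that("table generation is deterministic and refits exactly without noise", {
  supp <- make_planted_support(10)
  m <- planted_model(10, supp, intercept = 0.2, noise_sd = 0, n = 80, seed = 61)
  t1 <- gen_table(m)
  t2 <- gen_table(m)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # refit on the true support: zero residual
  nb <- apply_minmax(t1, fit_minmax(t1))
  keys <- descriptor_keys(supp$form, supp$i, supp$j)
  fit <- fit_mlr(nb, keys)
  pred <- predict(fit, as.matrix(nb[paste0("X", 1:10)]))
  expect_equal(max(abs(pred - nb$property)), 0, tolerance = 1e-10)
})

test_that("raw descriptors are counts within the configured range", {
  tb <- make_table(K1 = 6, n = 50, seed = 62)
  X <- as.matrix(tb[paste0("X", 1:6)])
  expect_true(all(X == round(X)))
  expect_true(all(X >= 0 & X <= 20))
})

test_that("a planted interaction correlates more than its margin", {
  supp <- tibble::tibble(form = "product", i = 1L, j = 2L, weight = 1)
  tb <- gen_table(planted_model(5, supp, intercept = 0, noise_sd = 0.05,
                                n = 200, seed = 63))
  nb <- apply_minmax(tb, fit_minmax(tb))
  z12 <- nb$X1 * nb$X2
  expect_gt(abs(cor(nb$property, z12)), abs(cor(nb$property, nb$X1)))
})

test_that("an empty planted support warns and yields pure noise", {
  supp <- tibble::tibble(form = character(0), i = integer(0),
                         j = integer(0), weight = numeric(0))
  m <- planted_model(4, supp, noise_sd = 0.3, n = 30, seed = 64)
  expect_warning(tb <- gen_table(m), "pure noise")
  expect_equal(nrow(tb), 30)
})

test_that("generated tables round-trip with their ground-truth sidecar", {
  tb <- make_table(K1 = 10, n = 30, seed = 65)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_gen_table(tb, csv)
  expect_true(file.exists(paste0(csv, ".truth.json")))
  truth <- jsonlite::read_json(paste0(csv, ".truth.json"), simplifyVector = TRUE)
  expect_equal(truth$K1, 10)
  expect_equal(nrow(truth$support), 5)
})

# --- eligibility filter ------------------------------------------------------

chain <- function(elements) {
  n <- length(elements)
  toy_molecule(elements, data.frame(from = seq_len(n - 1), to = 2:n, order = 1))
}

test_that("the eligibility rules keep and reject the canonical cases", {
  propane <- chain(c("C", "C", "C"))
  butane <- chain(c("C", "C", "C", "C"))
  neopentane <- toy_molecule(rep("C", 5),
    data.frame(from = c(1, 1, 1, 1), to = 2:5, order = 1))
  # central carbon with five neighbors (not a molecule, a degree probe)
  crowded <- toy_molecule(rep("C", 6),
    data.frame(from = rep(1, 5), to = 2:6, order = 1))
  two_ethanes <- toy_molecule(rep("C", 4),
    data.frame(from = c(1, 3), to = c(2, 4), order = 1))
  kept <- eligibility_filter(list(propane, butane, neopentane, crowded,
                                  two_ethanes))
  expect_length(kept, 2)
  expect_equal(vapply(kept, function(m) length(m$atoms), integer(1)), c(4L, 5L))
})

test_that("the filter is idempotent and counts unparsable records", {
  good <- chain(c("C", "C", "C", "C", "O"))
  expect_warning(kept <- eligibility_filter(list(good, "not a molecule")),
                 "unparsable")
  expect_length(kept, 1)
  expect_equal(attr(kept, "n_dropped"), 1)
  again <- eligibility_filter(kept)
  expect_equal(lapply(again, unclass), lapply(kept, unclass))
})

test_that("a double bond does not double-count a neighbor", {
  # C(=C)(C)(C)C : central carbon, 4 distinct neighbors, one via double bond
  mol <- toy_molecule(rep("C", 5),
    data.frame(from = c(1, 1, 1, 1), to = 2:5, order = c(2, 1, 1, 1)))
  expect_length(eligibility_filter(list(mol)), 1)
})

test_that("SMILES input flows through the parser into the filter", {
  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCC propane", "CCCC butane", "CC(C)(C)C neopentane"), smi)
  mols <- read_molecules_smiles(smi)
  expect_length(mols, 3)
  kept <- eligibility_filter(mols)
  expect_length(kept, 2)
})

test_that("span recovery separates signal sets from unrelated sets", {
  supp <- tibble::tibble(form = c("linear", "product"), i = c(1L, 2L),
                         j = c(NA, 3L), weight = c(1, 1))
  nb <- normalized_table(K1 = 6, n = 80, noise_sd = 0.01, seed = 66,
                         support = supp)
  planted <- descriptor_keys(supp$form, supp$i, supp$j)
  # the planted keys trivially span themselves
  expect_true(support_spanned(nb, planted, planted))
  # an equivalent representation spans them too: x2*x3 = x2 - x2*(1-x3)
  equiv <- descriptor_keys(c("linear", "linear", "complement"),
                           i = c(1, 2, 2), j = c(NA, NA, 3))
  expect_true(support_spanned(nb, equiv, planted))
  # an unrelated set does not
  other <- descriptor_keys(c("linear", "linear"), i = c(4, 5))
  expect_false(support_spanned(nb, other, planted))
})
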