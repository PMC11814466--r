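# Shared fixtures and independent oracles for the test suite.

# A small planted linear + quadratic model over K1 descriptors.
make_planted_support <- function(K1 = 10L) {
  supp <- tibble::tibble(
    form = c("linear", "linear", "product", "product", "complement"),
    i = c(3L, 7L, 1L, 5L, 2L),
    j = c(NA, NA, 2L, 9L, 4L),
    weight = c(0.8, -0.6, 1.2, 0.9, -0.7)
  )
  supp[pmax(supp$i, supp$j, na.rm = TRUE) <= K1, ]
}

make_table <- function(K1 = 10L, n = 120L, noise_sd = 0.01, seed = 1L,
                       support = make_planted_support(K1)) {
  gen_table(planted_model(K1, support, intercept = 0.2, noise_sd = noise_sd,
                          n = n, seed = seed))
}

normalized_table <- function(...) {
  tb <- make_table(...)
  apply_minmax(tb, fit_minmax(tb))
}

# Independent pure-R implementation of the g_p score: lm() per training fold,
# test-fold R^2 with the test-fold mean, median over the 5p scores. Shares
# only the fold assignments with the package implementation.
r2_cv_median_oracle <- function(df, keys, p, seed, property = "property") {
  desc <- setdiff(names(df), c(property, "compound_id"))
  X <- as.matrix(df[desc])
  Z <- evaluate_keys(X, keys)
  y <- df[[property]]
  folds <- cv_folds(length(y), p, seed)
  scores <- c()
  for (r in seq_len(p)) {
    for (f in 1:5) {
      tr <- folds[, r] != f
      dat <- data.frame(y = y, Z)
      fit <- stats::lm(y ~ ., data = dat[tr, , drop = FALSE])
      pred <- stats::predict(fit, newdata = dat[!tr, , drop = FALSE])
      pred[is.na(pred)] <- stats::coef(fit)[1]
      yte <- y[!tr]
      sstot <- sum((yte - mean(yte))^2)
      if (sstot <= 0) next
      scores <- c(scores, 1 - sum((yte - pred)^2) / sstot)
    }
  }
  stats::median(scores)
}

# Independently coded exhaustive greedy backward elimination using the oracle
# score; mirrors the first-occurrence tie-break over canonical key order.
greedy_oracle <- function(df, keys, p, seed, property = "property") {
  keys <- sort_keys(keys)
  active <- seq_len(nrow(keys))
  l_best <- r2_cv_median_oracle(df, keys, p, seed, property)
  best <- active
  while (length(active) > 0) {
    cand <- vapply(seq_along(active), function(k) {
      sub <- keys[active[-k], , drop = FALSE]
      if (nrow(sub) == 0) {
        # intercept-only model
        folds <- cv_folds(nrow(df), p, seed)
        scores <- c()
        y <- df[[property]]
        for (r in seq_len(p)) for (f in 1:5) {
          yte <- y[folds[, r] == f]
          mu <- mean(y[folds[, r] != f])
          sstot <- sum((yte - mean(yte))^2)
          if (sstot <= 0) next
          scores <- c(scores, 1 - sum((yte - mu)^2) / sstot)
        }
        stats::median(scores)
      } else {
        r2_cv_median_oracle(df, sub, p, seed, property)
      }
    }, numeric(1))
    k_star <- which.max(cand)
    active <- active[-k_star]
    if (cand[k_star] > l_best) {
      l_best <- cand[k_star]
      best <- active
    }
  }
  keys[best, , drop = FALSE]
}
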