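test_that("metric examples match hand computations", {
  s <- c(0.9, 0.8, 0.4, 0.3); l <- c(1, 0, 1, 0)
  expect_equal(auc(s, l), 0.75)
  expect_equal(auc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(rep(0.4, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")

  expect_equal(point_biserial_cor(l, l), 1.0)
  expect_equal(point_biserial_cor(1 - l, l), -1.0)
  expect_equal(point_biserial_cor(s, l), oracle_cor(s, l))
  expect_error(point_biserial_cor(rep(1, 4), l), "variance")

  t <- tss(s, l)
  expect_equal(t$tss, 0.5)
  expect_equal(t$threshold, 0.4)           # smallest maximizing threshold
  expect_equal(tss(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$tss, 1.0)

  expect_lt(binomial_deviance(c(1, 1, 0), c(1, 1, 0)), 4e-6)
  expect_equal(binomial_deviance(rep(0.5, 8), rep(c(0, 1), 4)), 2 * log(2))
  expect_equal(binomial_deviance(exp(-1), 1), 2)
})

test_that("metrics equal brute-force oracles on exhaustively enumerated small tables", {
  set.seed(31)
  for (n in 3:8) {
    scores <- round(runif(n), 1)           # coarse grid forces ties
    for (pattern in 1:(2^n - 2)) {
      labels <- as.integer(intToBits(pattern)[1:n])
      if (length(unique(labels)) < 2) next
      expect_equal(auc(scores, labels), oracle_auc(scores, labels))
      expect_equal(tss(scores, labels)$tss, oracle_tss(scores, labels))
      if (sd(scores) > 0)
        expect_equal(point_biserial_cor(scores, labels),
                     oracle_cor(scores, labels))
    }
  }
})

test_that("rank-based AUC agrees with an established ROC implementation", {
  set.seed(19)
  for (i in 1:10) {
    s <- c(rnorm(40), round(runif(20), 1))      # mixed, with ties
    l <- rbinom(60, 1, 0.4)
    if (length(unique(l)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc(s, l), ref, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transformations", {
  set.seed(8)
  for (i in 1:20) {
    s <- rnorm(30); l <- rbinom(30, 1, 0.3)
    if (length(unique(l)) < 2) next
    expect_equal(auc(exp(s), l), auc(s, l))
    expect_equal(auc(2 * s + 5, l), auc(s, l))
  }
})

test_that("TSS of label-independent scores is near zero", {
  set.seed(77)
  s <- runif(4000); l <- rbinom(4000, 1, 0.5)
  expect_lt(abs(tss(s, l)$tss), 0.08)
})

test_that("replicated evaluation: counts, partition sizes and determinism", {
  fx <- fixture_table(25, n_pres = 20, seed = 37)
  rec <- replicate_evaluate("linear_logistic", fx$table, "subsample",
                            n_reps = 3, seed = 5)
  expect_equal(nrow(rec), 3)
  expect_true(all(rec$auc >= 0 & rec$auc <= 1))
  expect_true(all(rec$deviance >= 0))
  rec2 <- replicate_evaluate("linear_logistic", fx$table, "subsample",
                             n_reps = 3, seed = 5)
  expect_identical(rec, rec2)
  recb <- replicate_evaluate("linear_logistic", fx$table, "bootstrap",
                             n_reps = 2, seed = 5)
  expect_equal(nrow(recb), 2)
})

test_that("stratified 70/30 splits withhold 30% of each class", {
  labels <- rep(c(1L, 0L), c(10, 90))
  set.seed(3)
  parts <- rattanSDM:::split_stratified(labels, 0.30)
  expect_length(parts$test, 30)
  expect_equal(sum(labels[parts$test]), 3)
  expect_length(intersect(parts$train, parts$test), 0)
})

test_that("spatial blocks: geometry, co-membership and the partition property", {
  # points spanning ~600 km x 600 km with 200 km blocks: 9 occupied blocks
  lat <- rep(seq(0.9, 5.9, length.out = 3), each = 3)   # ~185 km spacing
  lon <- rep(seq(0.9, 5.9, length.out = 3), times = 3)
  fa <- assign_spatial_blocks(data.frame(lon = lon, lat = lat),
                              block_km = 200, k = 5, seed = 2)
  expect_equal(length(unique(fa$block)), 9)
  expect_true(all(fa$fold %in% 1:5))
  expect_equal(nrow(fa), 9)

  # two points ~10 km apart share a block hence a fold; partition is total
  near <- data.frame(lon = c(100, 100.09, 102, 104, 101, 103, 100.5),
                     lat = c(0, 0, 2, 0.5, 3, 1.5, 4))
  fa2 <- assign_spatial_blocks(near, block_km = 100, k = 3, seed = 4)
  expect_equal(fa2$fold[1], fa2$fold[2])
  expect_equal(fa2$block[1], fa2$block[2])
  expect_false(anyNA(fa2$fold))
  # rows sharing a block always share a fold
  expect_true(all(tapply(fa2$fold, fa2$block,
                         function(f) length(unique(f))) == 1))
  expect_error(assign_spatial_blocks(near[1:2, ], block_km = 100, k = 3,
                                     seed = 1), "occupied block")
})

test_that("spatial cross-validation returns one AUC per usable fold", {
  fx <- fixture_table(30, n_pres = 25, seed = 41)
  folds <- assign_spatial_blocks(fx$table[, c("lon", "lat")], block_km = 30,
                                 k = 4, seed = 9, labels = fx$table$label)
  res <- spatial_cv("linear_logistic", fx$table, folds, seed = 3)
  expect_equal(nrow(res$per_fold), 4)
  expect_equal(res$mean_auc, mean(res$per_fold$auc))
  expect_true(all(res$per_fold$auc >= 0 & res$per_fold$auc <= 1))
})

test_that("null-model bookkeeping: significance flag matches its stored values", {
  spec <- grid_spec(0, 10, 0.5, 20, 20)
  mask <- matrix(TRUE, 20, 20)
  fit_fun <- function(coords, seed)
    rattanSDM:::with_seed(seed, runif(1, 0.4, 0.6))
  nd <- null_model_test(1.0, spec, mask, 10, fit_fun, n_null = 19, seed = 5)
  expect_true(nd$significant)
  expect_equal(nd$critical,
               unname(quantile(nd$null_auc, 0.95, type = 7)))
  expect_identical(nd$significant, nd$observed > nd$critical)
  nd2 <- null_model_test(0.45, spec, mask, 10, fit_fun, n_null = 19, seed = 5)
  expect_false(nd2$significant)
  expect_identical(nd$null_auc, nd2$null_auc)   # same seed, same nulls
})
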