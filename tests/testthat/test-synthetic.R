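test_that("environment generator is deterministic and honours the smoothing range", {
  spec <- fixture_spec(30)
  a <- generate_environment(spec, c("vpd", "light"), corr_range_cells = 4, seed = 5)
  b <- generate_environment(spec, c("vpd", "light"), corr_range_cells = 4, seed = 5)
  expect_identical(a$layers, b$layers)
  c <- generate_environment(spec, c("vpd", "light"), corr_range_cells = 4, seed = 6)
  expect_false(identical(a$layers$vpd, c$layers$vpd))

  # no smoothing: lag-1 spatial autocorrelation near zero
  w <- generate_environment(spec, "x", corr_range_cells = 0, seed = 9)$layers$x
  lag1 <- cor(as.vector(w[, -1]), as.vector(w[, -ncol(w)]))
  expect_lt(abs(lag1), 0.1)

  # smoothing induces strong lag-1 autocorrelation
  s <- generate_environment(spec, "x", corr_range_cells = 5, seed = 9)$layers$x
  lag1s <- cor(as.vector(s[, -1]), as.vector(s[, -ncol(s)]))
  expect_gt(lag1s, 0.8)
})

test_that("engineered collinear layers and soil triplets behave as stated", {
  spec <- fixture_spec(25)
  st <- generate_environment(
    spec, c("vpd", "light", "sand", "silt", "clay"), corr_range_cells = 3,
    collinear_spec = list(
      list(target = "vpd_copy", sources = "vpd", noise_sd = 0),
      list(target = "mix", sources = c("vpd", "light"), noise_sd = 0.5)),
    seed = 21)
  expect_identical(st$layers$vpd_copy, st$layers$vpd)
  expect_false(identical(st$layers$mix, st$layers$vpd + st$layers$light))
  expect_lt(max(abs(st$layers$mix - st$layers$vpd - st$layers$light)), 3)

  tri <- st$layers$sand + st$layers$silt + st$layers$clay
  expect_lt(max(abs(tri - 100)), 1e-6)
  expect_true(all(st$layers$sand >= 0 & st$layers$sand <= 100))

  expect_error(
    generate_environment(spec, "vpd", collinear_spec =
                           list(list(target = "bad", sources = "nope",
                                     noise_sd = 0)), seed = 1),
    "nope")
})

test_that("virtual species niche evaluation matches the closed form", {
  expect_equal(gaussian_response(5, 5, 2), 1)
  expect_equal(gaussian_response(7, 5, 2), exp(-1 / 2))

  spec <- grid_spec(0, 2, 1, 2, 2)
  st <- env_stack(spec, list(a = matrix(c(1, 2, 3, 4), 2, 2),
                             b = matrix(c(9, 8, 7, 6), 2, 2)))
  vs <- virtual_species(list(a = list(optimum = 3, breadth = 1, weight = 2)))
  s1 <- true_suitability(st, vs)
  # invariant to a permutation of the irrelevant layer
  st2 <- env_stack(spec, list(a = st$layers$a,
                              b = matrix(c(6, 7, 8, 9), 2, 2)))
  expect_equal(true_suitability(st2, vs)$values, s1$values)
  # cell at the optimum attains the link maximum (1 after rescaling)
  expect_equal(max(s1$values), 1)
  expect_true(all(s1$values >= 0 & s1$values <= 1))

  expect_error(true_suitability(st, virtual_species(
    list(zz = list(optimum = 0, breadth = 1, weight = 1)))), "zz")
  expect_error(virtual_species(list(a = list(optimum = 0, breadth = 1,
                                             weight = 0))), "positive")
})

test_that("presence sampling respects support, suitability and seeds", {
  spec <- grid_spec(0, 5, 1, 5, 5)
  uni <- suitability_map(spec, matrix(0.5, 5, 5))
  occ <- sample_presences(uni, 25, seed = 3)
  expect_equal(n_records(occ), 25)
  expect_equal(anyDuplicated(occ$records[, c("lon", "lat")]), 0)
  expect_true(all(occ$records$lon > 0 & occ$records$lon < 5))
  expect_error(sample_presences(uni, 26, seed = 3), "eligible")

  # degenerate support: the only positive-suitability cell is selected
  one <- matrix(0, 5, 5); one[2, 3] <- 1
  occ1 <- sample_presences(suitability_map(spec, one), 1, seed = 8)
  expect_equal(occ1$records$lon, 2.5)
  expect_equal(occ1$records$lat, 3.5)

  expect_identical(sample_presences(uni, 10, seed = 4)$records,
                   sample_presences(uni, 10, seed = 4)$records)

  # sampled cells are suitability-enriched relative to the grid mean
  st <- fixture_stack(20, seed = 31)
  suit <- true_suitability(st, fixture_species())
  means <- vapply(1:300, function(s)
    mean(predict_prob_at(suit, sample_presences(suit, 5, seed = s)$records$lon,
                         sample_presences(suit, 5, seed = s)$records$lat)), 0)
  expect_gt(mean(means), mean(suit$values))
})

test_that("per-cell selection frequency follows normalized suitability", {
  # 10-cell toy grid, 10,000 single draws: chi-square GOF not rejected
  spec <- grid_spec(0, 1, 1, 1, 10)
  p <- c(1, 2, 3, 4, 5, 5, 4, 3, 2, 1)
  suit <- suitability_map(spec, matrix(p / max(p), 1, 10))
  counts <- tabulate(vapply(1:10000, function(s)
    as.integer(sample_presences(suit, 1, seed = s)$records$lon + 0.5), 1L),
    nbins = 10)
  gof <- suppressWarnings(chisq.test(counts, p = p / sum(p)))
  expect_gt(gof$p.value, 0.01)
})

test_that("land-cover generator hits the target share and clusters", {
  spec <- fixture_spec(200, cell = 0.01)
  lc0 <- generate_landcover(spec, 0, seed = 2)
  expect_true(all(lc0$codes == 50L))
  lc1 <- generate_landcover(spec, 1, seed = 2)
  expect_true(all(lc1$codes == 10L))
  lc <- generate_landcover(spec, 0.5, cluster_cells = 6, seed = 2)
  share <- mean(lc$codes == 10L)
  expect_gte(share, 0.45); expect_lte(share, 0.55)
  # clustering: neighbouring cells agree far more often than independent ones
  agree <- mean(lc$codes[, -1] == lc$codes[, -200])
  expect_gt(agree, 0.8)
})
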