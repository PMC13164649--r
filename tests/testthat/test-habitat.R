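test_that("presence threshold follows order-statistic interpolation", {
  expect_equal(presence_threshold(1:100, 10), 10.9)
  expect_equal(presence_threshold(rep(0.3, 7), 10), 0.3)
  expect_equal(presence_threshold(rep(0.3, 7), 80), 0.3)
  expect_equal(presence_threshold(c(5, 1, 3), 0), 1)
  expect_error(presence_threshold(numeric(0)), "no presence")
})

test_that("habitat classification honours the stated boundary conventions", {
  spec <- grid_spec(0, 1, 1, 1, 5)
  s <- suitability_map(spec, matrix(c(0.05, 0.10, 0.40, 0.41, NA), 1, 5))
  cls <- classify_habitat(s, p10 = 0.10, core_cut = 0.40)
  expect_equal(as.vector(cls$classes), c(0L, 1L, 1L, 2L, NA))
  expect_error(classify_habitat(s, p10 = 0.5, core_cut = 0.4), "degenerate")

  # monotone: raising suitability never lowers the class
  set.seed(6)
  v <- matrix(runif(5), 1, 5)
  c1 <- classify_habitat(suitability_map(spec, v), 0.2, 0.4)$classes
  c2 <- classify_habitat(suitability_map(spec, pmin(v + 0.2, 1)), 0.2,
                         0.4)$classes
  expect_true(all(c2 >= c1))
})

test_that("cell areas match the spherical band formula and a numerical oracle", {
  expect_equal(round(cell_area_km2(0, 0.04), 2), 19.78)
  # cosine scaling in the small-cell limit
  expect_equal(cell_area_km2(60, 0.04) / cell_area_km2(0, 0.04), cos(pi / 3),
               tolerance = 1e-4)
  # numerical surface integral oracle: R^2 cos(lat) dlat dlon
  R <- 6371.0088
  for (lat in c(0, 10.37, 45, 75)) for (cs in c(0.04, 0.5, 1)) {
    oracle <- R^2 * (cs * pi / 180) *
      integrate(function(x) cos(x), (lat - cs / 2) * pi / 180,
                (lat + cs / 2) * pi / 180, rel.tol = 1e-12)$value
    expect_equal(cell_area_km2(lat, cs), oracle, tolerance = 1e-4)
  }
  # polar boundary cell: positive and below the equatorial area
  a_pole <- cell_area_km2(89.98, 0.04)
  expect_gt(a_pole, 0)
  expect_lt(a_pole, cell_area_km2(0, 0.04))
})

test_that("class areas partition total land area exactly", {
  spec <- grid_spec(100, 0.04, 0.04, 2, 2)    # 2x2 equatorial grid
  all_core <- classify_habitat(suitability_map(spec, matrix(0.9, 2, 2)),
                               0.1, 0.4)
  a <- class_area_summary(all_core)
  expect_equal(a$area_km2[a$class == "core"], 4 * 19.78, tolerance = 0.01)
  expect_equal(a$area_km2[a$class != "core"], c(0, 0))

  set.seed(13)
  spec2 <- grid_spec(100, 20, 0.25, 40, 40)
  v <- matrix(runif(1600), 40, 40); v[sample(1600, 100)] <- NA
  cls <- class_area_summary(classify_habitat(suitability_map(spec2, v),
                                             0.2, 0.4))
  lat <- 20 - (rep(1:40, each = 40) - 0.5) * 0.25
  land_total <- sum(cell_area_km2(lat, 0.25)[!is.na(t(v))])
  expect_equal(sum(cls$area_km2), land_total, tolerance = 1e-9)
  expect_equal(sum(cls$fraction), 1, tolerance = 1e-9)
})

test_that("pressure overlay: constructed shares, closure and relabeling invariance", {
  spec <- grid_spec(0, 0.04, 0.04, 2, 2)      # equatorial 2x2
  cls <- classify_habitat(suitability_map(spec, matrix(0.9, 2, 2)), 0.1, 0.4)

  mk_lc <- function(codes, mapping) landcover_grid(spec, codes, mapping)
  nat <- mk_lc(matrix(50L, 2, 2), data.frame(code = 50L, category = "natural"))
  p <- pressure_summary(cls, nat)
  expect_equal(p$anthropogenic, rep(0, 3))
  expect_equal(p$natural[p$class == "core"], 100)

  # half the core cells anthropogenic by area (equator: equal-area cells)
  half <- mk_lc(matrix(c(10L, 10L, 50L, 50L), 2, 2),
                data.frame(code = c(10L, 50L),
                           category = c("anthropogenic", "natural")))
  ph <- pressure_summary(cls, half)
  expect_equal(ph$anthropogenic[ph$class == "core"], 50, tolerance = 1e-6)
  # shares sum to 100 for every class that has any area
  expect_equal(ph$anthropogenic + ph$natural + ph$other,
               100 * as.numeric(ph$area_km2 > 0), tolerance = 1e-9)

  # relabeling codes under the same categories changes nothing
  relab <- mk_lc(matrix(c(77L, 77L, 3L, 3L), 2, 2),
                 data.frame(code = c(77L, 3L),
                            category = c("anthropogenic", "natural")))
  expect_equal(pressure_summary(cls, relab)$anthropogenic,
               ph$anthropogenic)

  bad <- matrix(c(10L, 99L, 50L, 50L), 2, 2)
  expect_error(pressure_summary(cls, landcover_grid(
    spec, bad, data.frame(code = c(10L, 50L, 99L),
                          category = c("anthropogenic", "natural", "other")))),
    NA)
  expect_error(landcover_grid(spec, bad,
                              data.frame(code = c(10L, 50L),
                                         category = c("anthropogenic",
                                                      "natural"))), "99")
})

test_that("finer land cover aggregates to the model grid by category area", {
  coarse <- grid_spec(0, 0.2, 0.2, 1, 1)
  cls <- classify_habitat(suitability_map(coarse, matrix(0.9, 1, 1)), 0.1, 0.4)
  fine <- grid_spec(0, 0.2, 0.05, 4, 4)
  codes <- matrix(50L, 4, 4); codes[, 1] <- 10L    # one quarter anthropogenic
  lc <- landcover_grid(fine, codes,
                       data.frame(code = c(10L, 50L),
                                  category = c("anthropogenic", "natural")))
  p <- pressure_summary(cls, lc)
  expect_equal(p$anthropogenic[p$class == "core"], 25, tolerance = 1e-3)
  mismatched <- grid_spec(0.01, 0.2, 0.05, 4, 4)
  expect_error(pressure_summary(cls, landcover_grid(
    mismatched, codes, lc$mapping)), "refinement")
})

test_that("environmental characterization separates distinct species and letters are consistent", {
  spec <- grid_spec(0, 40, 1, 40, 40)
  set.seed(21)
  # one layer with a strong north-south gradient, one pure noise
  ctr <- cell_centers(spec)
  grad <- matrix(ctr$lat, 40, 40, byrow = TRUE) +
    matrix(rnorm(1600, sd = 0.5), 40, 40)
  noise <- matrix(rnorm(1600), 40, 40)
  st <- env_stack(spec, list(grad = grad, noise = noise))
  north <- occ_from(data.frame(lon = runif(25, 1, 39),
                               lat = runif(25, 30, 39)), "north")
  south <- occ_from(data.frame(lon = runif(25, 1, 39),
                               lat = runif(25, 1, 10)), "south")
  mid <- occ_from(data.frame(lon = runif(25, 1, 39),
                             lat = runif(25, 16, 24)), "mid")
  res <- env_characterization(st, list(north = north, south = south,
                                       mid = mid))
  g <- res$grad
  # means 10+ sd apart: all three species get distinct letters
  expect_equal(length(unique(g$letters)), 3)
  expect_true(all(c("species", "median", "q1", "q3", "n_outliers",
                    "letters") %in% names(g)))
  # pure-noise layer: all species share a letter
  n <- res$noise
  shared <- Reduce(intersect, strsplit(n$letters, ""))
  expect_gt(length(shared), 0)

  tiny <- occ_from(data.frame(lon = 5, lat = 5), "tiny")
  expect_warning(env_characterization(
    st, list(north = north, south = south, tiny = tiny)), "excluded")
})

test_that("species sampled from one distribution usually share a letter", {
  spec <- grid_spec(0, 40, 1, 40, 40)
  set.seed(33)
  st <- env_stack(spec, list(x = matrix(rnorm(1600), 40, 40)))
  same_letter <- vapply(1:20, function(i) {
    set.seed(100 + i)
    a <- occ_from(data.frame(lon = runif(30, 1, 39), lat = runif(30, 1, 39)), "a")
    b <- occ_from(data.frame(lon = runif(30, 1, 39), lat = runif(30, 1, 39)), "b")
    r <- env_characterization(st, list(a = a, b = b))$x
    length(Reduce(intersect, strsplit(r$letters, ""))) > 0
  }, TRUE)
  expect_gte(mean(same_letter), 0.9)
})
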