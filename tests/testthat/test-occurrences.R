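raw_records <- function() {
  data.frame(
    lon = c(101.1, 101.1, 102.5, NA, 103.0, 103.0, 104.2),
    lat = c(3.1, 3.1, 4.0, 5.0, 4.5, 4.5, -60),
    event_year = c(1990L, 1990L, 1750L, 2000L, 2010L, 2010L, 2015L),
    basis = c("preserved specimen", "preserved specimen", "human observation",
              "human observation", "FossilSpecimen", "human observation",
              "human observation"),
    source = "gbif")
}

test_that("cleaning drops coordinates-missing, fossil, pre-cutoff and duplicate records", {
  out <- clean_records(occ_from(raw_records()))
  r <- out$records
  expect_equal(nrow(r), 3)                       # 101.1, 103.0(obs), 104.2
  expect_false(any(is.na(r$lon)))
  expect_false(any(grepl("fossil", r$basis, ignore.case = TRUE)))
  expect_true(all(is.na(r$event_year) | r$event_year >= 1800))
  # provenance is stage-monotone
  for (p in out$provenance) expect_lte(p$n_out, p$n_in)
  # unknown year is retained
  out2 <- clean_records(occ_from(data.frame(lon = 1, lat = 1,
                                            event_year = NA_integer_)))
  expect_equal(n_records(out2), 1)
})

test_that("extent filtering keeps interior and boundary points, drops ocean cells", {
  spec <- grid_spec(100, 10, 1, 5, 5)
  occ <- occ_from(data.frame(lon = c(100.5, 105, 99.5, 103.5),
                             lat = c(9.5, 5, 8, 7.5)))
  out <- filter_extent(occ, spec)
  expect_equal(out$records$lon, c(100.5, 105, 103.5))   # boundary retained

  layer <- matrix(1, 5, 5); layer[3, 4] <- NA           # "ocean" at 103.5, 7.5
  st <- env_stack(spec, list(x = layer))
  out2 <- filter_extent(occ, st)
  expect_equal(out2$records$lon, c(100.5, 105))
})

test_that("thinning keeps one deterministic record per cell", {
  spec <- grid_spec(100, 10, 1, 5, 5)
  # 10 records in one cell, years 1990..1999 shuffled: the 1990 record wins
  set.seed(1)
  yrs <- sample(1990:1999)
  occ <- occ_from(data.frame(lon = 100.2 + runif(10, 0, 0.6),
                             lat = 9.2 + runif(10, 0, 0.6),
                             event_year = yrs))
  out <- thin_to_grid(occ, spec)
  expect_equal(n_records(out), 1)
  expect_equal(out$records$event_year, 1990L)

  # distinct cells: unchanged, and output cells are pairwise distinct
  occ2 <- occ_from(data.frame(lon = c(100.5, 101.5, 102.5),
                              lat = c(9.5, 9.5, 8.5), event_year = 2000L))
  out2 <- thin_to_grid(occ2, spec)
  expect_equal(n_records(out2), 3)
  idx <- cell_index(spec, out2$records$lon, out2$records$lat)
  expect_equal(anyDuplicated(idx), 0)

  # year tie resolves to first input record
  occ3 <- occ_from(data.frame(lon = c(100.2, 100.8), lat = c(9.5, 9.5),
                              event_year = c(2005L, 2005L),
                              basis = c("first", "second")))
  expect_equal(thin_to_grid(occ3, spec)$records$basis, "first")
})

test_that("clean -> filter -> thin is monotone and idempotent", {
  spec <- grid_spec(100, 10, 0.5, 20, 20)
  set.seed(42)
  occ <- occ_from(data.frame(
    lon = runif(80, 99, 111), lat = runif(80, -1, 11),
    event_year = sample(c(NA, 1700:2020), 80, replace = TRUE),
    basis = sample(c("human observation", "fossil"), 80, replace = TRUE,
                   prob = c(0.9, 0.1))))
  once <- thin_to_grid(filter_extent(clean_records(occ), spec), spec)
  twice <- thin_to_grid(filter_extent(clean_records(once), spec), spec)
  expect_equal(twice$records, once$records)
  counts <- vapply(once$provenance, function(p) p$n_out, 0L)
  expect_true(all(diff(c(n_records(occ), counts)) <= 0))
})

test_that("merging sources unions cells then thins, preserving per-source counts", {
  spec <- grid_spec(100, 10, 1, 10, 10)
  a <- occ_from(data.frame(lon = c(100.5, 101.5, 102.5), lat = 9.5,
                           source = "gbif"))
  b <- occ_from(data.frame(lon = c(102.7, 104.5), lat = 9.5,
                           source = "literature"))   # 102.7 shares a's cell
  m <- merge_sources(list(a, b), spec)
  expect_equal(n_records(m), 4)
  expect_error(merge_sources(list(a, occ_from(data.frame(lon = 1, lat = 1),
                                              species = "other")), spec),
               "different species")
  # idempotence: merging a set with itself changes nothing
  m2 <- merge_sources(list(a, a), spec)
  expect_equal(n_records(m2), 3)
})

test_that("source sets with pairwise-distinct cells merge additively", {
  # emulates consolidating repository, literature and field sets that
  # occupy disjoint grid cells: 96 + 88 + 41 records merge to 225
  spec <- grid_spec(95, 25, 0.04, 700, 700)
  ctr <- cell_centers(spec)
  set.seed(99)
  pick <- sample(nrow(ctr), 225)
  mk <- function(i, src) occ_from(data.frame(lon = ctr$lon[i],
                                             lat = ctr$lat[i], source = src),
                                  species = "K. test")
  sets <- list(mk(pick[1:96], "gbif"),
               mk(pick[97:184], "literature"),
               mk(pick[185:225], "personal"))
  m <- merge_sources(sets, spec)
  expect_equal(n_records(m), 225)
})
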