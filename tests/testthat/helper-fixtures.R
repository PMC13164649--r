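# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite runs quickly.

fixture_spec <- function(n = 40, cell = 0.04, lon0 = 100, lat0 = 8) {
  grid_spec(lon0, lat0, cell, n, n)
}

# small environmental stack with a smooth vpd gradient plus noise layers
fixture_stack <- function(n = 40, seed = 101, ocean = 0,
                          layers = c("vpd", "light", "sand", "silt", "clay",
                                     "elevation")) {
  generate_environment(fixture_spec(n), layers, corr_range_cells = 5,
                       ocean_fraction = ocean, seed = seed)
}

# virtual species with one dominant driver: a narrow atmospheric-moisture
# specialist (niche breadth 0.6 x the field sd, optimum at the upper edge of
# the realized vpd range so the response is monotone over most of it)
fixture_species <- function() {
  virtual_species(list(vpd = list(optimum = 1.3, breadth = 0.15, weight = 1)))
}

# presence-background table from a seeded synthetic landscape
fixture_table <- function(n_grid = 40, n_pres = 30, ratio = 10, seed = 7) {
  st <- fixture_stack(n_grid, seed = seed)
  suit <- true_suitability(st, fixture_species())
  occ <- sample_presences(suit, n_pres, seed = derive_seed(seed, "pres"))
  pa <- sample_pseudo_absences(st$spec, land_mask(st), occ, ratio = ratio,
                               n_sets = 1, seed = derive_seed(seed, "bg"))
  list(stack = st, suit = suit, occ = occ, table = pb_table(st, occ, pa[[1]]))
}

# occurrence set straight from a records data.frame
occ_from <- function(df, species = "sp") occurrence_set(species, df)

# brute-force metric oracles -------------------------------------------------

oracle_auc <- function(scores, labels) {
  pres <- scores[labels == 1]; back <- scores[labels == 0]
  tot <- 0
  for (p in pres) for (b in back)
    tot <- tot + (p > b) + 0.5 * (p == b)
  tot / (length(pres) * length(back))
}

oracle_tss <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  best <- -Inf
  for (t in sort(unique(scores))) {
    pred <- scores >= t
    v <- sum(pred & labels == 1) / n1 + sum(!pred & labels == 0) / n0 - 1
    if (v > best) best <- v
  }
  best
}

oracle_cor <- function(scores, labels) {
  n <- length(scores)
  sx <- scores - mean(scores); sy <- labels - mean(labels)
  sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
}
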