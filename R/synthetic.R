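#' Virtual-landscape and virtual-species generators
#'
#' These generators produce environmental predictor stacks, virtual species
#' with a known environment-suitability function, occurrence samples drawn
#' proportionally to suitability, and clustered categorical land-cover
#' grids. They reproduce the statistical structure a presence-background
#' analysis assumes (smooth spatial autocorrelation, compositional soil
#' texture, optional engineered collinearity, suitability-biased sampling)
#' so that every downstream stage can be tested against known truth rather
#' than downloaded data.
#'
#' @name synthetic
NULL

# Stationary Gaussian random field on the grid: white noise convolved with an
# isotropic Gaussian kernel of the stated sd (in cells), via FFT with
# periodic wraparound, then standardized to mean 0 / sd 1.
gaussian_field <- function(n_rows, n_cols, range_cells) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (range_cells > 0) {
    ri <- c(0:(n_rows - 1)); ri <- pmin(ri, n_rows - ri)
    ci <- c(0:(n_cols - 1)); ci <- pmin(ci, n_cols - ci)
    d2 <- outer(ri^2, ci^2, "+")
    k <- exp(-d2 / (2 * range_cells^2))
    k <- k / sum(k)
    z <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) /
      (n_rows * n_cols)
  }
  (z - mean(z)) / stats::sd(z)
}

# Plausible physical scales per canonical layer name (mean, sd, lower and
# upper clamp). Unknown names fall back to a standardized field.
layer_scale <- function(name) {
  scales <- list(
    vpd                = c(0.80, 0.25, 0.05, Inf),   # kPa
    light              = c(16,   3,    1,    Inf),   # MJ m-2 day-1
    evapotranspiration = c(110,  25,   0,    Inf),   # mm
    bulk_density       = c(1.30, 0.15, 0.5,  2.2),   # g cm-3
    nitrogen           = c(2.5,  0.8,  0.1,  Inf),   # g kg-1
    elevation          = c(300,  250,  0,    Inf),   # m
    sand               = c(40,   10,   0,    100),   # %
    silt               = c(35,   10,   0,    100),   # %
    clay               = c(25,   10,   0,    100))   # %
  scales[[name]] %||% c(0, 1, -Inf, Inf)
}

#' Generate a synthetic environmental predictor stack
#'
#' Each requested layer is a smooth Gaussian random field low-pass filtered
#' to the stated spatial correlation range (isotropic Gaussian kernel,
#' sd = `corr_range_cells` cells) and rescaled to plausible physical units
#' keyed on the layer name (`vpd` kPa, `light` MJ m-2 day-1,
#' `evapotranspiration` mm, `bulk_density` g cm-3, `sand`/`silt`/`clay` %,
#' `nitrogen` g kg-1, `elevation` m). When all of `sand`, `silt` and `clay`
#' are requested the triplet is built from three positive fields normalized
#' per cell to sum to exactly 100, mimicking compositional soil texture.
#' Engineered collinear layers (for screening tests) are linear combinations
#' of already generated source layers plus Gaussian noise.
#'
#' @param spec A [grid_spec()].
#' @param layer_names Character vector of layers to generate.
#' @param corr_range_cells Spatial correlation range in cells (0 = white
#'   noise).
#' @param collinear_spec Optional list; each element is
#'   `list(target =, sources =, weights =, noise_sd =)` appending a layer
#'   equal to the weighted sum of the sources plus N(0, noise_sd) noise
#'   (weights default to 1).
#' @param ocean_fraction Fraction of cells masked as nodata "ocean",
#'   spatially clustered; 0 for a fully terrestrial grid.
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   output.
#' @return An [env_stack()].
#' @export
generate_environment <- function(spec, layer_names, corr_range_cells = 5,
                                 collinear_spec = NULL, ocean_fraction = 0,
                                 seed = 1L) {
  stopifnot(inherits(spec, "grid_spec"), length(layer_names) >= 1L,
            corr_range_cells >= 0, ocean_fraction >= 0, ocean_fraction < 1)
  with_seed(seed, {
    nr <- spec$n_rows; nc <- spec$n_cols
    layers <- list()
    triplet <- c("sand", "silt", "clay")
    has_triplet <- all(triplet %in% layer_names)
    for (nm in layer_names) {
      if (has_triplet && nm %in% triplet) next  # generated jointly below
      sc <- layer_scale(nm)
      f <- gaussian_field(nr, nc, corr_range_cells)
      layers[[nm]] <- pmin(pmax(sc[1] + sc[2] * f, sc[3]), sc[4])
    }
    if (has_triplet) {
      base <- c(sand = 40, silt = 35, clay = 25)
      pos <- lapply(triplet, function(nm)
        base[[nm]] * exp(0.6 * gaussian_field(nr, nc, corr_range_cells)))
      tot <- pos[[1]] + pos[[2]] + pos[[3]]
      tri <- lapply(pos, function(p) 100 * p / tot)
      names(tri) <- triplet
      # insert in requested order
      for (nm in layer_names) if (nm %in% triplet) layers[[nm]] <- tri[[nm]]
    }
    layers <- layers[layer_names]
    for (cs in collinear_spec) {
      stopifnot(!is.null(cs$target), !is.null(cs$sources))
      missing <- setdiff(cs$sources, names(layers))
      if (length(missing))
        stop(sprintf("collinear target '%s' references ungenerated source layer(s): %s",
                     cs$target, paste(missing, collapse = ", ")))
      w <- cs$weights %||% rep(1, length(cs$sources))
      v <- matrix(0, nr, nc)
      for (i in seq_along(cs$sources)) v <- v + w[i] * layers[[cs$sources[i]]]
      sdn <- cs$noise_sd %||% 0
      if (sdn > 0) v <- v + matrix(stats::rnorm(nr * nc, sd = sdn), nr, nc)
      layers[[cs$target]] <- v
    }
    if (ocean_fraction > 0) {
      f <- gaussian_field(nr, nc, max(corr_range_cells, 1))
      ocean <- f <= stats::quantile(f, ocean_fraction, type = 7)
      layers <- lapply(layers, function(l) { l[ocean] <- NA_real_; l })
    }
    env_stack(spec, layers)
  })
}

#' Define a virtual species
#'
#' A virtual species is a known environment-to-suitability function used to
#' validate the modeling pipeline by niche recovery: because the true niche
#' is known, a correct pipeline must rank the driving predictors first and
#' discriminate presences from background.
#'
#' Each response is Gaussian in one predictor:
#' `g(x) = exp(-((x - optimum) / breadth)^2 / 2)`, taking its maximum 1 at
#' the optimum. Responses are combined by a fixed link (see
#' [true_suitability()]).
#'
#' @param responses Named list (one entry per predictor) of
#'   `list(optimum =, breadth =, weight =)`; weights are unitless, >= 0,
#'   with at least one positive.
#' @param link `"logistic"` (default: logistic of the weighted mean response,
#'   rescaled so the attainable range maps onto 0..1) or `"weighted_mean"`
#'   (the weighted mean response itself).
#' @return An object of class `virtual_species`.
#' @export
virtual_species <- function(responses, link = c("logistic", "weighted_mean")) {
  link <- match.arg(link)
  stopifnot(is.list(responses), length(responses) >= 1L,
            !is.null(names(responses)), all(nzchar(names(responses))))
  w <- vapply(responses, function(r) r$weight %||% 1, 0)
  if (any(w < 0)) stop("response weights must be >= 0")
  if (!any(w > 0)) stop("at least one response weight must be positive")
  for (r in responses)
    if (is.null(r$optimum) || is.null(r$breadth) || r$breadth <= 0)
      stop("each response needs an optimum and a positive breadth")
  structure(list(responses = responses, link = link), class = "virtual_species")
}

#' @rdname virtual_species
#' @param x Predictor value(s).
#' @param optimum,breadth Gaussian response parameters (predictor units).
#' @return `gaussian_response()` returns values in (0, 1], equal to 1 at the
#'   optimum and `exp(-1/2)` one breadth away.
#' @export
gaussian_response <- function(x, optimum, breadth) {
  exp(-0.5 * ((x - optimum) / breadth)^2)
}

#' True suitability surface of a virtual species
#'
#' Evaluates the species' known niche on an environmental stack, cell by
#' cell. With the default logistic link, the weighted mean of the Gaussian
#' responses (which lies in 0..1) is passed through a logistic centered at
#' 0.5 and affinely rescaled so a cell at every optimum scores exactly 1 and
#' a cell with all responses at 0 scores exactly 0. The map is deterministic
#' given its inputs, and depends only on the predictors the species
#' references.
#'
#' @param stack An [env_stack()].
#' @param vs A [virtual_species()].
#' @param steepness Logistic steepness (default 6).
#' @return A `suitability_map` (grid spec + per-cell probability in 0..1).
#' @export
true_suitability <- function(stack, vs, steepness = 6) {
  stopifnot(inherits(stack, "env_stack"), inherits(vs, "virtual_species"))
  missing <- setdiff(names(vs$responses), names(stack$layers))
  if (length(missing))
    stop(sprintf("predictor(s) missing from stack: %s",
                 paste(missing, collapse = ", ")))
  w <- vapply(vs$responses, function(r) r$weight %||% 1, 0)
  acc <- matrix(0, stack$spec$n_rows, stack$spec$n_cols)
  for (nm in names(vs$responses)) {
    r <- vs$responses[[nm]]
    acc <- acc + (r$weight %||% 1) *
      gaussian_response(stack$layers[[nm]], r$optimum, r$breadth)
  }
  m <- acc / sum(w)                      # weighted mean response in [0, 1]
  if (vs$link == "weighted_mean") {
    s <- m
  } else {
    lo <- stats::plogis(steepness * (0 - 0.5))
    hi <- stats::plogis(steepness * (1 - 0.5))
    s <- (stats::plogis(steepness * (m - 0.5)) - lo) / (hi - lo)
  }
  suitability_map(stack$spec, s)
}

#' Per-cell probability surface
#'
#' Container for an ensemble or true suitability surface: a grid spec plus a
#' matrix of probabilities in 0..1 (`NA` = nodata).
#'
#' @param spec A [grid_spec()].
#' @param values Numeric matrix conforming to `spec`, values in 0..1 or `NA`.
#' @return An object of class `suitability_map`.
#' @export
suitability_map <- function(spec, values) {
  stopifnot(inherits(spec, "grid_spec"))
  check_layer_dim(spec, values, "suitability")
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("suitability values must lie in [0, 1]")
  values <- pmin(pmax(values, 0), 1)
  structure(list(spec = spec, values = values), class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf("<suitability_map> %d x %d, mean %.3f (%d nodata cells)\n",
              x$spec$n_rows, x$spec$n_cols, mean(x$values, na.rm = TRUE),
              sum(is.na(x$values))))
  invisible(x)
}

#' Sample presence records proportionally to suitability
#'
#' Draws `n` distinct cells without replacement with per-cell probability
#' proportional to suitability (times an optional bias surface) and places
#' one record at each sampled cell center. Cell-center placement (no
#' within-cell jitter) keeps grid thinning deterministic; jitter is
#' available but off by default.
#'
#' @param suit A `suitability_map`.
#' @param n Number of presences to draw (at most the number of non-nodata
#'   cells).
#' @param seed Integer seed.
#' @param bias Optional non-negative weight matrix conforming to the grid
#'   (e.g. sampling-effort bias).
#' @param species Species name recorded on the output.
#' @param jitter If TRUE, add uniform within-cell jitter to coordinates.
#' @return An [occurrence_set()] with `source = "synthetic"`.
#' @export
sample_presences <- function(suit, n, seed = 1L, bias = NULL,
                             species = "virtual species", jitter = FALSE) {
  stopifnot(inherits(suit, "suitability_map"), n >= 1)
  spec <- suit$spec
  p <- as.vector(t(suit$values))          # row-major over cell_centers order
  if (!is.null(bias)) {
    check_layer_dim(spec, bias, "bias")
    if (any(bias < 0, na.rm = TRUE)) stop("bias weights must be >= 0")
    p <- p * as.vector(t(bias))
  }
  eligible <- which(!is.na(p))
  if (n > length(eligible))
    stop(sprintf("n = %d exceeds the %d eligible (non-nodata) cells",
                 n, length(eligible)))
  centers <- cell_centers(spec)
  idx <- with_seed(seed, {
    picked <- sample(eligible, n, prob = p[eligible])
    if (jitter) jit <- matrix(stats::runif(2 * n, -0.5, 0.5), ncol = 2) else jit <- NULL
    list(picked = picked, jit = jit)
  })
  lon <- centers$lon[idx$picked]; lat <- centers$lat[idx$picked]
  if (!is.null(idx$jit)) {
    lon <- lon + idx$jit[, 1] * spec$cell_size
    lat <- lat + idx$jit[, 2] * spec$cell_size
  }
  occurrence_set(species,
                 data.frame(lon = lon, lat = lat,
                            event_year = 2020L,
                            basis = "human observation",
                            source = "synthetic"))
}

#' Categorical land-cover grid
#'
#' @param spec A [grid_spec()].
#' @param codes Integer matrix of land-cover class codes (`NA` = nodata).
#' @param mapping data.frame with columns `code` and `category`
#'   (`anthropogenic`, `natural` or `other`); every non-nodata code in
#'   `codes` must appear in it.
#' @return An object of class `landcover_grid`.
#' @export
landcover_grid <- function(spec, codes, mapping) {
  stopifnot(inherits(spec, "grid_spec"))
  check_layer_dim(spec, codes, "landcover")
  stopifnot(is.data.frame(mapping), all(c("code", "category") %in% names(mapping)))
  bad <- setdiff(unique(mapping$category), c("anthropogenic", "natural", "other"))
  if (length(bad))
    stop(sprintf("unknown land-cover categor%s: %s",
                 if (length(bad) > 1) "ies" else "y", paste(bad, collapse = ", ")))
  present <- unique(codes[!is.na(codes)])
  unmapped <- setdiff(present, mapping$code)
  if (length(unmapped))
    stop(sprintf("land-cover code(s) missing from mapping: %s",
                 paste(unmapped, collapse = ", ")))
  structure(list(spec = spec, codes = codes, mapping = mapping),
            class = "landcover_grid")
}

#' Generate a clustered categorical land-cover grid
#'
#' Thresholds a smooth Gaussian random field at the empirical quantile of
#' the requested anthropogenic fraction, so the realized share matches the
#' target up to ties and the classes form spatial clusters at the stated
#' range, emulating an aggregated land-cover product.
#'
#' @param spec A [grid_spec()].
#' @param anthropogenic_fraction Target share of anthropogenic cells, 0..1.
#' @param cluster_cells Spatial clustering range in cells.
#' @param seed Integer seed.
#' @param mask Optional logical matrix; cells where FALSE become nodata.
#' @return A [landcover_grid()] with codes 10 (cropland, anthropogenic) and
#'   50 (tree cover, natural).
#' @export
generate_landcover <- function(spec, anthropogenic_fraction, cluster_cells = 5,
                               seed = 1L, mask = NULL) {
  stopifnot(inherits(spec, "grid_spec"),
            anthropogenic_fraction >= 0, anthropogenic_fraction <= 1,
            cluster_cells > 0)
  f <- with_seed(seed, gaussian_field(spec$n_rows, spec$n_cols, cluster_cells))
  if (!is.null(mask)) { check_layer_dim(spec, mask, "mask"); f[!mask] <- NA }
  codes <- matrix(50L, spec$n_rows, spec$n_cols)
  if (anthropogenic_fraction >= 1) {
    codes[] <- 10L
  } else if (anthropogenic_fraction > 0) {
    q <- stats::quantile(f, anthropogenic_fraction, na.rm = TRUE, type = 7)
    codes[!is.na(f) & f <= q] <- 10L
  }
  codes[is.na(f)] <- NA_integer_
  mapping <- data.frame(code = c(10L, 50L),
                        category = c("anthropogenic", "natural"))
  landcover_grid(spec, codes, mapping)
}
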