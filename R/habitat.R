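#' Training-presence suitability threshold
#'
#' Empirical percentile of the ensemble suitability values at the training
#' presences (linear interpolation between order statistics). The 10th
#' percentile ("p10") is the customary lower bound of usable habitat: it
#' discards the 10% least-typical presence environments as noise.
#'
#' @param suitability_at_presences Suitability values at presence
#'   locations (at least one).
#' @param pct Percentile in 0..100 (default 10).
#' @return The threshold value.
#' @examples
#' presence_threshold(1:100, 10)  # 10.9
#' @export
presence_threshold <- function(suitability_at_presences, pct = 10) {
  v <- suitability_at_presences
  stopifnot(is.numeric(v), pct >= 0, pct <= 100)
  if (length(v) < 1L || all(is.na(v))) stop("no presence suitability values")
  unname(stats::quantile(v, pct / 100, na.rm = TRUE, type = 7))
}

#' Classify a suitability map into habitat classes
#'
#' Reclassifies an ensemble suitability surface into three classes:
#' unsuitable (below the presence threshold `p10`), marginal habitat
#' (`p10` up to and including `core_cut`) and core habitat (strictly above
#' `core_cut`, default 0.40). The marginal interval is closed on both
#' sides; a cell exactly at `core_cut` is marginal.
#'
#' @param map A [suitability_map()].
#' @param p10 Lower (presence-percentile) threshold; must not exceed
#'   `core_cut`.
#' @param core_cut Core-habitat cut (default 0.40).
#' @return An object of class `habitat_class_map`: the grid spec, an
#'   integer class matrix (0 unsuitable, 1 marginal, 2 core, `NA` nodata)
#'   and the thresholds used.
#' @export
classify_habitat <- function(map, p10, core_cut = 0.40) {
  stopifnot(inherits(map, "suitability_map"), is.numeric(p10))
  if (p10 > core_cut)
    stop(sprintf("degenerate thresholds: p10 (%g) exceeds core_cut (%g)",
                 p10, core_cut))
  s <- map$values
  cls <- matrix(NA_integer_, map$spec$n_rows, map$spec$n_cols)
  cls[!is.na(s) & s < p10] <- 0L
  cls[!is.na(s) & s >= p10 & s <= core_cut] <- 1L
  cls[!is.na(s) & s > core_cut] <- 2L
  structure(list(spec = map$spec, classes = cls,
                 p10 = p10, core_cut = core_cut,
                 labels = c("unsuitable", "marginal", "core")),
            class = "habitat_class_map")
}

#' @export
print.habitat_class_map <- function(x, ...) {
  n <- table(factor(x$classes, levels = 0:2, labels = x$labels))
  cat(sprintf("<habitat_class_map> p10 = %.4f, core_cut = %.2f | %s\n",
              x$p10, x$core_cut,
              paste(sprintf("%s: %d", names(n), n), collapse = ", ")))
  invisible(x)
}

#' Latitude-corrected cell area
#'
#' Exact spherical band area of a square geographic cell:
#' `A = (pi/180) R^2 w (sin(lat + h) - sin(lat - h))` with `w` the cell
#' width in degrees, `h` half the cell height in radians and
#' `R = 6371.0088` km. At the equator a 0.04-degree cell is about
#' 19.78 km2; area scales approximately with `cos(lat)` toward the poles.
#'
#' @param lat_center Cell-center latitude(s), degrees.
#' @param cell_size Cell edge length, degrees.
#' @return Cell area(s) in km2.
#' @export
cell_area_km2 <- function(lat_center, cell_size) {
  stopifnot(cell_size > 0, all(abs(lat_center) + cell_size / 2 <= 90))
  h <- (cell_size / 2) * pi / 180
  lat <- lat_center * pi / 180
  (pi / 180) * EARTH_RADIUS_KM^2 * cell_size * (sin(lat + h) - sin(lat - h))
}

#' Per-class habitat area accounting
#'
#' Sums latitude-corrected cell areas per habitat class. Class areas
#' partition the classified land exactly: unsuitable + marginal + core
#' equals the total non-nodata area.
#'
#' @param classes A [classify_habitat()] result.
#' @return data.frame with columns `class`, `area_km2` and `fraction` (of
#'   classified land), plus a `total` attribute (km2).
#' @export
class_area_summary <- function(classes) {
  stopifnot(inherits(classes, "habitat_class_map"))
  spec <- classes$spec
  lat <- spec$origin_lat - (seq_len(spec$n_rows) - 0.5) * spec$cell_size
  row_area <- cell_area_km2(lat, spec$cell_size)
  area_mat <- matrix(row_area, spec$n_rows, spec$n_cols)
  out <- data.frame(class = classes$labels,
                    area_km2 = vapply(0:2, function(k)
                      sum(area_mat[!is.na(classes$classes) &
                                     classes$classes == k]), 0))
  total <- sum(out$area_km2)
  out$fraction <- if (total > 0) out$area_km2 / total else 0
  attr(out, "total") <- total
  out
}

lc_category_of <- function(lc) {
  m <- lc$mapping
  cat_of <- m$category[match(lc$codes, m$code)]
  bad <- unique(lc$codes[!is.na(lc$codes) & is.na(cat_of)])
  if (length(bad))
    stop(sprintf("unmapped land-cover code(s): %s", paste(bad, collapse = ", ")))
  matrix(cat_of, lc$spec$n_rows, lc$spec$n_cols)
}

# aggregate a finer land-cover grid to per-category area (km2) per coarse
# model cell; returns list of matrices named by category
lc_area_by_category <- function(lc, spec) {
  cats <- c("anthropogenic", "natural", "other")
  cat_mat <- lc_category_of(lc)
  if (same_grid(lc$spec, spec)) {
    lat <- spec$origin_lat - (seq_len(spec$n_rows) - 0.5) * spec$cell_size
    area <- matrix(cell_area_km2(lat, spec$cell_size), spec$n_rows, spec$n_cols)
    return(stats::setNames(lapply(cats, function(cc) {
      a <- area; a[is.na(cat_mat) | cat_mat != cc] <- 0; a
    }), cats))
  }
  ratio <- spec$cell_size / lc$spec$cell_size
  if (abs(ratio - round(ratio)) > 1e-6 ||
      abs(lc$spec$origin_lon - spec$origin_lon) > 1e-9 ||
      abs(lc$spec$origin_lat - spec$origin_lat) > 1e-9 ||
      lc$spec$n_rows != spec$n_rows * round(ratio) ||
      lc$spec$n_cols != spec$n_cols * round(ratio))
    stop("land-cover grid must coincide with, or be an aligned integer refinement of, the model grid")
  ratio <- as.integer(round(ratio))
  lat_f <- lc$spec$origin_lat - (seq_len(lc$spec$n_rows) - 0.5) * lc$spec$cell_size
  area_f <- matrix(cell_area_km2(lat_f, lc$spec$cell_size),
                   lc$spec$n_rows, lc$spec$n_cols)
  coarse_row <- (seq_len(lc$spec$n_rows) - 1L) %/% ratio + 1L
  coarse_col <- (seq_len(lc$spec$n_cols) - 1L) %/% ratio + 1L
  stats::setNames(lapply(cats, function(cc) {
    a <- area_f; a[is.na(cat_mat) | cat_mat != cc] <- 0
    # sum fine-cell areas into coarse cells
    rowsum_r <- rowsum(a, coarse_row)
    t(rowsum(t(rowsum_r), coarse_col))
  }), cats)
}

#' Anthropogenic pressure within habitat classes
#'
#' Overlays an aggregated land-cover grid on a habitat classification and
#' reports, per habitat class, the area shares of the anthropogenic,
#' natural and other categories (latitude-corrected areas; shares sum to
#' 100 per class). A land-cover grid at finer resolution than the model
#' grid is aggregated by per-cell category area fractions; it must be an
#' aligned integer refinement of the model grid.
#'
#' @param classes A [classify_habitat()] result.
#' @param lc A [landcover_grid()].
#' @return data.frame with columns `class`, `anthropogenic`, `natural`,
#'   `other` (percentages) and `area_km2` (class land-cover area).
#' @export
pressure_summary <- function(classes, lc) {
  stopifnot(inherits(classes, "habitat_class_map"),
            inherits(lc, "landcover_grid"))
  by_cat <- lc_area_by_category(lc, classes$spec)
  out <- lapply(0:2, function(k) {
    in_class <- !is.na(classes$classes) & classes$classes == k
    a <- vapply(by_cat, function(m) sum(m[in_class]), 0)
    tot <- sum(a)
    pct <- if (tot > 0) 100 * a / tot else c(anthropogenic = 0, natural = 0, other = 0)
    data.frame(class = classes$labels[k + 1L],
               anthropogenic = pct[["anthropogenic"]],
               natural = pct[["natural"]],
               other = pct[["other"]],
               area_km2 = tot)
  })
  do.call(rbind, out)
}

#' Environmental characterization at species locations
#'
#' Extracts each predictor at the occurrences of several species and tests
#' for interspecific differences variable by variable: one-way ANOVA with
#' Tukey HSD pairwise comparisons (default) or Kruskal-Wallis with
#' pairwise Wilcoxon tests. Species are summarized by median, quartiles
#' and an outlier count (1.5 IQR rule), and labelled with a compact letter
#' display: species sharing a letter do not differ significantly at
#' `alpha`.
#'
#' @param stack An [env_stack()].
#' @param occ_by_species Named list of [occurrence_set()]s (>= 2 species,
#'   each with >= 2 usable records; smaller species are dropped with a
#'   warning).
#' @param alpha Significance level (default 0.05).
#' @param test `"anova"` (Tukey HSD via multcomp) or `"kruskal"`.
#' @return Named list (one entry per predictor) of data.frames with
#'   columns `species`, `n`, `median`, `q1`, `q3`, `n_outliers`, `letters`.
#' @export
env_characterization <- function(stack, occ_by_species, alpha = 0.05,
                                 test = c("anova", "kruskal")) {
  test <- match.arg(test)
  stopifnot(inherits(stack, "env_stack"), is.list(occ_by_species),
            length(occ_by_species) >= 2L, !is.null(names(occ_by_species)))
  feats <- list()
  for (sp in names(occ_by_species)) {
    occ <- occ_by_species[[sp]]
    stopifnot(inherits(occ, "occurrence_set"))
    f <- extract_at_points(stack, occ$records$lon, occ$records$lat)
    if (nrow(f) < 2L) {
      warning(sprintf("species '%s' has fewer than 2 usable records; excluded", sp))
      next
    }
    f$species <- sp
    feats[[sp]] <- f
  }
  if (length(feats) < 2L) stop("need at least 2 species with >= 2 records")
  df <- do.call(rbind, feats)
  df$species <- factor(df$species)
  out <- list()
  for (v in names(stack$layers)) {
    letters <- tryCatch({
      if (test == "anova") {
        fit <- stats::aov(stats::reformulate("species", v), data = df)
        cld <- multcomp::cld(
          multcomp::glht(fit, linfct = multcomp::mcp(species = "Tukey")),
          level = alpha)
        cld$mcletters$Letters
      } else {
        pw <- stats::pairwise.wilcox.test(df[[v]], df$species,
                                          p.adjust.method = "holm",
                                          exact = FALSE)
        letters_from_pmatrix(pw$p.value, levels(df$species), alpha)
      }
    }, error = function(e) stats::setNames(rep("a", nlevels(df$species)),
                                           levels(df$species)))
    rows <- lapply(levels(df$species), function(sp) {
      x <- df[[v]][df$species == sp]
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      iqr <- q[3] - q[1]
      data.frame(species = sp, n = length(x), median = q[2],
                 q1 = q[1], q3 = q[3],
                 n_outliers = sum(x < q[1] - 1.5 * iqr | x > q[3] + 1.5 * iqr),
                 letters = unname(letters[sp]))
    })
    out[[v]] <- do.call(rbind, rows)
  }
  out
}

# compact letter display from a pairwise p-value matrix (insert-and-absorb)
letters_from_pmatrix <- function(pmat, groups, alpha) {
  k <- length(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (i in rownames(pmat)) for (j in colnames(pmat)) {
    p <- pmat[i, j]
    if (!is.na(p) && p < alpha) { sig[i, j] <- TRUE; sig[j, i] <- TRUE }
  }
  sets <- list(groups)  # start with one letter covering everyone
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig[i, j]) next
    gi <- groups[i]; gj <- groups[j]
    new_sets <- list()
    for (s in sets) {
      if (all(c(gi, gj) %in% s)) {
        new_sets <- c(new_sets, list(setdiff(s, gi)), list(setdiff(s, gj)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb: drop sets contained in another set
    keep <- vapply(seq_along(new_sets), function(a) {
      !any(vapply(seq_along(new_sets), function(b) {
        if (a == b) return(FALSE)
        all(new_sets[[a]] %in% new_sets[[b]]) &&
          (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)
      }, TRUE))
    }, TRUE)
    sets <- new_sets[keep]
  }
  lab <- stats::setNames(rep("", k), groups)
  for (s in seq_along(sets))
    for (g in sets[[s]]) lab[g] <- paste0(lab[g], letters[s])
  lab
}
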