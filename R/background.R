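#' Spatially constrained pseudo-absence sampling
#'
#' Generates replicate sets of pseudo-absence (background) points for a
#' presence-background design. Points are drawn uniformly at random, without
#' replacement, from the eligible cells of the modeling grid: terrestrial
#' (non-nodata), not containing any presence record, and with cell center
#' farther than `buffer_km` great-circle kilometres from every presence.
#' The buffer reduces false absences and spatial autocorrelation between
#' the two classes. Each set pairs with the presences to form one modeling
#' table; the conventional design is ten sets at a 10:1
#' background-to-presence ratio with a 1 km exclusion buffer.
#'
#' Distances use the haversine formula on a sphere of radius 6371.0088 km.
#' At typical modeling resolutions (0.04 degrees, about 4.4 km) a 1 km
#' buffer mainly excludes the presence cells themselves.
#'
#' @param spec The modeling [grid_spec()].
#' @param mask Logical matrix conforming to `spec`; TRUE marks eligible
#'   (terrestrial) cells. Use [land_mask()] on an environmental stack.
#' @param presences An [occurrence_set()] of thinned presences.
#' @param ratio Background points per presence (default 10).
#' @param n_sets Number of independent replicate sets (default 10).
#' @param buffer_km Exclusion buffer around presences in km (default 1).
#' @param seed Integer seed; set s uses a child seed derived from it.
#' @return List of `n_sets` objects of class `pseudo_absence_set`, each with
#'   `set_id`, `points` (data.frame lon/lat at cell centers) and `seed`.
#' @export
sample_pseudo_absences <- function(spec, mask, presences, ratio = 10,
                                   n_sets = 10, buffer_km = 1.0, seed = 1L) {
  stopifnot(inherits(spec, "grid_spec"), inherits(presences, "occurrence_set"),
            ratio >= 1, n_sets >= 1, buffer_km >= 0)
  check_layer_dim(spec, mask, "mask")
  np <- n_records(presences)
  if (np < 1L) stop("at least one presence record is required")
  need <- as.integer(round(ratio * np))

  centers <- cell_centers(spec)
  elig <- as.vector(t(mask))                       # row-major, matches centers
  pidx <- cell_index(spec, presences$records$lon, presences$records$lat)
  pcell <- unique((pidx$row - 1L) * spec$n_cols + pidx$col)
  pcell <- pcell[!is.na(pcell)]
  elig[pcell] <- FALSE
  cand <- which(elig)
  if (buffer_km > 0 && length(cand)) {
    pts <- cbind(centers$lon[cand], centers$lat[cand])
    mind <- rep(Inf, length(cand))
    for (j in seq_len(np)) {
      d <- geosphere::distHaversine(
        c(presences$records$lon[j], presences$records$lat[j]), pts,
        r = EARTH_RADIUS_KM * 1000) / 1000
      mind <- pmin(mind, d)
    }
    cand <- cand[mind > buffer_km]
  }
  if (length(cand) < need)
    stop(sprintf("insufficient eligible cells: need %d, found %d (shortfall %d)",
                 need, length(cand), need - length(cand)))
  lapply(seq_len(n_sets), function(s) {
    child <- derive_seed(seed, "pseudo_absence", s)
    picked <- with_seed(child, sample(cand, need))
    structure(list(set_id = s,
                   points = data.frame(lon = centers$lon[picked],
                                       lat = centers$lat[picked]),
                   seed = child),
              class = "pseudo_absence_set")
  })
}

#' @export
print.pseudo_absence_set <- function(x, ...) {
  cat(sprintf("<pseudo_absence_set> set %d: %d point(s)\n",
              x$set_id, nrow(x$points)))
  invisible(x)
}

#' Assemble a presence-background modeling table
#'
#' Extracts predictor values at presence and background locations and binds
#' them into the single table contract every model family consumes: one row
#' per point with a binary label (1 = presence, 0 = background), predictor
#' columns, coordinates, and the background set id.
#'
#' @param stack An [env_stack()] of screened predictors.
#' @param presences An [occurrence_set()].
#' @param background A `pseudo_absence_set` (or data.frame with lon/lat).
#' @return A data.frame of class `pb_table` with columns `label`, `lon`,
#'   `lat`, `set_id` and one column per predictor; attribute `predictors`
#'   names the predictor columns.
#' @export
pb_table <- function(stack, presences, background) {
  stopifnot(inherits(stack, "env_stack"), inherits(presences, "occurrence_set"))
  bp <- if (inherits(background, "pseudo_absence_set")) background$points
        else as.data.frame(background)
  set_id <- if (inherits(background, "pseudo_absence_set")) background$set_id else 1L
  fp <- extract_at_points(stack, presences$records$lon, presences$records$lat)
  fb <- extract_at_points(stack, bp$lon, bp$lat)
  preds <- names(stack$layers)
  tab <- rbind(
    cbind(data.frame(label = 1L, set_id = set_id), fp),
    cbind(data.frame(label = 0L, set_id = set_id), fb))
  tab <- tab[, c("label", "lon", "lat", "set_id", preds)]
  rownames(tab) <- NULL
  structure(tab, predictors = preds, class = c("pb_table", "data.frame"))
}

pb_predictors <- function(table) {
  p <- attr(table, "predictors")
  if (is.null(p))
    p <- setdiff(names(table), c("label", "lon", "lat", "set_id"))
  p
}

# subset rows of a pb_table keeping its attributes
pb_rows <- function(table, i) {
  out <- table[i, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, predictors = pb_predictors(table),
            class = c("pb_table", "data.frame"))
}
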