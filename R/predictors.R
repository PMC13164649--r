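#' Temporal mean of a time-indexed layer series
#'
#' Per-cell arithmetic mean across layers (e.g. monthly or annual rasters
#' averaged into a decadal normal), ignoring nodata: a cell is nodata in the
#' output only if it is nodata in every input.
#'
#' @param layers List of conformal numeric matrices.
#' @return A numeric matrix of the same dimensions.
#' @export
temporal_mean <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  d <- dim(layers[[1L]])
  for (l in layers) if (!identical(dim(l), d)) stop("layers are not conformal")
  a <- array(unlist(layers), dim = c(d, length(layers)))
  out <- apply(a, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  out
}

#' Average two soil depth intervals
#'
#' Combines a shallow and a deep soil property layer into a single rooting
#' zone value. The default is the unweighted mean of the two intervals; set
#' `thickness_weights` (e.g. `c(5, 10)` cm for 0-5 and 5-15 cm intervals) to
#' weight by interval thickness instead.
#'
#' @param shallow,deep Conformal numeric matrices.
#' @param thickness_weights Optional length-2 positive weights.
#' @return A numeric matrix.
#' @export
depth_average <- function(shallow, deep, thickness_weights = NULL) {
  if (!identical(dim(shallow), dim(deep))) stop("depth layers are not conformal")
  if (is.null(thickness_weights)) return((shallow + deep) / 2)
  stopifnot(length(thickness_weights) == 2L, all(thickness_weights > 0))
  w <- thickness_weights / sum(thickness_weights)
  shallow * w[1] + deep * w[2]
}

#' Bilinear resampling between grids
#'
#' Resamples a layer from one grid geometry to another: each target cell
#' center takes the bilinear interpolation of the four surrounding source
#' cell centers. Target cells outside the source center hull (or adjacent to
#' a source nodata cell) are nodata. Constants and affine functions of
#' lon/lat are reproduced exactly on interior cells.
#'
#' @param layer Source numeric matrix conforming to `from`.
#' @param from,to Source and target [grid_spec()]s (extents must overlap).
#' @return Numeric matrix conforming to `to`.
#' @export
resample_bilinear <- function(layer, from, to) {
  stopifnot(inherits(from, "grid_spec"), inherits(to, "grid_spec"))
  check_layer_dim(from, layer, "source")
  f_east <- from$origin_lon + from$n_cols * from$cell_size
  f_south <- from$origin_lat - from$n_rows * from$cell_size
  t_east <- to$origin_lon + to$n_cols * to$cell_size
  t_south <- to$origin_lat - to$n_rows * to$cell_size
  if (t_east <= from$origin_lon || to$origin_lon >= f_east ||
      to$origin_lat <= f_south || t_south >= from$origin_lat)
    stop("source and target extents are disjoint")
  ctr <- cell_centers(to)
  # fractional position in source cell-center coordinates (1-based)
  gx <- (ctr$lon - (from$origin_lon + 0.5 * from$cell_size)) / from$cell_size + 1
  gy <- ((from$origin_lat - 0.5 * from$cell_size) - ctr$lat) / from$cell_size + 1
  x0 <- floor(gx); y0 <- floor(gy)
  wx <- gx - x0; wy <- gy - y0
  x1 <- x0 + 1; y1 <- y0 + 1
  # exact center alignment collapses the interpolation axis, so aligned
  # targets on the first/last row or column keep support
  snapx <- wx < 1e-9 & x0 >= 1 & x0 <= from$n_cols
  snapy <- wy < 1e-9 & y0 >= 1 & y0 <= from$n_rows
  x1[snapx] <- x0[snapx]
  y1[snapy] <- y0[snapy]
  out <- rep(NA_real_, nrow(ctr))
  ok <- x0 >= 1 & x1 <= from$n_cols & y0 >= 1 & y1 <= from$n_rows
  i <- which(ok)
  v00 <- layer[cbind(y0[i], x0[i])]
  v01 <- layer[cbind(y0[i], x1[i])]
  v10 <- layer[cbind(y1[i], x0[i])]
  v11 <- layer[cbind(y1[i], x1[i])]
  out[i] <- (1 - wy[i]) * ((1 - wx[i]) * v00 + wx[i] * v01) +
    wy[i] * ((1 - wx[i]) * v10 + wx[i] * v11)
  matrix(out, to$n_rows, to$n_cols, byrow = TRUE)
}

#' Extract predictor values at point locations
#'
#' Returns, for each point, the value of the containing grid cell in every
#' layer (containment semantics, no interpolation: a point anywhere inside a
#' cell gets that cell's value). Points in nodata cells are excluded and
#' counted; points outside the extent are an error naming the point.
#'
#' @param stack An [env_stack()].
#' @param lon,lat Point coordinates (degrees).
#' @return data.frame with `lon`, `lat` and one column per layer; attribute
#'   `n_nodata_excluded` counts points dropped for falling in nodata cells.
#' @export
extract_at_points <- function(stack, lon, lat) {
  stopifnot(inherits(stack, "env_stack"), length(lon) == length(lat))
  idx <- cell_index(stack$spec, lon, lat)
  outside <- which(is.na(idx$row))
  if (length(outside))
    stop(sprintf("point(s) outside the grid extent: %s",
                 paste(sprintf("#%d (%.4f, %.4f)", utils::head(outside, 5),
                               lon[utils::head(outside, 5)],
                               lat[utils::head(outside, 5)]), collapse = "; ")))
  mask <- land_mask(stack)
  on_land <- mask[cbind(idx$row, idx$col)]
  keep <- which(on_land)
  out <- data.frame(lon = lon[keep], lat = lat[keep])
  for (nm in names(stack$layers))
    out[[nm]] <- stack$layers[[nm]][cbind(idx$row[keep], idx$col[keep])]
  attr(out, "n_nodata_excluded") <- sum(!on_land)
  out
}

vif_values <- function(df) {
  vars <- names(df)
  vapply(vars, function(v) {
    fit <- stats::lm(stats::reformulate(setdiff(vars, v), response = v),
                     data = df)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-10) Inf else 1 / (1 - r2)
  }, 0)
}

#' Iterative variance-inflation-factor screening
#'
#' Removes multicollinear predictors before model fitting. At each
#' iteration, VIF_j = 1 / (1 - R2_j) is computed for every retained column
#' (R2_j from an ordinary least-squares regression of column j on all other
#' retained columns; exact collinearity gives infinite VIF). While the
#' largest VIF is at or above the threshold, that column is removed (ties
#' resolve to the later column in input order). The default threshold 5 is
#' the conventional cutoff in distribution modeling.
#'
#' @param table data.frame of numeric predictor columns (more rows than
#'   columns; non-predictor columns such as coordinates should be removed
#'   first).
#' @param threshold VIF threshold (default 5).
#' @return A list of class `vif_report`: `table` (retained columns),
#'   `removed` (names in removal order), `iterations` (per-iteration VIF
#'   data.frames), `threshold`.
#' @export
vif_filter <- function(table, threshold = 5) {
  stopifnot(is.data.frame(table), ncol(table) >= 2L)
  if (!all(vapply(table, is.numeric, TRUE)))
    stop("all predictor columns must be numeric")
  df <- table
  removed <- character()
  iterations <- list()
  repeat {
    if (nrow(df) <= ncol(df))
      stop(sprintf("too few rows (%d) for a VIF computation on %d columns",
                   nrow(df), ncol(df)))
    if (ncol(df) < 2L) break
    v <- vif_values(df)
    iterations[[length(iterations) + 1L]] <-
      data.frame(iteration = length(iterations) + 1L,
                 variable = names(v), vif = unname(v),
                 removed = FALSE)
    if (max(v) < threshold) break
    # ties on the max: drop the later column in input order
    drop_i <- max(which(v == max(v)))
    iterations[[length(iterations)]]$removed[drop_i] <- TRUE
    removed <- c(removed, names(df)[drop_i])
    df <- df[, -drop_i, drop = FALSE]
  }
  structure(list(table = df, removed = removed,
                 iterations = iterations, threshold = threshold),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("<vif_report> retained %d column(s), removed %d (threshold %g)\n",
              ncol(x$table), length(x$removed), x$threshold))
  if (length(x$removed))
    cat("  removal order:", paste(x$removed, collapse = " > "), "\n")
  invisible(x)
}

#' @rdname vif_filter
#' @param report A `vif_report`.
#' @param path Output CSV path.
#' @return `write_vif_report()` writes the per-iteration table
#'   (iteration, variable, vif, removed) and returns the path invisibly.
#' @export
write_vif_report <- function(report, path) {
  stopifnot(inherits(report, "vif_report"))
  tab <- do.call(rbind, report$iterations)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
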