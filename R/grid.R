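#' Georeferenced grid geometry
#'
#' A `grid_spec` describes the geometry shared by every raster layer in an
#' analysis: a north-up, square-celled grid in WGS84 geographic coordinates,
#' anchored at its top-left (north-west) corner. All layers, occurrence
#' thinning, pseudo-absence sampling and area accounting refer to one of
#' these objects, which guarantees co-registration.
#'
#' @param origin_lon Longitude of the top-left corner, decimal degrees.
#' @param origin_lat Latitude of the top-left corner, decimal degrees.
#' @param cell_size Cell edge length in degrees (square cells). The default
#'   0.04 degrees matches the resolution of decadal climate normals commonly
#'   used for regional suitability modeling.
#' @param n_rows,n_cols Grid dimensions (rows count southward from the
#'   origin, columns eastward).
#' @param nodata Sentinel value used when layers are written to disk;
#'   in-memory layers use `NA`.
#' @return An object of class `grid_spec`.
#' @examples
#' spec <- grid_spec(100, 10, cell_size = 0.04, n_rows = 50, n_cols = 50)
#' head(cell_centers(spec))
#' @export
grid_spec <- function(origin_lon, origin_lat, cell_size = 0.04,
                      n_rows, n_cols, nodata = -9999) {
  stopifnot(is.numeric(origin_lon), is.numeric(origin_lat),
            length(origin_lon) == 1L, length(origin_lat) == 1L)
  if (!is.numeric(cell_size) || cell_size <= 0)
    stop("`cell_size` must be a positive number of degrees")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("grid must have at least one row and column")
  south_lat <- origin_lat - n_rows * cell_size
  # all cell centers must stay strictly inside the poles
  if (origin_lat - cell_size / 2 >= 90 || south_lat + cell_size / 2 <= -90)
    stop("cell centers must satisfy |lat| < 90")
  structure(
    list(origin_lon = origin_lon, origin_lat = origin_lat,
         cell_size = cell_size, n_rows = n_rows, n_cols = n_cols,
         crs = "EPSG:4326", nodata = nodata),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g deg, origin (%g, %g), %s\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat, x$crs))
  invisible(x)
}

#' @rdname grid_spec
#' @param spec A `grid_spec`.
#' @return `cell_centers()` returns a data.frame with columns
#'   `row`, `col`, `lon`, `lat` in row-major order.
#' @export
cell_centers <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  row <- rep(seq_len(spec$n_rows), each = spec$n_cols)
  col <- rep(seq_len(spec$n_cols), times = spec$n_rows)
  data.frame(row = row, col = col,
             lon = spec$origin_lon + (col - 0.5) * spec$cell_size,
             lat = spec$origin_lat - (row - 0.5) * spec$cell_size)
}

#' Locate points on a grid
#'
#' Maps lon/lat points to the containing grid cell (containment semantics,
#' no interpolation). Points on the outer boundary of the extent are
#' assigned to the adjacent interior cell, i.e. the extent is treated as
#' closed; points outside get `NA` row/col.
#'
#' @param spec A `grid_spec`.
#' @param lon,lat Numeric vectors of coordinates (degrees).
#' @return data.frame with integer columns `row` and `col` (`NA` outside).
#' @export
cell_index <- function(spec, lon, lat) {
  stopifnot(inherits(spec, "grid_spec"), length(lon) == length(lat))
  east <- spec$origin_lon + spec$n_cols * spec$cell_size
  south <- spec$origin_lat - spec$n_rows * spec$cell_size
  inside <- !is.na(lon) & !is.na(lat) &
    lon >= spec$origin_lon & lon <= east & lat >= south & lat <= spec$origin_lat
  col <- floor((lon - spec$origin_lon) / spec$cell_size) + 1L
  row <- floor((spec$origin_lat - lat) / spec$cell_size) + 1L
  # closed boundary: points exactly on the east/south edge fold inward
  col <- pmin(as.integer(col), spec$n_cols)
  row <- pmin(as.integer(row), spec$n_rows)
  col[!inside] <- NA_integer_; row[!inside] <- NA_integer_
  data.frame(row = row, col = col)
}

#' @rdname grid_spec
#' @param a,b Two `grid_spec` objects.
#' @return `same_grid()` returns TRUE when the two geometries coincide
#'   within floating-point tolerance.
#' @export
same_grid <- function(a, b) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  isTRUE(all.equal(c(a$origin_lon, a$origin_lat, a$cell_size),
                   c(b$origin_lon, b$origin_lat, b$cell_size),
                   tolerance = 1e-9)) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

stop_if_not_conformal <- function(a, b, what = "grids") {
  if (!same_grid(a, b)) stop(sprintf("%s are not conformal", what))
  invisible(TRUE)
}

check_layer_dim <- function(spec, layer, name = "layer") {
  if (!is.matrix(layer) || nrow(layer) != spec$n_rows || ncol(layer) != spec$n_cols)
    stop(sprintf("layer '%s' does not conform to the grid (%d x %d expected)",
                 name, spec$n_rows, spec$n_cols))
  invisible(TRUE)
}

#' Named stack of co-registered predictor layers
#'
#' Bundles one `grid_spec` with an ordered, named list of real-valued
#' matrices (one per predictor). All layers must conform to the grid, and
#' missing (`NA`) cells must coincide across layers so that a single land
#' mask applies to the whole stack.
#'
#' @param spec A `grid_spec`.
#' @param layers Named list of numeric matrices (`n_rows` x `n_cols`).
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(spec, layers) {
  stopifnot(inherits(spec, "grid_spec"), is.list(layers), length(layers) >= 1L)
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("all layers must be named")
  if (anyDuplicated(names(layers))) stop("layer names must be unique")
  for (nm in names(layers)) check_layer_dim(spec, layers[[nm]], nm)
  na0 <- is.na(layers[[1L]])
  for (nm in names(layers)[-1L])
    if (!identical(is.na(layers[[nm]]), na0))
      stop(sprintf("nodata cells of layer '%s' do not coincide with '%s'",
                   nm, names(layers)[1L]))
  structure(list(spec = spec, layers = layers), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layer(s) on a %d x %d grid: %s\n",
              length(x$layers), x$spec$n_rows, x$spec$n_cols,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' @rdname env_stack
#' @param stack An `env_stack`.
#' @return `land_mask()` returns a logical matrix, TRUE where the stack has
#'   data (non-`NA` in every layer).
#' @export
land_mask <- function(stack) {
  stopifnot(inherits(stack, "env_stack"))
  !is.na(stack$layers[[1L]])
}
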