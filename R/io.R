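#' Raster layer file I/O
#'
#' Layers are stored as ESRI ASCII grid (.asc) files: a plain-text,
#' GIS-interchangeable single-band raster format (north-up, square cells,
#' WGS84 coordinates by package convention). Reading and writing go through
#' the sp package. A write-then-read round trip reproduces the grid
#' geometry and values to representation precision.
#'
#' @param layer Numeric matrix conforming to `spec` (`NA` = nodata).
#' @param spec A [grid_spec()].
#' @param path File path (.asc).
#' @return `write_raster_asc()` returns `path` invisibly;
#'   `read_raster_asc()` returns `list(spec =, values =)`.
#' @export
write_raster_asc <- function(layer, spec, path) {
  stopifnot(inherits(spec, "grid_spec"))
  check_layer_dim(spec, layer, "layer")
  cs <- spec$cell_size
  south <- spec$origin_lat - spec$n_rows * cs
  gt <- sp::GridTopology(
    cellcentre.offset = c(spec$origin_lon + cs / 2, south + cs / 2),
    cellsize = c(cs, cs),
    cells.dim = c(spec$n_cols, spec$n_rows))
  # SpatialGridDataFrame stores values row-major from the top-left cell
  sgdf <- sp::SpatialGridDataFrame(sp::SpatialGrid(gt),
                                   data.frame(value = as.vector(t(layer))))
  sp::write.asciigrid(sgdf, path, na.value = spec$nodata)
  invisible(path)
}

#' @rdname write_raster_asc
#' @param nodata Sentinel value to restore on the returned spec.
#' @export
read_raster_asc <- function(path, nodata = -9999) {
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path))
  sgdf <- sp::read.asciigrid(path)
  gp <- sp::gridparameters(sgdf)
  cs <- gp$cellsize[1]
  if (abs(gp$cellsize[1] - gp$cellsize[2]) > 1e-9 * cs)
    stop("non-square cells are not supported")
  n_cols <- gp$cells.dim[1]; n_rows <- gp$cells.dim[2]
  origin_lon <- gp$cellcentre.offset[1] - cs / 2
  origin_lat <- gp$cellcentre.offset[2] - cs / 2 + n_rows * cs
  vals <- sgdf@data[[1]]
  vals[vals == nodata] <- NA_real_
  spec <- grid_spec(origin_lon, origin_lat, cs, n_rows, n_cols, nodata = nodata)
  list(spec = spec, values = matrix(vals, n_rows, n_cols, byrow = TRUE))
}

#' @rdname write_raster_asc
#' @param stack An [env_stack()].
#' @param dir Output directory (one `<layer>.asc` per layer).
#' @export
write_stack_asc <- function(stack, dir) {
  stopifnot(inherits(stack, "env_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(stack$layers))
    write_raster_asc(stack$layers[[nm]], stack$spec,
                     file.path(dir, paste0(nm, ".asc")))
  invisible(dir)
}

#' Occurrence CSV I/O
#'
#' Occurrences are exchanged as CSV with DarwinCore-style columns:
#' `species`, `decimalLongitude`, `decimalLatitude`, `eventDate` (ISO date
#' or year; may be empty), `basisOfRecord`, `source`. Reading validates
#' coordinate bounds and reports offending row numbers.
#'
#' @param path CSV path.
#' @param species Optional species filter.
#' @return `read_occurrences()` returns an [occurrence_set()] (records of
#'   one species; supply `species` when the file holds several).
#' @export
read_occurrences <- function(path, species = NULL) {
  if (!file.exists(path)) stop(sprintf("occurrence file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "decimalLongitude", "decimalLatitude")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("occurrence CSV lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  if (!is.null(species)) df <- df[df$species == species, , drop = FALSE]
  sp_names <- unique(df$species)
  if (length(sp_names) != 1L)
    stop("occurrence CSV must contain exactly one species (use `species =` to select)")
  lon <- suppressWarnings(as.numeric(df$decimalLongitude))
  lat <- suppressWarnings(as.numeric(df$decimalLatitude))
  bad <- which((!is.na(lon) & (lon < -180 | lon > 180)) |
                 (!is.na(lat) & (lat < -90 | lat > 90)))
  if (length(bad))
    stop(sprintf("coordinate(s) out of range at row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  year <- if ("eventDate" %in% names(df))
    suppressWarnings(as.integer(substr(as.character(df$eventDate), 1, 4)))
  else rep(NA_integer_, nrow(df))
  occurrence_set(sp_names,
                 data.frame(lon = lon, lat = lat, event_year = year,
                            basis = if ("basisOfRecord" %in% names(df))
                              df$basisOfRecord else "unknown",
                            source = if ("source" %in% names(df))
                              df$source else "unknown"))
}

#' @rdname read_occurrences
#' @param set An [occurrence_set()].
#' @export
write_occurrences <- function(set, path) {
  stopifnot(inherits(set, "occurrence_set"))
  r <- set$records
  utils::write.csv(
    data.frame(species = set$species,
               decimalLongitude = r$lon, decimalLatitude = r$lat,
               eventDate = ifelse(is.na(r$event_year), "",
                                  sprintf("%d-01-01", r$event_year)),
               basisOfRecord = r$basis, source = r$source),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_occurrences
#' @return `write_provenance()` writes the set's provenance log as JSON.
#' @export
write_provenance <- function(set, path) {
  stopifnot(inherits(set, "occurrence_set"))
  jsonlite::write_json(set$provenance, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Land-cover class-aggregation table I/O
#'
#' The mapping table aggregates raw land-cover class codes into the three
#' analysis categories (`anthropogenic`, `natural`, `other`); CSV columns
#' `code` (integer) and `category`.
#'
#' @param path CSV path.
#' @return data.frame with columns `code` and `category`.
#' @export
read_landcover_mapping <- function(path) {
  if (!file.exists(path)) stop(sprintf("mapping file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("code", "category") %in% names(df)))
    stop("mapping CSV needs columns `code` and `category`")
  bad <- setdiff(unique(df$category), c("anthropogenic", "natural", "other"))
  if (length(bad))
    stop(sprintf("unknown categor%s in mapping: %s",
                 if (length(bad) > 1) "ies" else "y",
                 paste(bad, collapse = ", ")))
  df$code <- as.integer(df$code)
  df
}
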