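#' Occurrence record set
#'
#' Holds the cleaned (or raw) presence records of one species together with
#' a provenance log: every filtering stage appends its name and in/out
#' record counts, so the final dataset documents how it was reduced from the
#' raw sources.
#'
#' @param species Species name; all records in a set share it.
#' @param records data.frame with columns `lon`, `lat` (decimal degrees, may
#'   be `NA` before cleaning), `event_year` (integer or `NA`), `basis`
#'   (e.g. "preserved specimen", "human observation", "fossil") and `source`
#'   (`gbif`, `literature`, `personal` or `synthetic`).
#' @param provenance List of `list(stage, n_in, n_out)` entries.
#' @return An object of class `occurrence_set`.
#' @export
occurrence_set <- function(species, records, provenance = list()) {
  stopifnot(is.character(species), length(species) == 1L, nzchar(species))
  if (missing(records) || is.null(records))
    records <- data.frame(lon = numeric(), lat = numeric(),
                          event_year = integer(), basis = character(),
                          source = character())
  stopifnot(is.data.frame(records))
  for (col in c("lon", "lat")) if (!col %in% names(records))
    stop(sprintf("records must have a '%s' column", col))
  if (!"event_year" %in% names(records)) records$event_year <- NA_integer_
  if (!"basis" %in% names(records)) records$basis <- "unknown"
  if (!"source" %in% names(records)) records$source <- "unknown"
  ok_lon <- is.na(records$lon) | (records$lon >= -180 & records$lon <= 180)
  ok_lat <- is.na(records$lat) | (records$lat >= -90 & records$lat <= 90)
  if (!all(ok_lon & ok_lat)) {
    bad <- which(!(ok_lon & ok_lat))
    stop(sprintf("coordinates out of range at record(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  rownames(records) <- NULL
  structure(list(species = species, records = records, provenance = provenance),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %s: %d record(s), %d provenance stage(s)\n",
              x$species, nrow(x$records), length(x$provenance)))
  invisible(x)
}

#' @rdname occurrence_set
#' @param x An `occurrence_set`.
#' @return `n_records()` returns the record count.
#' @export
n_records <- function(x) {
  stopifnot(inherits(x, "occurrence_set"))
  nrow(x$records)
}

log_stage <- function(set, stage, n_in, n_out) {
  if (n_out > n_in) stop("provenance violation: stage cannot add records")
  set$provenance <- c(set$provenance,
                      list(list(stage = stage, n_in = n_in, n_out = n_out)))
  set
}

#' Clean raw occurrence records
#'
#' Applies the standard vetting filters for repository-derived occurrence
#' data: drops records lacking coordinates, fossil specimens, records dated
#' before `min_year`, and exact duplicates (same coordinates, year and
#' basis; first kept). Records with an unknown year are retained. Each
#' sub-filter is logged in the provenance.
#'
#' @param raw An [occurrence_set()].
#' @param min_year Earliest acceptable collection year (default 1800).
#' @return A cleaned `occurrence_set` (possibly empty).
#' @export
clean_records <- function(raw, min_year = 1800) {
  stopifnot(inherits(raw, "occurrence_set"))
  set <- raw
  r <- set$records

  keep <- !is.na(r$lon) & !is.na(r$lat)
  set <- log_stage(set, "drop_missing_coordinates", nrow(r), sum(keep))
  r <- r[keep, , drop = FALSE]

  keep <- !grepl("fossil", r$basis, ignore.case = TRUE)
  set <- log_stage(set, "drop_fossil_specimens", nrow(r), sum(keep))
  r <- r[keep, , drop = FALSE]

  keep <- is.na(r$event_year) | r$event_year >= min_year
  set <- log_stage(set, sprintf("drop_pre_%d_records", min_year),
                   nrow(r), sum(keep))
  r <- r[keep, , drop = FALSE]

  keep <- !duplicated(r[, c("lon", "lat", "event_year", "basis")])
  set <- log_stage(set, "drop_exact_duplicates", nrow(r), sum(keep))
  r <- r[keep, , drop = FALSE]

  occurrence_set(set$species, r, set$provenance)
}

#' Restrict records to a study extent
#'
#' Retains records whose point falls inside the extent. The extent may be a
#' [grid_spec()] (bounding-box test, boundary points retained) or an
#' [env_stack()] (additionally requires the containing cell to be
#' non-nodata, i.e. terrestrial).
#'
#' @param set An [occurrence_set()] with coordinates.
#' @param extent A `grid_spec` or `env_stack`.
#' @return The filtered `occurrence_set`.
#' @export
filter_extent <- function(set, extent) {
  stopifnot(inherits(set, "occurrence_set"))
  r <- set$records
  if (inherits(extent, "env_stack")) {
    spec <- extent$spec
    idx <- cell_index(spec, r$lon, r$lat)
    mask <- land_mask(extent)
    keep <- !is.na(idx$row) & mask[cbind(idx$row, idx$col)]
    keep[is.na(keep)] <- FALSE
  } else if (inherits(extent, "grid_spec")) {
    idx <- cell_index(extent, r$lon, r$lat)
    keep <- !is.na(idx$row)
  } else stop("`extent` must be a grid_spec or env_stack")
  set <- log_stage(set, "filter_extent", nrow(r), sum(keep))
  occurrence_set(set$species, r[keep, , drop = FALSE], set$provenance)
}

#' Thin records to one per grid cell
#'
#' Retains at most one record per cell of the modeling grid, removing
#' pixel-level clustering that would otherwise inflate apparent model
#' performance. Within a cell the earliest-dated record wins (unknown years
#' sort last); remaining ties resolve to the first record in stable input
#' order, so thinning is fully deterministic.
#'
#' @param set An [occurrence_set()] with coordinates.
#' @param spec The thinning [grid_spec()] (normally the modeling grid).
#' @return The thinned `occurrence_set`, records in original input order.
#' @export
thin_to_grid <- function(set, spec) {
  stopifnot(inherits(set, "occurrence_set"), inherits(spec, "grid_spec"))
  r <- set$records
  if (nrow(r) == 0L) return(log_stage(set, "thin_to_grid", 0L, 0L))
  if (anyNA(r$lon) || anyNA(r$lat))
    stop("thin_to_grid requires coordinates on every record")
  idx <- cell_index(spec, r$lon, r$lat)
  cell <- (idx$row - 1L) * spec$n_cols + idx$col  # NA for outside points
  year <- ifelse(is.na(r$event_year), Inf, r$event_year)
  ord <- order(cell, year, seq_len(nrow(r)))
  first <- ord[!duplicated(cell[ord]) & !is.na(cell[ord])]
  keep <- sort(first)                              # restore input order
  set <- log_stage(set, "thin_to_grid", nrow(r), length(keep))
  occurrence_set(set$species, r[keep, , drop = FALSE], set$provenance)
}

#' Merge occurrence sets from several sources
#'
#' Takes the union of records across sources (e.g. repository, literature
#' and personal observations), then thins to the grid so cells observed by
#' several sources contribute one record. Per-source input counts are kept
#' in the provenance.
#'
#' @param sets List of [occurrence_set()] objects sharing one species.
#' @param spec The thinning [grid_spec()].
#' @return The merged, thinned `occurrence_set`.
#' @export
merge_sources <- function(sets, spec) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  for (s in sets) stopifnot(inherits(s, "occurrence_set"))
  sp <- unique(vapply(sets, function(s) s$species, ""))
  if (length(sp) != 1L)
    stop(sprintf("sets name different species: %s", paste(sp, collapse = ", ")))
  rec <- do.call(rbind, lapply(sets, function(s) s$records))
  prov <- list(list(stage = "merge_sources",
                    n_in = sum(vapply(sets, n_records, 0L)),
                    n_out = nrow(rec),
                    per_source = lapply(sets, function(s)
                      list(n = n_records(s),
                           sources = unique(s$records$source)))))
  merged <- occurrence_set(sp, rec, prov)
  thin_to_grid(merged, spec)
}
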