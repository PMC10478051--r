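#' Generate a unit-square tract lattice
#'
#' Builds `n_rows * n_cols` unit-square census-tract stand-ins with
#' deterministic GEOID-style identifiers (`sprintf("%03d%03d", row, col)`,
#' 1-based). Cell (r, c) occupies `[c-1, c] x [r-1, r]` in planar
#' coordinates; real tract GeoJSON is accepted by the same downstream
#' readers.
#'
#' @param config a [synth_config()].
#' @return a `data.table` of class `tract_geoms` with columns `tract_id`,
#'   `ring` (list of closed 5x2 coordinate matrices), `centroid_x`,
#'   `centroid_y`.
#' @export
generate_lattice <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  grid <- CJ(row_id = seq_len(config$n_rows), col_id = seq_len(config$n_cols))
  geoms <- grid[, .(
    tract_id = sprintf("%03d%03d", row_id, col_id),
    row_id, col_id,
    centroid_x = col_id - 0.5, centroid_y = row_id - 0.5)]
  geoms[, ring := Map(function(r, c) {
    matrix(c(c - 1, r - 1,  c, r - 1,  c, r,  c - 1, r,  c - 1, r - 1),
           ncol = 2L, byrow = TRUE)
  }, row_id, col_id)]
  setcolorder(geoms, c("tract_id", "row_id", "col_id",
                       "centroid_x", "centroid_y", "ring"))
  setattr(geoms, "class", c("tract_geoms", class(geoms)))
  geoms[]
}

#' Write tract geometries as GeoJSON
#'
#' Emits an RFC 7946 FeatureCollection, one Polygon Feature per tract with a
#' `tract_id` property.
#'
#' @param geoms a `tract_geoms` table (see [generate_lattice()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tracts_geojson <- function(geoms, path) {
  features <- Map(function(id, ring) {
    list(type = "Feature",
         properties = list(tract_id = id),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(
                           seq_len(nrow(ring)),
                           function(i) as.numeric(ring[i, ])))))
  }, geoms$tract_id, geoms$ring)
  names(features) <- NULL
  fc <- list(type = "FeatureCollection", features = features)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read tract geometries from GeoJSON
#'
#' Accepts a FeatureCollection of Polygons (or MultiPolygons, from which the
#' first outer ring is taken) carrying a `tract_id` property; returns the
#' same `tract_geoms` structure [generate_lattice()] produces. Centroids are
#' ring-vertex means, sufficient for distance-band weights on near-convex
#' tracts.
#'
#' @param path GeoJSON file path.
#' @return a `tract_geoms` data.table.
#' @export
read_tracts_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  rows <- lapply(fc$features, function(f) {
    id <- f$properties$tract_id
    if (is.null(id)) stop("feature without tract_id property", call. = FALSE)
    g <- f$geometry
    ring_raw <- switch(g$type,
      Polygon = g$coordinates[[1]],
      MultiPolygon = g$coordinates[[1]][[1]],
      stop("unsupported geometry type: ", g$type, call. = FALSE))
    ring <- do.call(rbind, lapply(ring_raw, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    list(tract_id = as.character(id), ring = ring,
         centroid_x = mean(ring[-nrow(ring), 1]),
         centroid_y = mean(ring[-nrow(ring), 2]))
  })
  geoms <- data.table(
    tract_id = vapply(rows, `[[`, character(1), "tract_id"),
    centroid_x = vapply(rows, `[[`, numeric(1), "centroid_x"),
    centroid_y = vapply(rows, `[[`, numeric(1), "centroid_y"),
    ring = lapply(rows, `[[`, "ring"))
  if (anyDuplicated(geoms$tract_id))
    stop("duplicate tract_id in GeoJSON", call. = FALSE)
  setattr(geoms, "class", c("tract_geoms", class(geoms)))
  geoms[]
}
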