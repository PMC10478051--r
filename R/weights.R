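#' Build spatial weights for Gi* hot-spot analysis
#'
#' Two schemes, both with self-inclusion (w_ii = 1, the Gi* convention) and
#' binary weights:
#' \describe{
#'   \item{queen}{polygons sharing at least one boundary vertex are
#'     neighbours (exact for lattices and for boundary files whose shared
#'     borders share vertices; coordinates are rounded to 1e-8 before
#'     matching).}
#'   \item{distance_band}{centroids within `band_distance` are neighbours;
#'     the default band is the smallest distance guaranteeing every tract at
#'     least one non-self neighbour (max-min centroid spacing).}
#' }
#'
#' @param geoms a `tract_geoms` table ([generate_lattice()] /
#'   [read_tracts_geojson()]).
#' @param scheme `"queen"` or `"distance_band"`.
#' @param band_distance optional numeric band for the distance scheme.
#' @return object of class `spatial_weights`: list with `ids`, `neighbours`
#'   (list of integer indices including self), `weights` (parallel list),
#'   `scheme`, `isolates` (ids with no non-self neighbour, also warned
#'   about).
#' @export
build_weights <- function(geoms, scheme = c("queen", "distance_band"),
                          band_distance = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(geoms, "tract_geoms"))
  n <- nrow(geoms)
  if (n < 2L) stop("need at least two tracts; statistic undefined",
                   call. = FALSE)
  ids <- geoms$tract_id

  if (scheme == "queen") {
    # vertex-sharing: map rounded vertex keys to the tracts touching them
    keys <- lapply(geoms$ring, function(r) {
      r <- r[-nrow(r), , drop = FALSE]  # drop closing vertex
      unique(paste(round(r[, 1], 8), round(r[, 2], 8)))
    })
    vert <- data.table(vkey = unlist(keys),
                       idx = rep(seq_len(n), lengths(keys)))
    pairs <- vert[, if (.N > 1L) {
      g <- expand.grid(i = idx, j = idx)
      g[g$i != g$j, ]
    }, by = vkey][, .(i, j)]
    pairs <- unique(pairs)
    nbr <- split(pairs$j, factor(pairs$i, levels = seq_len(n)))
    neighbours <- lapply(seq_len(n), function(i)
      sort(unique(c(i, nbr[[i]]))))
  } else {
    d <- as.matrix(stats::dist(cbind(geoms$centroid_x, geoms$centroid_y)))
    if (is.null(band_distance)) {
      diag(d) <- Inf
      band_distance <- max(apply(d, 1L, min))
      diag(d) <- 0
    }
    neighbours <- lapply(seq_len(n), function(i)
      which(d[i, ] <= band_distance))
  }

  isolates <- ids[lengths(neighbours) == 1L]
  if (length(isolates))
    warning(length(isolates), " tract(s) have no non-self neighbour: ",
            paste(head(isolates, 5L), collapse = ", "), call. = FALSE)
  structure(list(ids = ids, neighbours = neighbours,
                 weights = lapply(neighbours, function(x) rep(1, length(x))),
                 scheme = scheme, band_distance = band_distance,
                 isolates = isolates),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("spatial_weights:", length(x$ids), "tracts,", x$scheme, "scheme,",
      "mean neighbours", round(mean(lengths(x$neighbours)), 2), "\n")
  invisible(x)
}
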