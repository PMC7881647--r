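## Vector geometries (water bodies, admin polygons) are consumed from GeoJSON.
## GeoJSON is plain JSON, so jsonlite is the parser; coordinates are assumed
## already projected to planar km (the package works in an azimuthal
## equidistant plane centred on the study domain throughout).

#' Read features from a GeoJSON file
#'
#' Supports `Polygon`, `MultiPolygon` and `LineString` geometries inside a
#' `FeatureCollection` (or a bare geometry / single `Feature`).  Returns a
#' list of features, each a list with `id`, `properties`, and `rings` — a list
#' of two-column coordinate matrices (for polygons, ring 1 is the outer ring;
#' holes are not supported and are treated as additional outer rings).
#'
#' @param path path to a GeoJSON file with planar-km coordinates.
#' @return list of feature lists.
#' @export
read_geojson_features <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- switch(g$type %||% "",
    FeatureCollection = g$features,
    Feature = list(g),
    list(list(type = "Feature", properties = list(), geometry = g)))
  out <- vector("list", length(feats))
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, coords_to_matrix),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(p) lapply(p, coords_to_matrix)),
                            recursive = FALSE),
      LineString = list(coords_to_matrix(geom$coordinates)),
      stop("unsupported geometry type: ", geom$type))
    out[[k]] <- list(
      id = f$id %||% f$properties$id %||% k,
      type = geom$type,
      properties = f$properties %||% list(),
      rings = rings)
  }
  out
}

coords_to_matrix <- function(cc) {
  m <- do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
  storage.mode(m) <- "double"
  m
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' @param pts two-column matrix of points (km).
#' @param ring two-column matrix of polygon vertices (closed or open ring).
#' @return logical vector; boundary points count as inside.
#' @export
point_in_ring <- function(pts, ring) {
  pts <- rbind(pts)
  if (nrow(ring) > 1 &&
      all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  vapply(seq_len(nrow(pts)), function(i) {
    px <- pts[i, 1]; py <- pts[i, 2]
    # boundary check first: distance to any edge == 0
    if (min(point_segment_distance(px, py, xs, ys, xe, ye)) < 1e-12) return(TRUE)
    crosses <- ((ys > py) != (ye > py)) &
      (px < (xe - xs) * (py - ys) / (ye - ys) + xs)
    sum(crosses) %% 2L == 1L
  }, logical(1))
}

## vectorized distance from one point to many segments
point_segment_distance <- function(px, py, xs, ys, xe, ye) {
  dx <- xe - xs; dy <- ye - ys
  len2 <- dx^2 + dy^2
  t <- ifelse(len2 == 0, 0, pmin(1, pmax(0, ((px - xs) * dx + (py - ys) * dy) / len2)))
  sqrt((px - (xs + t * dx))^2 + (py - (ys + t * dy))^2)
}

#' Distance from points to a feature set
#'
#' Euclidean distance (km) to the nearest feature boundary; points strictly
#' inside a polygon feature have distance 0.
#'
#' @param pts two-column matrix of points (km).
#' @param features feature list as returned by [read_geojson_features()], or a
#'   list of two-column coordinate matrices.
#' @return numeric vector of distances, one per point.
#' @export
distance_to_features <- function(pts, features) {
  if (length(features) == 0) stop("empty geometry set", call. = FALSE)
  pts <- rbind(pts)
  # normalize to list(list(rings=..., type=...))
  if (is.matrix(features[[1]]))
    features <- lapply(features, function(m) list(rings = list(m), type = "LineString"))
  vapply(seq_len(nrow(pts)), function(i) {
    px <- pts[i, 1]; py <- pts[i, 2]
    d <- Inf
    for (f in features) {
      polygonal <- f$type %in% c("Polygon", "MultiPolygon")
      for (ring in f$rings) {
        if (polygonal && point_in_ring(cbind(px, py), ring)) return(0)
        n <- nrow(ring)
        if (n == 1) { d <- min(d, sqrt((px - ring[1,1])^2 + (py - ring[1,2])^2)); next }
        last <- if (polygonal) c(2:n, 1) else 2:n
        first <- if (polygonal) 1:n else 1:(n - 1)
        d <- min(d, min(point_segment_distance(px, py, ring[first, 1], ring[first, 2],
                                               ring[last, 1], ring[last, 2])))
      }
    }
    d
  }, numeric(1))
}
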