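# Polygons are represented in the polyclip convention: a polygon is a list of
# rings, each ring a list(x = <numeric>, y = <numeric>) of vertices in WGS84
# decimal degrees (planar degree space). Multi-part results keep one ring per
# part; holes carry opposite orientation so signed areas compose.

#' Construct a single-ring polygon
#'
#' @param x,y Vertex coordinates (lon, lat), not closed (first vertex is not
#'   repeated).
#' @return A polygon: list of one ring.
#' @export
polygon_ring <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  list(list(x = as.numeric(x), y = as.numeric(y)))
}

ring_signed_area <- function(r) {
  x <- r$x; y <- r$y
  j <- c(length(x), seq_len(length(x) - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

ring_centroid <- function(r) {
  x <- r$x; y <- r$y
  j <- c(length(x), seq_len(length(x) - 1L))
  cross <- x[j] * y - x * y[j]
  a <- sum(cross) / 2
  if (a == 0) return(c(mean(x), mean(y)))
  c(sum((x[j] + x) * cross) / (6 * a), sum((y[j] + y) * cross) / (6 * a))
}

#' Polygon area in planar degree space
#'
#' Shoelace (Green's theorem) area summed over rings; rings oriented opposite
#' to the outer boundary (holes) subtract.
#'
#' @param poly A polygon (list of rings).
#' @return Area in square degrees (non-negative for well-oriented input).
#' @export
polygon_area <- function(poly) {
  abs(sum(vapply(poly, ring_signed_area, numeric(1))))
}

#' Area-weighted planar centroid of a (multi-part) polygon
#'
#' Green's-theorem centroid per ring, combined with signed-area weights, so
#' holes subtract correctly and multi-part polygons are weighted by part area.
#'
#' @param poly A polygon (list of rings) in lon/lat degrees.
#' @return Named numeric `c(lon, lat)`.
#' @export
polygon_centroid <- function(poly) {
  if (!length(poly)) stopf("empty polygon")
  areas <- vapply(poly, ring_signed_area, numeric(1))
  total <- sum(areas)
  if (abs(total) < 1e-12) stopf("degenerate zero-area polygon")
  cents <- vapply(poly, ring_centroid, numeric(2))
  c(lon = sum(cents[1, ] * areas) / total,
    lat = sum(cents[2, ] * areas) / total)
}

#' Buffered union of polygons
#'
#' Unions the input polygons and dilates the result by `buffer_deg` degrees in
#' planar degree space with round joins (Minkowski sum with a disc). The 1 to
#' 3 degree range is the documented expansion band for hotspot polygons; a
#' buffer outside it triggers a warning (or an error under `strict`).
#' Optionally clips the result against a mask polygon (e.g. a sea mask).
#'
#' @param polygons A polygon or a (possibly named) list of polygons.
#' @param buffer_deg Dilation radius in degrees.
#' @param clip Optional mask polygon to intersect with.
#' @param strict If `TRUE`, a buffer outside \[1, 3\] degrees is an error
#'   instead of a warning.
#' @return A polygon (list of rings, possibly multi-part) with attribute
#'   `buffer_deg`.
#' @export
buffered_union <- function(polygons, buffer_deg = 1, clip = NULL, strict = FALSE) {
  if (is_polygon(polygons)) polygons <- list(polygons)
  polygons <- polygons[lengths(polygons) > 0L]
  if (!length(polygons)) stopf("empty geometry list")
  if (buffer_deg < 1 || buffer_deg > 3) {
    msg <- sprintf("buffer %.3g degrees is outside the documented [1, 3] degree range",
                   buffer_deg)
    if (strict) stopf("%s", msg) else warning(msg, call. = FALSE)
  }
  u <- Reduce(function(a, b) polyclip::polyclip(a, b, op = "union"), polygons)
  out <- if (buffer_deg > 0) {
    polyclip::polyoffset(u, buffer_deg, jointype = "round",
                         arctol = abs(buffer_deg) / 1000)
  } else {
    u
  }
  if (!is.null(clip)) out <- polyclip::polyclip(out, clip, op = "intersection")
  if (!length(out)) stopf("buffered union is empty (clip removed all geometry?)")
  structure(out, buffer_deg = buffer_deg)
}

is_polygon <- function(p) {
  is.list(p) && length(p) > 0 && is.list(p[[1]]) &&
    !is.null(p[[1]]$x) && !is.null(p[[1]]$y)
}

#' Number of outer parts of a polygon
#'
#' Counts positively-oriented rings, i.e. connected components (holes are
#' negatively oriented and not counted).
#'
#' @param poly A polygon (list of rings).
#' @return Integer part count.
#' @export
polygon_parts <- function(poly) {
  sum(vapply(poly, ring_signed_area, numeric(1)) > 0)
}

#' Read region polygons from GeoJSON
#'
#' Loads a GeoJSON FeatureCollection of Polygon/MultiPolygon features keyed by
#' a country-code property, as used for EEZ layers. The packaged default is a
#' deliberately coarse synthetic stand-in for the Mediterranean EEZs, adequate
#' for tests and examples; pass real Marine Regions GeoJSON for faithful
#' geometry.
#'
#' @param path GeoJSON path; default the packaged synthetic EEZ layer.
#' @param key Property naming the country code (default `"country"`).
#' @return Named list of polygons (lists of rings).
#' @export
read_region_polygons <- function(path = NULL, key = "country") {
  path <- path %||% system.file("extdata", "med_eez_synthetic.geojson",
                                package = "nismomentum", mustWork = TRUE)
  if (!file.exists(path)) stopf("GeoJSON file not found: %s", path)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) stopf("expected a GeoJSON FeatureCollection")
  out <- list()
  for (f in gj$features) {
    code <- f$properties[[key]]
    if (is.null(code)) stopf("feature without a '%s' property", key)
    g <- f$geometry
    rings <- switch(
      g$type,
      Polygon = lapply(g$coordinates, coords_to_ring),
      MultiPolygon = unlist(lapply(g$coordinates,
                                   function(pg) lapply(pg, coords_to_ring)),
                            recursive = FALSE),
      stopf("unsupported geometry type '%s' for feature '%s'", g$type, code)
    )
    out[[code]] <- rings
  }
  out
}

coords_to_ring <- function(coords) {
  x <- vapply(coords, function(p) as.numeric(p[[1]]), numeric(1))
  y <- vapply(coords, function(p) as.numeric(p[[2]]), numeric(1))
  n <- length(x)
  if (n > 1 && x[1] == x[n] && y[1] == y[n]) {  # drop GeoJSON ring closure
    x <- x[-n]; y <- y[-n]
  }
  list(x = x, y = y)
}

ring_to_coords <- function(r) {
  n <- length(r$x)
  idx <- c(seq_len(n), 1L)  # GeoJSON rings are closed
  lapply(idx, function(i) c(r$x[i], r$y[i]))
}

geojson_feature <- function(geometry, properties) {
  list(type = "Feature", properties = properties, geometry = geometry)
}

polygon_geometry <- function(poly) {
  # every ring emitted as its own Polygon part; adequate for hole-free layers
  if (length(poly) == 1L) {
    list(type = "Polygon", coordinates = list(ring_to_coords(poly[[1]])))
  } else {
    list(type = "MultiPolygon",
         coordinates = lapply(poly, function(r) list(ring_to_coords(r))))
  }
}

write_feature_collection <- function(features, path) {
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
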