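#' Dominant hotspot selection at one momentum
#'
#' Ranks the countries recorded at a momentum by species count (ties broken
#' alphabetically by code) and selects the minimal prefix whose cumulative
#' share of that momentum's records strictly exceeds `threshold` percent:
#' the dominant hotspot of introductions at that momentum.
#'
#' @param heatmap A country-level `momentum_heatmap` (see [heatmap_counts()]).
#' @param momentum_index Momentum column to select from (0-based).
#' @param threshold Cumulative share threshold in percent (default 50).
#' @return A `hotspot_selection`: list with `momentum`, `ranked` (data frame
#'   `country`, `count`, `share_pct`, `cumulative_pct`), `selected` (country
#'   codes) and `cumulative_share_pct`.
#' @export
select_dominant_hotspot <- function(heatmap, momentum_index, threshold = 50) {
  stopifnot(inherits(heatmap, "momentum_heatmap"))
  if (!identical(attr(heatmap, "level"), "country")) {
    stopf("dominant hotspots are selected on a country-level heatmap")
  }
  col <- paste0("t", momentum_index)
  if (!col %in% colnames(heatmap)) stopf("momentum t%d not tabulated", momentum_index)
  counts <- heatmap[, col]
  counts <- counts[counts > 0]
  total <- sum(counts)
  if (total == 0L) stopf("no records at momentum t%d", momentum_index)

  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  share <- 100 * counts / total
  cum <- cumsum(share)
  n_sel <- which(cum > threshold)[1]
  ranked <- data.frame(country = names(counts), count = as.integer(counts),
                       share_pct = as.numeric(share), cumulative_pct = as.numeric(cum),
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(
    list(momentum = as.integer(momentum_index),
         ranked = ranked,
         selected = ranked$country[seq_len(n_sel)],
         cumulative_share_pct = cum[[n_sel]],
         threshold = threshold),
    class = "hotspot_selection"
  )
}

#' @export
print.hotspot_selection <- function(x, ...) {
  cat(sprintf("dominant hotspot at t%d (> %g%%): %s (%.1f%% of %d records)\n",
              x$momentum, x$threshold, paste(x$selected, collapse = ", "),
              x$cumulative_share_pct, sum(x$ranked$count)))
  invisible(x)
}

#' Trajectory entry point
#'
#' The inferred origin of every spread trajectory. The default is the
#' Mediterranean mouth of the Suez Canal near Port Said; the location must
#' fall within the Mediterranean basin's bounding box.
#'
#' @param name Label for the entry point.
#' @param lon,lat Coordinates in decimal degrees WGS84.
#' @return An `entry_point` list with `name`, `lon`, `lat`.
#' @export
entry_point <- function(name = "Suez Canal", lon = 32.32, lat = 31.28) {
  if (lon < -6 || lon > 37 || lat < 30 || lat > 46) {
    stopf("entry point (%g, %g) is outside the Mediterranean bounding box", lon, lat)
  }
  structure(list(name = name, lon = lon, lat = lat), class = "entry_point")
}

#' Per-momentum hotspot polygons and centroids
#'
#' For each momentum with records, selects the dominant hotspot countries,
#' unions their region polygons dilated by the buffer, and takes the planar
#' area-weighted centroid.
#'
#' @param heatmap Country-level `momentum_heatmap`.
#' @param polygons Named list of per-country polygons
#'   (see [read_region_polygons()]).
#' @param buffer_deg Buffer in degrees, scalar or one value per momentum
#'   (recycled); each value should lie in the 1 to 3 degree band.
#' @param threshold Hotspot share threshold in percent.
#' @param clip Optional mask polygon intersected with every hotspot polygon.
#' @return List of `trajectory_point`s, one per populated momentum, each with
#'   `momentum`, `countries`, `polygon`, `centroid` (lon/lat), `buffer_deg`.
#' @export
trajectory_points <- function(heatmap, polygons, buffer_deg = 1,
                              threshold = 50, clip = NULL) {
  stopifnot(inherits(heatmap, "momentum_heatmap"))
  max_m <- attr(heatmap, "max_momentum")
  populated <- which(colSums(heatmap) > 0) - 1L
  buffer_deg <- rep_len(buffer_deg, length(populated))
  out <- vector("list", length(populated))
  for (i in seq_along(populated)) {
    m <- populated[i]
    sel <- select_dominant_hotspot(heatmap, m, threshold = threshold)
    missing <- setdiff(sel$selected, names(polygons))
    if (length(missing)) {
      stopf("no polygon for selected hotspot country(ies): %s",
            paste(missing, collapse = ", "))
    }
    poly <- buffered_union(polygons[sel$selected], buffer_deg = buffer_deg[i],
                           clip = clip)
    out[[i]] <- structure(
      list(momentum = m, countries = sel$selected, polygon = poly,
           centroid = polygon_centroid(poly), buffer_deg = buffer_deg[i]),
      class = "trajectory_point"
    )
  }
  out
}

#' Entry-point-anchored spread trajectory
#'
#' Aligns the per-momentum hotspot centroids into the ordered polyline that
#' starts at the entry point and visits the centroid of every successive
#' momentum: `entry, t0, t1, ..., t_max`. Momentum indices must be
#' consecutive from 0.
#'
#' @param points List of `trajectory_point`s (see [trajectory_points()]),
#'   sorted by momentum.
#' @param entry An [entry_point()].
#' @return A `spread_trajectory` data frame with one vertex per row:
#'   `label`, `momentum` (`NA` for the entry vertex), `lon`, `lat`,
#'   `buffer_deg`; attributes `entry` and `points`.
#' @export
build_trajectory <- function(points, entry = entry_point()) {
  stopifnot(inherits(entry, "entry_point"), length(points) >= 1)
  momenta <- vapply(points, `[[`, numeric(1), "momentum")
  if (!identical(as.integer(momenta), seq_along(momenta) - 1L)) {
    stopf("momentum indices must be consecutive from 0, got: %s",
          paste(momenta, collapse = ", "))
  }
  cents <- t(vapply(points, `[[`, numeric(2), "centroid"))
  out <- data.frame(
    label = c(entry$name, paste0("t", momenta)),
    momentum = c(NA_integer_, as.integer(momenta)),
    lon = c(entry$lon, cents[, 1]),
    lat = c(entry$lat, cents[, 2]),
    buffer_deg = c(NA_real_, vapply(points, `[[`, numeric(1), "buffer_deg")),
    stringsAsFactors = FALSE
  )
  structure(out, entry = entry, points = points,
            class = c("spread_trajectory", "data.frame"))
}

#' @export
print.spread_trajectory <- function(x, ...) {
  cat(sprintf("spread trajectory: %d vertices (%s -> t%d)\n",
              nrow(x), attr(x, "entry")$name, max(x$momentum, na.rm = TRUE)))
  print(as.data.frame(x))
  invisible(x)
}

#' Write a trajectory (and its hotspot polygons) as GeoJSON
#'
#' Emits a FeatureCollection holding the trajectory LineString, one Point per
#' vertex, and one (Multi)Polygon per momentum hotspot, each tagged with its
#' momentum and buffer in the feature properties. Output is deterministic:
#' identical inputs produce byte-identical files.
#'
#' @param trajectory A `spread_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_geojson <- function(trajectory, path) {
  feats <- list(geojson_feature(
    list(type = "LineString",
         coordinates = lapply(seq_len(nrow(trajectory)),
                              function(i) c(trajectory$lon[i], trajectory$lat[i]))),
    list(role = "trajectory")
  ))
  for (i in seq_len(nrow(trajectory))) {
    feats <- c(feats, list(geojson_feature(
      list(type = "Point", coordinates = c(trajectory$lon[i], trajectory$lat[i])),
      list(role = "vertex", label = trajectory$label[i],
           momentum = trajectory$momentum[i])
    )))
  }
  for (pt in attr(trajectory, "points")) {
    feats <- c(feats, list(geojson_feature(
      polygon_geometry(pt$polygon),
      list(role = "hotspot", momentum = pt$momentum,
           countries = paste(pt$countries, collapse = ","),
           buffer_deg = pt$buffer_deg)
    )))
  }
  write_feature_collection(feats, path)
}
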