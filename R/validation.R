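#' Georeferenced point track of one invasive species
#'
#' Wraps a species' georeferenced records (year, lon, lat), with an explicit
#' exclusions list for records removed before analysis (e.g. an isolated early
#' sighting judged a non-successful invasion attempt). Exclusions are applied
#' by year and recorded, never silently dropped.
#'
#' @param species Species name.
#' @param points Data frame with columns `year`, `lon`, `lat`.
#' @param exclusions Optional data frame with columns `year`, `reason`.
#' @return A `point_track` list with `species`, `points`, `exclusions`.
#' @export
point_track <- function(species, points, exclusions = NULL) {
  stopifnot(all(c("year", "lon", "lat") %in% names(points)))
  if (!is.null(exclusions)) {
    stopifnot(all(c("year", "reason") %in% names(exclusions)))
    points <- points[!points$year %in% exclusions$year, , drop = FALSE]
  }
  if (!nrow(points)) stopf("no points remain after exclusions for %s", species)
  points <- points[order(points$year), , drop = FALSE]
  rownames(points) <- NULL
  structure(list(species = species, points = points,
                 exclusions = exclusions %||%
                   data.frame(year = integer(0), reason = character(0))),
            class = "point_track")
}

#' Read point tracks from CSV
#'
#' @param path CSV with columns `species`, `year`, `lon`, `lat`.
#' @param exclusions_path Optional CSV with columns `species`, `year`,
#'   `reason`.
#' @return Named list of `point_track`s.
#' @export
read_point_tracks <- function(path, exclusions_path = NULL) {
  if (!file.exists(path)) stopf("point-record file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "year", "lon", "lat") %in% names(df)))
  excl <- if (!is.null(exclusions_path)) {
    utils::read.csv(exclusions_path, stringsAsFactors = FALSE)
  }
  species <- unique(df$species)
  stats::setNames(lapply(species, function(sp) {
    ex <- if (!is.null(excl)) excl[excl$species == sp, c("year", "reason"), drop = FALSE]
    point_track(sp, df[df$species == sp, c("year", "lon", "lat")],
                exclusions = if (!is.null(ex) && nrow(ex)) ex)
  }), species)
}

#' Actual duration of invasive activity
#'
#' Inclusive year count between the first and last year of recorded activity;
#' a single-year presence counts as 1 year.
#'
#' @param first_year,last_year Integer years, `last_year >= first_year`.
#' @return Duration in years.
#' @export
actual_duration <- function(first_year, last_year) {
  if (last_year < first_year) stopf("last_year precedes first_year")
  as.integer(last_year - first_year + 1)
}

#' Annual and moving-average centroids of a point track
#'
#' Annual centroid = arithmetic mean of (lon, lat) over the points of each
#' year with records. The moving-average centroid at year y is the mean of
#' the annual centroids over the trailing window of up to `window` available
#' record-years ending at y (or, with `align = "centered"`, the window of
#' available years centred on y).
#'
#' @param track A [point_track()].
#' @param window Window length in record-years (default 5).
#' @param align `"trailing"` (default) or `"centered"`.
#' @return List of two data frames, `annual` and `moving` (columns `year`,
#'   `lon`, `lat`).
#' @export
windowed_centroids <- function(track, window = 5L, align = c("trailing", "centered")) {
  align <- match.arg(align)
  stopifnot(inherits(track, "point_track"), window >= 1)
  pts <- track$points
  years <- sort(unique(pts$year))
  annual <- data.frame(
    year = years,
    lon = vapply(years, function(y) mean(pts$lon[pts$year == y]), numeric(1)),
    lat = vapply(years, function(y) mean(pts$lat[pts$year == y]), numeric(1))
  )
  n <- nrow(annual)
  idx <- function(i) {
    if (align == "trailing") {
      seq(max(1L, i - window + 1L), i)
    } else {
      half <- (window - 1L) %/% 2L
      seq(max(1L, i - half), min(n, i + half))
    }
  }
  moving <- annual
  for (i in seq_len(n)) {
    w <- idx(i)
    moving$lon[i] <- mean(annual$lon[w])
    moving$lat[i] <- mean(annual$lat[w])
  }
  list(annual = annual, moving = moving)
}

#' Match an endmost centroid to a trajectory momentum
#'
#' Returns the momentum whose trajectory centroid is nearest to the species'
#' endmost centroid under great-circle (haversine) distance; ties resolve to
#' the lower momentum.
#'
#' @param endmost Numeric `c(lon, lat)`.
#' @param trajectory A `spread_trajectory` (see [build_trajectory()]).
#' @return Integer momentum index.
#' @export
match_endmost_to_momentum <- function(endmost, trajectory) {
  stopifnot(inherits(trajectory, "spread_trajectory"))
  cand <- trajectory[!is.na(trajectory$momentum), , drop = FALSE]
  if (!nrow(cand)) stopf("trajectory has no momentum vertices")
  d <- geosphere::distHaversine(matrix(endmost, ncol = 2),
                                as.matrix(cand[, c("lon", "lat")]))
  cand$momentum[which.min(d)]  # which.min takes the first (lowest) on ties
}

#' Inferred duration of invasive activity at a momentum
#'
#' Reads the cumulative median spread curve at the matched momentum: the
#' cumulative eCDF-median years from entry through that momentum's transition.
#'
#' @param momentum_index Matched momentum (>= 1).
#' @param curve A `cumulative_curve` (all-records scenario, by convention).
#' @return Years (possibly fractional).
#' @export
inferred_duration <- function(momentum_index, curve) {
  stopifnot(inherits(curve, "cumulative_curve"))
  if (momentum_index == 0) return(0)  # still at the entry momentum
  row <- match(momentum_index, curve$step)
  if (is.na(row)) stopf("curve does not cover momentum transition %d", momentum_index)
  curve$cumulative[row]
}

#' Temporal validation percentage
#'
#' Agreement between a species' actual spread duration and the
#' momentum-inferred duration, as `100 * min(a, b) / max(a, b)`. The score is
#' symmetric, equals 100 only for exact agreement, and reproduces the
#' published validation arithmetic exactly (15 vs 13.5 -> 90;
#' 17 vs 19.5 -> 87.2; 19 vs 13.5 -> 71 at integer precision).
#'
#' @param actual,inferred Positive durations in years.
#' @return Percentage in (0, 100].
#' @export
temporal_validation <- function(actual, inferred) {
  if (actual <= 0 || inferred <= 0) stopf("durations must be positive")
  100 * min(actual, inferred) / max(actual, inferred)
}

#' Render a percentage at report precision
#'
#' One decimal, with a trailing `.0` dropped (so 90.0 prints as 90).
#'
#' @param x Percentage.
#' @return Character scalar.
#' @export
format_percent <- function(x) {
  if (is.na(x)) return("NA")
  r <- round(x, 1)
  if (r == round(r)) sprintf("%d", as.integer(round(r))) else sprintf("%.1f", r)
}

#' Trajectory verdict for a species track
#'
#' Tests whether a species' moving-average centroid sequence exhibits the
#' basin-scale northwest drift of the inferred spread trajectory. The default
#' rule is a sign test on the net displacement from the first to the endmost
#' moving-average centroid: validated iff net delta-latitude > 0 (northward)
#' and net delta-longitude < 0 (westward). An angular-sector alternative
#' accepts any net bearing inside `sector` (degrees clockwise from north).
#' Per-step initial bearings (great-circle) are returned as diagnostics.
#'
#' @param centroids Data frame of moving-average centroids (`year`, `lon`,
#'   `lat`), at least two rows.
#' @param rule `"sign"` (default) or `"sector"`.
#' @param sector Numeric `c(from, to)` bearing window in degrees, used when
#'   `rule = "sector"`; a window crossing north (from > to) is allowed.
#' @return List with `validated` (logical), `net_dlon`, `net_dlat`,
#'   `net_bearing_deg`, and `step_bearings_deg`.
#' @export
trajectory_verdict <- function(centroids, rule = c("sign", "sector"),
                               sector = c(270, 360)) {
  rule <- match.arg(rule)
  if (nrow(centroids) < 2L) stopf("need at least two moving-average centroids")
  first <- c(centroids$lon[1], centroids$lat[1])
  last <- c(centroids$lon[nrow(centroids)], centroids$lat[nrow(centroids)])
  net_dlon <- last[1] - first[1]
  net_dlat <- last[2] - first[2]
  bearing <- geosphere::bearing(first, last) %% 360
  validated <- if (rule == "sign") {
    net_dlat > 0 && net_dlon < 0
  } else if (sector[1] <= sector[2]) {
    bearing >= sector[1] && bearing < sector[2]
  } else {
    bearing >= sector[1] || bearing < sector[2]
  }
  steps <- if (nrow(centroids) > 2L) {
    p <- as.matrix(centroids[, c("lon", "lat")])
    geosphere::bearing(p[-nrow(p), , drop = FALSE], p[-1, , drop = FALSE]) %% 360
  } else {
    bearing
  }
  list(validated = validated, net_dlon = net_dlon, net_dlat = net_dlat,
       net_bearing_deg = bearing, step_bearings_deg = steps)
}

#' Full species-level validation report
#'
#' Runs the ground-truth procedure for one species: annual and moving-average
#' centroids, endmost-centroid matching against the inferred trajectory,
#' inferred vs. actual duration, the temporal validation percentage, and the
#' trajectory verdict.
#'
#' @param track A [point_track()].
#' @param trajectory A `spread_trajectory`.
#' @param curve A `cumulative_curve` (all-records scenario).
#' @param window Moving-average window in record-years (default 5).
#' @param ... Passed on to [trajectory_verdict()].
#' @return A `validation_report` list: `species`, `actual_duration`,
#'   `matched_momentum`, `inferred_duration`, `temporal_validation_pct`,
#'   `trajectory_validated`, `endmost_centroid`, `centroids`, `verdict`.
#' @export
validate_species <- function(track, trajectory, curve, window = 5L, ...) {
  cents <- windowed_centroids(track, window = window)
  endmost <- c(cents$moving$lon[nrow(cents$moving)],
               cents$moving$lat[nrow(cents$moving)])
  matched <- match_endmost_to_momentum(endmost, trajectory)
  actual <- actual_duration(min(track$points$year), max(track$points$year))
  inferred <- inferred_duration(matched, curve)
  verdict <- trajectory_verdict(cents$moving, ...)
  structure(
    list(species = track$species,
         actual_duration = actual,
         matched_momentum = matched,
         inferred_duration = inferred,
         temporal_validation_pct = if (inferred > 0) {
           temporal_validation(actual, inferred)
         } else {
           NA_real_  # track never left the entry momentum
         },
         trajectory_validated = verdict$validated,
         endmost_centroid = c(lon = endmost[1], lat = endmost[2]),
         centroids = cents,
         verdict = verdict),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "%s: actual %d y, matched t%d, inferred %.4g y, temporal validation %s%%, trajectory %s\n",
    x$species, x$actual_duration, x$matched_momentum, x$inferred_duration,
    format_percent(x$temporal_validation_pct),
    if (x$trajectory_validated) "validated" else "not validated"))
  invisible(x)
}
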