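# Step-interval distributions are given as tagged lists:
#   list(kind = "fixed", k = 3)
#   list(kind = "geometric", p = 0.4)        # support {0, 1, 2, ...}
#   list(kind = "table", values = 0:3, probs = c(.1, .4, .3, .2))
# Zero-year gaps are legal everywhere: a species may be first-recorded in two
# countries within the same year.

draw_interval <- function(dist, n) {
  switch(
    dist$kind,
    fixed = {
      if (!is_count(dist$k) || dist$k < 0) stopf("fixed interval `k` must be an integer >= 0")
      rep(as.integer(dist$k), n)
    },
    geometric = {
      if (!is.numeric(dist$p) || dist$p <= 0 || dist$p > 1) {
        stopf("geometric interval `p` must be in (0, 1]")
      }
      stats::rgeom(n, dist$p)
    },
    table = {
      if (length(dist$values) != length(dist$probs) || any(dist$probs < 0) ||
          sum(dist$probs) <= 0) {
        stopf("interval table needs matching `values`/`probs` with non-negative probs")
      }
      sample(as.integer(dist$values), n, replace = TRUE, prob = dist$probs)
    },
    stopf("unknown interval distribution kind '%s'", dist$kind %||% "<missing>")
  )
}

#' Median of a step-interval distribution
#'
#' Closed-form median of the generator's interval distributions, used as the
#' ground truth in parameter-recovery checks.
#'
#' @param dist Tagged distribution list (see [spread_config()]).
#' @return The distribution median.
#' @export
interval_median <- function(dist) {
  switch(
    dist$kind,
    fixed = dist$k,
    geometric = stats::qgeom(0.5, dist$p),
    table = {
      ord <- order(dist$values)
      v <- dist$values[ord]
      cdf <- cumsum(dist$probs[ord]) / sum(dist$probs)
      v[which(cdf >= 0.5)[1]]
    },
    stopf("unknown interval distribution kind '%s'", dist$kind %||% "<missing>")
  )
}

#' Configuration for the synthetic spread generator
#'
#' Describes a stepping-stone spread process: every species enters at
#' `entry_region` in a uniform random year of `entry_year_range`, then
#' advances east-to-west along `region_chain`, one new country per momentum,
#' with year gaps drawn i.i.d. from `step_interval`. `max_steps` caps the
#' number of momenta per species (scalar, or one value per species to plant a
#' known establishment fraction); the chain length is a hard cap. An optional
#' `detect_lag` distribution adds an independent per-record reporting delay.
#'
#' @param n_species Number of species to simulate.
#' @param region_chain Ordered country codes, entry first.
#' @param entry_region Entry country (must head the chain).
#' @param entry_year_range Inclusive year bounds for the entry year.
#' @param step_interval Tagged interval distribution (see above).
#' @param max_steps Momenta per species (recycled to `n_species`).
#' @param detect_lag Optional tagged distribution for detection lag, or
#'   `NULL` (default: no lag).
#' @param seed Mandatory integer seed; generation is fully deterministic.
#' @return A `spread_config` list.
#' @export
spread_config <- function(n_species,
                          region_chain,
                          entry_region = region_chain[1],
                          entry_year_range = c(1950L, 1990L),
                          step_interval = list(kind = "geometric", p = 0.4),
                          max_steps = length(region_chain),
                          detect_lag = NULL,
                          seed) {
  if (missing(seed)) stopf("`seed` is mandatory for the spread generator")
  if (!is_count(n_species) || n_species < 1) stopf("`n_species` must be a positive integer")
  if (!length(region_chain)) stopf("`region_chain` must be non-empty")
  if (!entry_region %in% region_chain) stopf("`entry_region` must be in `region_chain`")
  if (entry_region != region_chain[1]) {
    stopf("`entry_region` must be the first element of `region_chain`")
  }
  if (entry_year_range[1] > entry_year_range[2]) stopf("invalid `entry_year_range`")
  max_steps <- rep_len(as.integer(max_steps), n_species)
  if (any(max_steps < 1)) stopf("`max_steps` must be >= 1")
  draw_interval(step_interval, 0)  # validate parameters eagerly
  if (!is.null(detect_lag)) draw_interval(detect_lag, 0)
  structure(
    list(n_species = as.integer(n_species),
         region_chain = as.character(region_chain),
         entry_region = entry_region,
         entry_year_range = as.integer(entry_year_range),
         step_interval = step_interval,
         max_steps = max_steps,
         detect_lag = detect_lag,
         seed = as.integer(seed)),
    class = "spread_config"
  )
}

#' Generate a synthetic detection-record table with known ground truth
#'
#' Simulates the spread process described by a [spread_config()] and emits a
#' record table in the same CSV dialect the reader consumes, plus the ground
#' truth (true momentum sequences, true step intervals, true establishment
#' flags). Identical config and seed give identical output.
#'
#' @param config A [spread_config()].
#' @return List with `records` (data frame `species`, `year`, `country`) and
#'   `truth` (list with per-species `series`, `intervals`, `established`, and
#'   a `config` echo).
#' @export
generate_spread_dataset <- function(config) {
  stopifnot(inherits(config, "spread_config"))
  with_seed(config$seed, {
    chain_cap <- length(config$region_chain)
    rows <- vector("list", config$n_species)
    series <- vector("list", config$n_species)
    intervals <- vector("list", config$n_species)
    ids <- sprintf("sp%04d", seq_len(config$n_species))
    for (i in seq_len(config$n_species)) {
      n_steps <- min(config$max_steps[i], chain_cap)
      pool <- config$entry_year_range[1]:config$entry_year_range[2]
      entry_year <- pool[sample.int(length(pool), 1L)]
      gaps <- if (n_steps > 1L) draw_interval(config$step_interval, n_steps - 1L) else integer(0)
      years <- entry_year + c(0L, cumsum(gaps))
      countries <- config$region_chain[seq_len(n_steps)]
      obs_years <- years
      if (!is.null(config$detect_lag)) {
        obs_years <- years + draw_interval(config$detect_lag, n_steps)
      }
      rows[[i]] <- data.frame(species = ids[i], year = obs_years,
                              country = countries, stringsAsFactors = FALSE)
      series[[i]] <- data.frame(momentum = seq_len(n_steps) - 1L,
                                country = countries, year = years,
                                stringsAsFactors = FALSE)
      intervals[[i]] <- gaps
    }
    records <- do.call(rbind, rows)
    rownames(records) <- NULL
    list(records = records,
         truth = list(series = stats::setNames(series, ids),
                      intervals = stats::setNames(intervals, ids),
                      established = stats::setNames(
                        vapply(series, nrow, integer(1)) >= 3L, ids),
                      config = config))
  })
}

#' Generate a synthetic georeferenced point track with linear drift
#'
#' Emits yearly Gaussian point clouds whose true centroid drifts linearly:
#' the year-y cloud is centred on `start + (y - start_year) * drift` with
#' isotropic scatter. The ground-truth endmost centroid is
#' `start + (n_years - 1) * drift`. A zero scatter gives annual centroids
#' exactly on the drift line.
#'
#' @param n_years Number of consecutive years (>= 2).
#' @param start Numeric `c(lon, lat)` of the first-year centroid.
#' @param drift Numeric `c(dlon, dlat)` per-year drift.
#' @param scatter Isotropic per-point standard deviation in degrees (>= 0).
#' @param points_per_year Points per annual cloud.
#' @param start_year First calendar year.
#' @param species Track label.
#' @param seed Mandatory integer seed.
#' @return List with `track` (a [point_track()]) and `truth` (`endmost`
#'   centroid, `annual_centroids`, config echo).
#' @export
generate_point_track <- function(n_years, start, drift, scatter = 0.2,
                                 points_per_year = 20L, start_year = 2000L,
                                 species = "synthetic_ias", seed) {
  if (missing(seed)) stopf("`seed` is mandatory for the track generator")
  if (!is_count(n_years) || n_years < 2) stopf("`n_years` must be an integer >= 2")
  if (scatter < 0) stopf("`scatter` must be >= 0")
  if (!is_count(points_per_year) || points_per_year < 1) {
    stopf("`points_per_year` must be a positive integer")
  }
  with_seed(seed, {
    years <- start_year + seq_len(n_years) - 1L
    truth_cent <- data.frame(
      year = years,
      lon = start[1] + (seq_len(n_years) - 1L) * drift[1],
      lat = start[2] + (seq_len(n_years) - 1L) * drift[2]
    )
    pts <- do.call(rbind, lapply(seq_len(n_years), function(i) {
      data.frame(year = years[i],
                 lon = truth_cent$lon[i] + stats::rnorm(points_per_year, 0, scatter),
                 lat = truth_cent$lat[i] + stats::rnorm(points_per_year, 0, scatter))
    }))
    list(track = point_track(species, pts),
         truth = list(endmost = c(lon = truth_cent$lon[n_years],
                                  lat = truth_cent$lat[n_years]),
                      annual_centroids = truth_cent,
                      drift = drift, scatter = scatter,
                      points_per_year = points_per_year, seed = seed))
  })
}
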