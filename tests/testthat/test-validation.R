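test_that("actual duration counts both endpoint years inclusively", {
  expect_equal(actual_duration(2008, 2022), 15L)
  expect_equal(actual_duration(2003, 2019), 17L)
  expect_equal(actual_duration(2000, 2018), 19L)
  expect_equal(actual_duration(2010, 2010), 1L)
  expect_error(actual_duration(2010, 2009), "precedes")
})

test_that("annual and moving-average centroids follow the direct mean oracle", {
  trk <- point_track("x", data.frame(year = c(2000, 2000),
                                     lon = c(30, 34), lat = c(32, 36)))
  cents <- windowed_centroids(trk)
  expect_equal(cents$annual$lon, 32)
  expect_equal(cents$annual$lat, 34)

  # five years of drifting annual lons; trailing window of 5 ends at the mean
  trk5 <- point_track("x", data.frame(year = 2000:2004, lon = 30:34, lat = 31))
  c5 <- windowed_centroids(trk5, window = 5)
  expect_equal(c5$moving$lon[5], 32)
  expect_equal(c5$moving$lon[1:4], c(30, 30.5, 31, 31.5))  # shorter head windows
  # constant annual centroids: moving average equals the constant
  trkc <- point_track("x", data.frame(year = 2000:2005, lon = 25, lat = 33))
  expect_equal(windowed_centroids(trkc)$moving$lon, rep(25, 6))
  # window = 1 reduces to the annual centroids
  expect_equal(windowed_centroids(trk5, window = 1)$moving, c5$annual)
})

test_that("exclusions are applied explicitly, never silently", {
  trk <- point_track("pm",
                     data.frame(year = c(1991, 2008:2010),
                                lon = c(35, 34, 33.5, 33), lat = c(32, 32, 33, 34)),
                     exclusions = data.frame(year = 1991,
                                             reason = "isolated early record"))
  expect_equal(min(trk$points$year), 2008)
  expect_equal(trk$exclusions$year, 1991)
  expect_error(point_track("x", data.frame(year = 2000, lon = 1, lat = 1),
                           exclusions = data.frame(year = 2000, reason = "r")),
               "no points remain")
})

test_that("endmost centroid matches the nearest trajectory momentum, ties to lower", {
  series <- make_series(rep(paste0("s", 1:3), each = 4),
                        rep(c("IL", "TR", "GR", "TN"), 3),
                        rep(c(1950, 1953, 1957, 1961), 3))
  hm <- heatmap_counts(series, "country", rt)
  traj <- build_trajectory(trajectory_points(hm, read_region_polygons()),
                           entry_point())
  cents <- traj[!is.na(traj$momentum), ]
  # exactly on a centroid
  expect_equal(match_endmost_to_momentum(c(cents$lon[4], cents$lat[4]), traj), 3L)
  # exact tie: two momenta share one centroid; the lower index wins
  lons <- c(30.5, 32.5, 32.5, 36.5)
  pts <- lapply(0:3, function(m) {
    structure(list(momentum = m, countries = "IL",
                   polygon = unit_square(lons[m + 1] - 0.5, 34),
                   centroid = c(lon = lons[m + 1], lat = 34.5), buffer_deg = 1),
              class = "trajectory_point")
  })
  ttraj <- build_trajectory(pts, entry_point())
  expect_equal(match_endmost_to_momentum(c(32.5, 34.5), ttraj), 1L)
  # planted nearest index recovered by exhaustive scan
  for (k in c(0, 3)) {
    target <- c(lons[k + 1] + 0.3, 34.5)
    d <- geosphere::distHaversine(matrix(target, ncol = 2), cbind(lons, 34.5))
    expect_equal(match_endmost_to_momentum(target, ttraj), which.min(d) - 1L)
  }
})

test_that("inferred duration reads the cumulative curve at the matched momentum", {
  curve <- cumulative_median_curve(make_series(
    rep(c("a", "b"), each = 4),
    rep(c("IL", "TR", "GR", "LY"), 2),
    c(1950, 1954, 1956, 1960, 1950, 1954, 1957, 1959)), "all")
  expect_equal(curve$cumulative, c(4, 6.5, 9.5))
  expect_equal(inferred_duration(2, curve), 6.5)
  expect_equal(inferred_duration(3, curve), 9.5)
  expect_equal(inferred_duration(0, curve), 0)
  expect_error(inferred_duration(7, curve), "cover")
})

test_that("temporal validation reproduces the published arithmetic and its properties", {
  expect_equal(temporal_validation(15, 13.5), 90)
  expect_equal(round(temporal_validation(17, 19.5), 1), 87.2)
  expect_equal(round(temporal_validation(19, 13.5)), 71)
  expect_equal(temporal_validation(12, 12), 100)
  expect_error(temporal_validation(0, 5), "positive")

  set.seed(71)
  for (i in 1:25) {
    a <- runif(1, 1, 40); b <- runif(1, 1, 40)
    expect_equal(temporal_validation(a, b), temporal_validation(b, a))  # symmetry
    expect_lte(temporal_validation(a, b), 100)
  }
  # monotone: moving inferred toward actual never decreases the score
  scores <- vapply(seq(5, 20, by = 0.5), temporal_validation, numeric(1), actual = 20)
  expect_true(all(diff(scores) >= 0))

  expect_equal(format_percent(temporal_validation(15, 13.5)), "90")
  expect_equal(format_percent(temporal_validation(17, 19.5)), "87.2")
  expect_equal(format_percent(temporal_validation(19, 13.5)), "71.1")
})

test_that("trajectory verdict detects the planted northwest drift", {
  nw <- data.frame(year = 2000:2004, lon = seq(33, 26, length.out = 5),
                   lat = seq(31.5, 36, length.out = 5))
  v <- trajectory_verdict(nw)
  expect_true(v$validated)
  expect_lt(v$net_dlon, 0)
  expect_gt(v$net_dlat, 0)
  expect_true(v$net_bearing_deg > 270 && v$net_bearing_deg < 360)

  se <- data.frame(year = 2000:2002, lon = c(26, 28, 30), lat = c(36, 34, 33))
  expect_false(trajectory_verdict(se)$validated)
  expect_true(trajectory_verdict(se, rule = "sector", sector = c(90, 180))$validated)
  expect_error(trajectory_verdict(nw[1, ]), "at least two")

  # generator-planted drift recovered end to end
  g <- generate_point_track(8, start = c(34, 31.5), drift = c(-0.6, 0.4),
                            scatter = 0.05, points_per_year = 40, seed = 13)
  cents <- windowed_centroids(g$track)$moving
  expect_true(trajectory_verdict(cents)$validated)
})

test_that("validate_species assembles the full report", {
  series <- make_series(rep(paste0("s", 1:3), each = 4),
                        rep(c("IL", "TR", "GR", "TN"), 3),
                        rep(c(1950, 1953, 1957, 1961), 3))
  hm <- heatmap_counts(series, "country", rt)
  traj <- build_trajectory(trajectory_points(hm, read_region_polygons()),
                           entry_point())
  curve <- cumulative_median_curve(series, "all")
  g <- generate_point_track(10, start = c(34.5, 32), drift = c(-0.9, 0.6),
                            scatter = 0.1, points_per_year = 25, seed = 17)
  rep <- validate_species(g$track, traj, curve)
  expect_s3_class(rep, "validation_report")
  expect_equal(rep$actual_duration, 10L)
  expect_true(rep$matched_momentum %in% 0:3)
  expect_true(rep$trajectory_validated)
  if (rep$matched_momentum >= 1) {
    expect_equal(rep$inferred_duration, curve$cumulative[rep$matched_momentum])
    expect_equal(rep$temporal_validation_pct,
                 temporal_validation(10, rep$inferred_duration))
  }
})
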