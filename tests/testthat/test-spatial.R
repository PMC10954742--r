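test_that("dominant hotspot is the minimal prefix strictly above the threshold", {
  # a controlled t0 column: 63 IL, 37 TR, 30 GR (total 130)
  series <- make_series(paste0("s", 1:130),
                        rep(c("IL", "TR", "GR"), c(63, 37, 30)),
                        rep(1950, 130))
  hm <- heatmap_counts(series, "country", rt)
  sel <- select_dominant_hotspot(hm, 0)
  expect_equal(sel$ranked$country, c("IL", "TR", "GR"))
  expect_equal(round(sel$ranked$share_pct[1], 1), 48.5)
  expect_equal(sel$selected, c("IL", "TR"))
  expect_equal(round(sel$cumulative_share_pct, 1), 76.9)

  # 51/49: the leader alone suffices
  hm2 <- heatmap_counts(make_series(paste0("s", 1:100),
                                    rep(c("IL", "TR"), c(51, 49)),
                                    rep(1950, 100)), "country", rt)
  expect_equal(select_dominant_hotspot(hm2, 0)$selected, "IL")

  # 50/50 boundary: strict > 50 needs both; alphabetical tie order
  hm3 <- heatmap_counts(make_series(paste0("s", 1:100),
                                    rep(c("TR", "IL"), c(50, 50)),
                                    rep(1950, 100)), "country", rt)
  sel3 <- select_dominant_hotspot(hm3, 0)
  expect_equal(sel3$ranked$country, c("IL", "TR"))
  expect_equal(sel3$selected, c("IL", "TR"))

  expect_error(select_dominant_hotspot(hm, 5), "no records")
  expect_error(select_dominant_hotspot(heatmap_counts(series, "msfd", rt), 0),
               "country-level")
})

test_that("hotspot minimality: dropping the last selected country falls to or below 50%", {
  set.seed(61)
  codes <- names(rt$countries)
  for (i in 1:60) {
    n_c <- sample(2:10, 1)
    counts <- sample(1:40, n_c, replace = TRUE)
    cc <- sample(codes, n_c)
    series <- make_series(paste0("s", seq_len(sum(counts))),
                          rep(cc, counts), rep(1950, sum(counts)))
    sel <- select_dominant_hotspot(heatmap_counts(series, "country", rt), 0)
    total <- sum(counts)
    sel_counts <- sel$ranked$count[match(sel$selected, sel$ranked$country)]
    expect_gt(sum(sel_counts) / total, 0.5)
    expect_lte((sum(sel_counts) - sel_counts[length(sel_counts)]) / total, 0.5)
    # exhaustive prefix scan oracle
    shares <- cumsum(sel$ranked$count) / total
    expect_equal(length(sel$selected), which(shares > 0.5)[1])
  }
})

test_that("trajectory has entry + one vertex per momentum, and rejects gaps", {
  series <- make_series(rep(paste0("s", 1:4), each = 3),
                        rep(c("IL", "TR", "GR"), 4),
                        rep(c(1950, 1953, 1956), 4))
  hm <- heatmap_counts(series, "country", rt)
  polys <- read_region_polygons()
  pts <- trajectory_points(hm, polys, buffer_deg = 1)
  traj <- build_trajectory(pts, entry_point())
  expect_s3_class(traj, "spread_trajectory")
  expect_equal(nrow(traj), length(pts) + 1L)   # momenta + 1 vertices
  expect_equal(traj$label[1], "Suez Canal")
  expect_equal(traj$momentum[-1], 0:(length(pts) - 1L))
  # centroid of each hotspot lies inside its polygon's bounding box
  for (p in pts) {
    bx <- range(unlist(lapply(p$polygon, `[[`, "x")))
    by <- range(unlist(lapply(p$polygon, `[[`, "y")))
    expect_true(p$centroid[["lon"]] >= bx[1] && p$centroid[["lon"]] <= bx[2])
    expect_true(p$centroid[["lat"]] >= by[1] && p$centroid[["lat"]] <= by[2])
  }
  expect_error(build_trajectory(pts[c(1, 3)], entry_point()), "consecutive")
  expect_error(entry_point(lon = 120, lat = 10), "bounding box")
})

test_that("synthetic westward spread yields a westward-drifting trajectory", {
  chain <- c("IL", "CY", "GR", "MT", "TN", "DZ", "ES")  # east to west
  cfg <- spread_config(n_species = 25, region_chain = chain,
                       step_interval = list(kind = "fixed", k = 2), seed = 9)
  sim <- generate_spread_dataset(cfg)
  series <- momentum_table(clean_detection_records(sim$records, rt)$records, rt)
  hm <- heatmap_counts(series, "country", rt)
  traj <- build_trajectory(trajectory_points(hm, read_region_polygons()),
                           entry_point())
  lon <- traj$lon[!is.na(traj$momentum)]
  # all species move strictly along the east-to-west chain
  expect_true(all(diff(lon) < 0))
})

test_that("trajectory GeoJSON output is byte-identical across reruns", {
  series <- make_series(rep(paste0("s", 1:3), each = 2),
                        rep(c("IL", "TR"), 3), rep(c(1950, 1952), 3))
  hm <- heatmap_counts(series, "country", rt)
  traj <- build_trajectory(trajectory_points(hm, read_region_polygons()),
                           entry_point())
  f1 <- withr::local_tempfile(fileext = ".geojson")
  f2 <- withr::local_tempfile(fileext = ".geojson")
  write_trajectory_geojson(traj, f1)
  write_trajectory_geojson(traj, f2)
  expect_identical(readLines(f1), readLines(f2))
  gj <- jsonlite::read_json(f1)
  expect_equal(gj$type, "FeatureCollection")
  roles <- vapply(gj$features, function(f) f$properties$role, "")
  expect_equal(sum(roles == "vertex"), nrow(traj))
  expect_equal(sum(roles == "hotspot"), nrow(traj) - 1L)
})
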