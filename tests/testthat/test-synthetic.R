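test_that("fixed-interval spread produces the exact stepping-stone records", {
  cfg <- spread_config(n_species = 1, region_chain = c("IL", "TR", "GR"),
                       entry_year_range = c(2000L, 2000L),
                       step_interval = list(kind = "fixed", k = 3),
                       max_steps = 3, seed = 1)
  sim <- generate_spread_dataset(cfg)
  expect_equal(sim$records$year, c(2000L, 2003L, 2006L))
  expect_equal(sim$records$country, c("IL", "TR", "GR"))
  expect_true(sim$truth$established[["sp0001"]])
})

test_that("generation is deterministic under config + seed and leaves the RNG alone", {
  cfg <- spread_config(n_species = 15, region_chain = c("IL", "TR", "GR", "LY"),
                       seed = 99)
  a <- generate_spread_dataset(cfg)
  set.seed(12345); before <- runif(3)
  set.seed(12345)
  b <- generate_spread_dataset(cfg)
  after <- runif(3)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$series, b$truth$series)
  expect_identical(before, after)  # caller's RNG stream untouched
  # different seed, different draw
  c <- generate_spread_dataset(spread_config(n_species = 15,
                                             region_chain = c("IL", "TR", "GR", "LY"),
                                             seed = 100))
  expect_false(identical(a$records$year, c$records$year))
})

test_that("config validation rejects impossible setups", {
  expect_error(spread_config(n_species = 5, region_chain = c("IL", "TR")),
               "seed")
  expect_error(spread_config(n_species = 5, region_chain = character(0), seed = 1),
               "non-empty")
  expect_error(spread_config(n_species = 5, region_chain = c("IL", "TR"),
                             entry_region = "TR", seed = 1), "first element")
  expect_error(spread_config(n_species = 5, region_chain = "IL",
                             step_interval = list(kind = "geometric", p = 1.5),
                             seed = 1), "in \\(0, 1\\]")
  expect_error(spread_config(n_species = 5, region_chain = "IL",
                             step_interval = list(kind = "bogus"), seed = 1),
               "unknown interval")
})

test_that("ground truth matches the emitted records through the full pipeline", {
  cfg <- spread_config(n_species = 60, region_chain = c("IL", "LB", "CY", "TR", "GR"),
                       max_steps = rep(c(5L, 2L), c(45, 15)), seed = 7)
  sim <- generate_spread_dataset(cfg)
  series <- momentum_table(clean_detection_records(sim$records, rt)$records, rt)
  # momentum sequences recovered exactly (no lag configured)
  for (sp in names(series)) {
    expect_equal(series[[sp]]$country, sim$truth$series[[sp]]$country)
    expect_equal(series[[sp]]$year, sim$truth$series[[sp]]$year)
  }
  # establishment flags recovered exactly: 45/60 configured
  expect_equal(unname(classify_established(series)),
               unname(sim$truth$established))
  expect_equal(mean(classify_established(series)), 0.75)
  # entry region is the dominant hotspot at t0 for a shared entry
  hm <- heatmap_counts(series, "country", rt)
  expect_equal(select_dominant_hotspot(hm, 0)$selected, "IL")
})

test_that("detection lag shifts observed years without breaking cleaning", {
  cfg <- spread_config(n_species = 10, region_chain = c("IL", "TR", "GR"),
                       step_interval = list(kind = "fixed", k = 2),
                       detect_lag = list(kind = "fixed", k = 1), seed = 3)
  sim <- generate_spread_dataset(cfg)
  truth_years <- unlist(lapply(sim$truth$series, `[[`, "year"), use.names = FALSE)
  expect_equal(sim$records$year, truth_years + 1L)
})

test_that("point tracks drift linearly with centroids near truth", {
  # zero scatter: annual centroids exactly on the drift line
  g0 <- generate_point_track(5, start = c(34, 31), drift = c(-0.5, 0.3),
                             scatter = 0, points_per_year = 3, seed = 2)
  cents <- windowed_centroids(g0$track)$annual
  expect_equal(cents$lon, g0$truth$annual_centroids$lon)
  expect_equal(cents$lat, g0$truth$annual_centroids$lat)

  # zero drift: endmost centroid equals the start
  gz <- generate_point_track(4, start = c(30, 35), drift = c(0, 0),
                             scatter = 0, points_per_year = 2, seed = 2)
  expect_equal(unname(gz$truth$endmost), c(30, 35))

  # scatter: estimated annual centroid within 3 standard errors of truth
  gs <- generate_point_track(6, start = c(33, 32), drift = c(-0.4, 0.25),
                             scatter = 0.2, points_per_year = 200, seed = 8)
  est <- windowed_centroids(gs$track)$annual
  se3 <- 3 * 0.2 / sqrt(200)
  expect_true(all(abs(est$lon - gs$truth$annual_centroids$lon) < se3))
  expect_true(all(abs(est$lat - gs$truth$annual_centroids$lat) < se3))

  expect_error(generate_point_track(1, c(0, 0), c(0, 0), seed = 1), ">= 2")
  expect_error(generate_point_track(3, c(0, 0), c(0, 0), scatter = -1, seed = 1),
               "scatter")
})
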