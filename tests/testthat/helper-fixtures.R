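# Shared fixtures, built in code.

rt <- nismomentum::region_table()

# Build a cleaned record data frame from parallel vectors.
make_records <- function(species, country, year, lon = NA_real_, lat = NA_real_) {
  df <- data.frame(species = species, country = country, year = as.integer(year),
                   lon = lon, lat = lat, stringsAsFactors = FALSE)
  nismomentum::clean_detection_records(df, rt)$records
}

# Momentum series list straight from vectors.
make_series <- function(species, country, year) {
  nismomentum::momentum_table(make_records(species, country, year), rt)
}

# Write a CSV and return its path.
write_tmp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Random simple (star-shaped, non-self-intersecting) polygon around a centre.
rand_simple_polygon <- function(n = 8, centre = c(0, 0), rmin = 0.5, rmax = 2) {
  theta <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rmin, rmax)
  nismomentum::polygon_ring(centre[1] + r * cos(theta), centre[2] + r * sin(theta))
}

# Independent shoelace / Green's-theorem centroid for a single ring.
shoelace_centroid <- function(ring) {
  x <- ring$x; y <- ring$y
  n <- length(x)
  x2 <- c(x, x[1]); y2 <- c(y, y[1])
  cross <- x2[-(n + 1)] * y2[-1] - x2[-1] * y2[-(n + 1)]
  a <- sum(cross) / 2
  c(sum((x2[-(n + 1)] + x2[-1]) * cross) / (6 * a),
    sum((y2[-(n + 1)] + y2[-1]) * cross) / (6 * a))
}

unit_square <- function(x0 = 0, y0 = 0, side = 1) {
  nismomentum::polygon_ring(c(x0, x0 + side, x0 + side, x0),
                            c(y0, y0, y0 + side, y0 + side))
}

# Country-level heatmap with a single t0 column, straight from a named
# count vector.
make_heatmap_t0 <- function(counts) {
  m <- matrix(as.integer(counts), ncol = 1,
              dimnames = list(names(counts), "t0"))
  structure(m, level = "country", max_momentum = 0L,
            class = c("momentum_heatmap", "matrix"))
}

example_records_path <- function() {
  system.file("extdata", "example_records_synthetic.csv",
              package = "nismomentum", mustWork = TRUE)
}
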