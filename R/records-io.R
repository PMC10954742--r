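#' Read and clean NIS detection records
#'
#' Parses a CSV of historical detection records (one row = one dated sighting
#' of one species in one country), validates and cleans it, and annotates each
#' surviving record with its MSFD subregion. Cleaning drops records with an
#' unknown country code, a non-integer or out-of-range year, or incomplete /
#' out-of-range coordinates, then removes exact duplicates on the
#' (species, country, year) triple. Input row order is preserved and every
#' kept record carries its original row index as `source_rank`, the
#' deterministic tie-breaker used downstream when two first records share a
#' year.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param region_table A [region_table()].
#' @param columns Named list mapping the canonical column roles `species`,
#'   `year`, `country` (required) and `lon`, `lat`, `msfd` (optional) to the
#'   column names used in the file.
#' @param year_range Acceptable year bounds, inclusive. The default guard band
#'   `[1800, current year]` comfortably contains the 1882 onward span of
#'   Mediterranean first-record datasets.
#'
#' @return A list with `records` (a `detection_records` data frame: `species`,
#'   `year`, `country`, `msfd`, `lon`, `lat`, `source_rank`) and `report`
#'   (a [clean_report]).
#' @export
read_detection_records <- function(path, region_table,
                                   columns = list(),
                                   year_range = c(1800L, as.integer(format(Sys.Date(), "%Y")))) {
  if (!file.exists(path)) stopf("detection record file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  clean_detection_records(df, region_table, columns = columns, year_range = year_range)
}

#' Clean an in-memory detection-record table
#'
#' @param df Data frame of raw records, as read from CSV.
#' @inheritParams read_detection_records
#' @return Same as [read_detection_records()].
#' @export
clean_detection_records <- function(df, region_table,
                                    columns = list(),
                                    year_range = c(1800L, as.integer(format(Sys.Date(), "%Y")))) {
  stopifnot(inherits(region_table, "region_table"))
  cols <- utils::modifyList(
    list(species = "species", year = "year", country = "country",
         lon = "lon", lat = "lat", msfd = "msfd"),
    columns
  )
  required <- c("species", "year", "country")
  missing <- vapply(required, function(r) !cols[[r]] %in% names(df), logical(1))
  if (any(missing)) {
    stopf("required column(s) missing from input: %s",
          paste(unlist(cols[required][missing]), collapse = ", "))
  }

  n_input <- nrow(df)
  species <- trimws(as.character(df[[cols$species]]))
  country <- trimws(as.character(df[[cols$country]]))
  year <- suppressWarnings(as.numeric(df[[cols$year]]))
  has_lon <- cols$lon %in% names(df)
  has_lat <- cols$lat %in% names(df)
  lon <- if (has_lon) suppressWarnings(as.numeric(df[[cols$lon]])) else rep(NA_real_, n_input)
  lat <- if (has_lat) suppressWarnings(as.numeric(df[[cols$lat]])) else rep(NA_real_, n_input)
  msfd_over <- if (cols$msfd %in% names(df)) trimws(as.character(df[[cols$msfd]])) else rep(NA_character_, n_input)
  msfd_over[!nzchar(msfd_over) | is.na(msfd_over)] <- NA_character_

  messages <- character(0)
  invalid <- logical(n_input)
  flag <- function(bad, reason) {
    bad <- bad & !invalid
    if (any(bad)) {
      rs <- if (length(reason) == 1L) rep(reason, sum(bad)) else reason[bad]
      messages <<- c(messages, sprintf("row %d: %s", which(bad), rs))
      invalid[bad] <<- TRUE
    }
  }
  flag(is.na(species) | !nzchar(species), "empty species name")
  flag(!country %in% names(region_table$countries),
       sprintf("unknown country code '%s'", country))
  flag(is.na(year) | year != floor(year), "non-integer year")
  flag(!is.na(year) & (year < year_range[1] | year > year_range[2]),
       sprintf("year %s outside [%d, %d]", year, year_range[1], year_range[2]))
  flag(xor(is.na(lon), is.na(lat)), "one of lon/lat missing")
  flag(!is.na(lon) & (lon < -180 | lon > 180), "longitude outside [-180, 180]")
  flag(!is.na(lat) & (lat < -90 | lat > 90), "latitude outside [-90, 90]")
  # an MSFD override must be a membership of the record's country
  known <- country %in% names(region_table$countries)
  bad_over <- !is.na(msfd_over) & known & !mapply(
    function(ov, cc) ov %in% region_table$countries[[cc]]$msfd,
    msfd_over, country
  )
  flag(bad_over, "MSFD override not a membership of the record's country")

  keep <- !invalid
  dup <- duplicated(data.frame(species, country, year)[keep, , drop = FALSE])
  n_dropped_duplicate <- sum(dup)
  if (n_dropped_duplicate) {
    messages <- c(messages, sprintf("row %d: duplicate (species, country, year)",
                                    which(keep)[dup]))
  }
  kept_idx <- which(keep)[!dup]
  if (!length(kept_idx)) stopf("no valid detection records survive cleaning")

  records <- data.frame(
    species = species[kept_idx],
    year = as.integer(year[kept_idx]),
    country = country[kept_idx],
    msfd = map_country_to_msfd(country[kept_idx], region_table,
                               override = msfd_over[kept_idx]),
    lon = lon[kept_idx],
    lat = lat[kept_idx],
    source_rank = kept_idx,
    stringsAsFactors = FALSE
  )
  class(records) <- c("detection_records", "data.frame")

  report <- structure(
    list(n_input = n_input,
         n_dropped_invalid = sum(invalid),
         n_dropped_duplicate = n_dropped_duplicate,
         n_kept = length(kept_idx),
         messages = messages),
    class = "clean_report"
  )
  list(records = records, report = report)
}

#' Cleaning report
#'
#' Record counts from a cleaning pass: `n_input` rows read,
#' `n_dropped_invalid` failing validation, `n_dropped_duplicate` exact
#' (species, country, year) duplicates, `n_kept` surviving, plus
#' human-readable `messages`. Counts always satisfy
#' `n_input = n_dropped_invalid + n_dropped_duplicate + n_kept`.
#'
#' @name clean_report
NULL

#' @export
print.clean_report <- function(x, ...) {
  cat(sprintf("detection records: %d read, %d invalid, %d duplicate, %d kept\n",
              x$n_input, x$n_dropped_invalid, x$n_dropped_duplicate, x$n_kept))
  if (length(x$messages)) {
    cat(paste0("  - ", utils::head(x$messages, 10L), collapse = "\n"), "\n")
    if (length(x$messages) > 10L) cat("  ...", length(x$messages) - 10L, "more\n")
  }
  invisible(x)
}

#' Write cleaned detection records to CSV
#'
#' Serializes a cleaned record table in the same CSV dialect the reader
#' consumes, so that a write/read round trip reproduces the kept records.
#'
#' @param records A `detection_records` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detection_records <- function(records, path) {
  out <- records[, c("species", "year", "country", "msfd", "lon", "lat")]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
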