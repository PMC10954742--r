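#' Country to MSFD subregion lookup table
#'
#' Builds the table mapping Mediterranean country codes to Marine Strategy
#' Framework Directive (MSFD) subregions: EMED (Eastern Mediterranean),
#' CMED (Central Mediterranean), ADRIA (Adriatic Sea) and WMED (Western
#' Mediterranean). The packaged default mirrors the standard country list of
#' Mediterranean NIS studies; countries bordering more than one subregion
#' (Greece, Italy, Tunisia, Libya) carry an ordered membership list and a
#' configurable default used when a record gives no explicit subregion.
#'
#' @param path Path to a JSON region table. Defaults to the packaged table.
#' @param defaults Named character vector of per-country default MSFD
#'   overrides, e.g. `c(GR = "CMED")`. Each override must be one of the
#'   country's listed subregions.
#'
#' @return An object of class `region_table`: a list with `countries`
#'   (per-country name, MSFD membership, default), `msfd_order` (east to west
#'   display order) and `country_order`.
#' @export
region_table <- function(path = NULL, defaults = NULL) {
  path <- path %||% system.file("extdata", "msfd_regions.json",
                                package = "nismomentum", mustWork = TRUE)
  if (!file.exists(path)) stopf("region table file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  countries <- lapply(raw$countries, function(x) {
    list(name = x$name, msfd = unlist(x$msfd), default = x$default)
  })
  for (code in names(countries)) {
    cn <- countries[[code]]
    if (!cn$default %in% cn$msfd) {
      stopf("default MSFD code %s for %s is not in its membership list",
            cn$default, code)
    }
  }
  tab <- structure(
    list(countries = countries,
         msfd_order = unlist(raw$msfd_order),
         country_order = unlist(raw$country_order)),
    class = "region_table"
  )
  if (!is.null(defaults)) {
    for (code in names(defaults)) {
      cn <- tab$countries[[code]]
      if (is.null(cn)) stopf("unknown country code in `defaults`: %s", code)
      if (!defaults[[code]] %in% cn$msfd) {
        stopf("default %s is not an MSFD membership of %s", defaults[[code]], code)
      }
      tab$countries[[code]]$default <- defaults[[code]]
    }
  }
  tab
}

#' @export
print.region_table <- function(x, ...) {
  cat("MSFD region table:", length(x$countries), "countries;",
      "subregions", paste(x$msfd_order, collapse = " > "), "\n")
  multi <- names(x$countries)[vapply(x$countries, function(c) length(c$msfd) > 1L, logical(1))]
  if (length(multi)) {
    cat("multi-region countries:",
        paste(sprintf("%s (default %s)", multi,
                      vapply(x$countries[multi], `[[`, "", "default")),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Map a country code to its MSFD subregion
#'
#' Resolves a country code to a single MSFD subregion code. Countries
#' bordering several subregions resolve to their configured default unless a
#' per-record `override` is supplied (e.g. from an explicit `msfd` column).
#'
#' @param country Character vector of country codes.
#' @param region_table A [region_table()].
#' @param override Optional character vector (recycled NA-tolerant) of
#'   explicit MSFD codes; non-`NA` entries win over the default, and must be a
#'   listed membership of the country.
#'
#' @return Character vector of MSFD codes, same length as `country`.
#' @export
map_country_to_msfd <- function(country, region_table, override = NULL) {
  stopifnot(inherits(region_table, "region_table"))
  unknown <- setdiff(unique(country), names(region_table$countries))
  if (length(unknown)) {
    stopf("unknown country code(s): %s", paste(unknown, collapse = ", "))
  }
  out <- vapply(country, function(cc) region_table$countries[[cc]]$default, "",
                USE.NAMES = FALSE)
  if (!is.null(override)) {
    override <- rep_len(as.character(override), length(country))
    hit <- !is.na(override) & nzchar(override)
    for (i in which(hit)) {
      member <- region_table$countries[[country[i]]]$msfd
      if (!override[i] %in% member) {
        stopf("MSFD override %s is not a membership of country %s",
              override[i], country[i])
      }
      out[i] <- override[i]
    }
  }
  out
}
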