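#' Momentum sequence of a single species
#'
#' Converts one species' detection records into its momentum sequence: the
#' ordered first records per country. A momentum t_x is the x-th first-record
#' event of the species in a country it had not previously occupied, in
#' ascending temporal order; t_0 is the species' first record anywhere in the
#' basin. For each country only the earliest record is kept (ties on year
#' broken by smallest `source_rank`, i.e. input row order); repeat records
#' within an already-occupied country never advance the momentum. Same-year
#' transitions between different countries are legal and yield a downstream
#' year gap of zero.
#'
#' @param records A `detection_records` data frame containing records of
#'   exactly one species.
#' @param region_table A [region_table()]; used to fill the MSFD column if
#'   absent.
#'
#' @return A `momentum_series`: a data frame with columns `momentum`
#'   (0, 1, 2, ... consecutive), `country`, `msfd`, `year`, and attribute
#'   `species`.
#' @export
assign_momenta <- function(records, region_table) {
  if (nrow(records) == 0L) stopf("no records supplied")
  sp <- unique(records$species)
  if (length(sp) != 1L) {
    stopf("assign_momenta() expects records of a single species, got %d", length(sp))
  }
  if (is.null(records$msfd)) {
    records$msfd <- map_country_to_msfd(records$country, region_table)
  }
  if (is.null(records$source_rank)) records$source_rank <- seq_len(nrow(records))

  # earliest record per country, then temporal order with source_rank ties
  ord <- order(records$year, records$source_rank)
  records <- records[ord, , drop = FALSE]
  first <- records[!duplicated(records$country), , drop = FALSE]

  out <- data.frame(
    momentum = seq_len(nrow(first)) - 1L,
    country = first$country,
    msfd = first$msfd,
    year = first$year,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, species = sp, class = c("momentum_series", "data.frame"))
}

#' Momentum sequences for every species in a record table
#'
#' @param records A cleaned `detection_records` data frame (any number of
#'   species).
#' @param region_table A [region_table()].
#' @return Named list of `momentum_series`, one per species, in order of each
#'   species' first appearance in the input.
#' @export
momentum_table <- function(records, region_table) {
  if (nrow(records) == 0L) stopf("no records supplied")
  species <- unique(records$species)
  out <- lapply(species, function(sp) {
    assign_momenta(records[records$species == sp, , drop = FALSE], region_table)
  })
  stats::setNames(out, species)
}

#' Establishment classification
#'
#' A species is classified as established when its momentum sequence has at
#' least three successive first records (momenta t_0, t_1, t_2), i.e. it has
#' been sighted in at least three distinct countries.
#'
#' @param series A `momentum_series` (or a list of them).
#' @return Logical scalar (or named logical vector over the list).
#' @export
classify_established <- function(series) {
  if (inherits(series, "momentum_series")) return(nrow(series) >= 3L)
  vapply(series, function(s) nrow(s) >= 3L, logical(1))
}

#' Momentum heatmap counts
#'
#' Aggregates momentum sequences into a region-by-momentum count matrix: how
#' many species had their momentum-t first record in each country (or MSFD
#' subregion). Column t_0 sums to the number of species; column sums are
#' non-increasing in t because a species reaches momentum t only through
#' momentum t-1.
#'
#' @param all_series List of `momentum_series` (see [momentum_table()]).
#' @param level `"country"` or `"msfd"`.
#' @param region_table A [region_table()]; fixes the east-to-west row order.
#' @param max_momentum Highest momentum index tabulated (default 10, i.e. the
#'   t_0 to t_10 analysis window).
#'
#' @return A `momentum_heatmap`: integer matrix regions x momenta with
#'   dimnames, attributes `level` and `max_momentum`. Only regions with at
#'   least one record are kept as rows.
#' @export
heatmap_counts <- function(all_series, level = c("country", "msfd"),
                           region_table, max_momentum = 10L) {
  level <- match.arg(level)
  if (!length(all_series)) stopf("no momentum series supplied")
  steps <- do.call(rbind, lapply(all_series, function(s) {
    data.frame(region = s[[level]], momentum = s$momentum, stringsAsFactors = FALSE)
  }))
  steps <- steps[steps$momentum <= max_momentum, , drop = FALSE]

  region_order <- if (level == "country") region_table$country_order else region_table$msfd_order
  regions <- region_order[region_order %in% steps$region]
  extra <- setdiff(unique(steps$region), region_order)
  if (length(extra)) regions <- c(regions, sort(extra))

  counts <- matrix(0L, nrow = length(regions), ncol = max_momentum + 1L,
                   dimnames = list(regions, paste0("t", 0:max_momentum)))
  tab <- table(factor(steps$region, levels = regions), factor(steps$momentum, levels = 0:max_momentum))
  counts[] <- as.integer(tab)
  structure(counts, level = level, max_momentum = as.integer(max_momentum),
            class = c("momentum_heatmap", "matrix"))
}

#' @export
print.momentum_heatmap <- function(x, ...) {
  cat(sprintf("momentum heatmap (%s level): %d regions x momenta t0-t%d; %d species at t0\n",
              attr(x, "level"), nrow(x), attr(x, "max_momentum"), sum(x[, 1L])))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Export a heatmap as a long-format table
#'
#' @param heatmap A `momentum_heatmap`.
#' @return Data frame with columns `region`, `momentum`, `count`.
#' @export
heatmap_long <- function(heatmap) {
  df <- expand.grid(region = rownames(heatmap),
                    momentum = 0:attr(heatmap, "max_momentum"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$count <- as.integer(heatmap[cbind(df$region, paste0("t", df$momentum))])
  df[order(df$momentum, match(df$region, rownames(heatmap))), c("region", "momentum", "count")]
}
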