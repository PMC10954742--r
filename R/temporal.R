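#' Delta-of-momenta sample at one transition
#'
#' Pools, over species, the year gap of one momentum transition:
#' for every species possessing both momentum `step_index - 1` and
#' `step_index`, the contribution is `year[step_index] - year[step_index-1]`.
#' Gaps of zero (same-year transfers between countries) are legal sample
#' values.
#'
#' @param all_series List of `momentum_series`.
#' @param step_index Momentum transition index, >= 1 (1 means the
#'   t_0 -> t_1 transition, labelled `dt1-t0`).
#' @param species_filter Optional character vector of species names; when
#'   given, only those species contribute (used for the dominant-hotspot
#'   scenario).
#'
#' @return A `delta_distribution`: list with `step` (index), `label`,
#'   `values` (integer year gaps) and `n`.
#' @export
step_deltas <- function(all_series, step_index, species_filter = NULL) {
  if (!is_count(step_index) || step_index < 1) stopf("`step_index` must be an integer >= 1")
  if (!is.null(species_filter)) {
    all_series <- all_series[names(all_series) %in% species_filter]
  }
  values <- unlist(lapply(all_series, function(s) {
    if (nrow(s) > step_index) s$year[step_index + 1L] - s$year[step_index] else integer(0)
  }), use.names = FALSE)
  if (!length(values)) {
    stopf("no species possesses momenta %d and %d (empty delta distribution)",
          step_index - 1L, step_index)
  }
  structure(
    list(step = as.integer(step_index),
         label = sprintf("dt%d-t%d", step_index, step_index - 1L),
         values = as.integer(values),
         n = length(values)),
    class = "delta_distribution"
  )
}

#' @export
print.delta_distribution <- function(x, ...) {
  cat(sprintf("delta distribution %s: n = %d, min = %d, median = %g, max = %d\n",
              x$label, x$n, min(x$values), stats::median(x$values), max(x$values)))
  invisible(x)
}

#' Empirical CDF and sample median
#'
#' The empirical cumulative distribution function F(x) = fraction of values
#' <= x, together with the standard sample median (midpoint of the two central
#' order statistics for even n, so fractional years are possible).
#'
#' @param values Numeric vector, at least one value.
#' @return List with `ecdf` (a right-continuous step function, see
#'   [stats::ecdf()]) and `median`.
#' @export
ecdf_median <- function(values) {
  if (!length(values) || anyNA(values)) stopf("`values` must be non-empty and NA-free")
  list(ecdf = stats::ecdf(values), median = stats::median(values))
}

#' Species in the dominant hotspot at each momentum transition
#'
#' Implements the dominant-hotspot scenario's sample restriction: a species
#' contributes to the transition onto momentum k only if its momentum-k first
#' record lies in a country of the dominant hotspot selected at momentum k
#' (the minimal set of countries holding strictly more than `threshold`
#' percent of that momentum's records).
#'
#' @param all_series List of `momentum_series`.
#' @param region_table A [region_table()].
#' @param max_momentum Highest momentum considered.
#' @param threshold Cumulative share threshold in percent (default 50).
#' @return List indexed by step 1..max_momentum of character vectors of
#'   qualifying species names.
#' @export
dominant_step_species <- function(all_series, region_table,
                                  max_momentum = 10L, threshold = 50) {
  hm <- heatmap_counts(all_series, level = "country", region_table = region_table,
                       max_momentum = max_momentum)
  out <- vector("list", max_momentum)
  for (k in seq_len(max_momentum)) {
    if (sum(hm[, k + 1L]) == 0L) {
      out[[k]] <- character(0)
      next
    }
    sel <- select_dominant_hotspot(hm, k, threshold = threshold)
    keep <- vapply(all_series, function(s) {
      nrow(s) > k && s$country[k + 1L] %in% sel$selected
    }, logical(1))
    out[[k]] <- names(all_series)[keep]
  }
  out
}

#' Cumulative median spread curve
#'
#' For each momentum transition up to `max_momentum`, takes the eCDF median of
#' the pooled delta-of-momenta sample and accumulates those medians into the
#' running total of years since entry. Under the `"dominant"` scenario each
#' transition's sample is restricted to species whose record at that momentum
#' falls in the dominant hotspot (see [dominant_step_species()]). The curve is
#' truncated at the last transition with a non-empty sample.
#'
#' @param all_series List of `momentum_series`.
#' @param scenario `"all"` (every species; scenario 1) or `"dominant"`
#'   (hotspot-restricted; scenario 2).
#' @param region_table A [region_table()]; required for `"dominant"`.
#' @param max_momentum Highest momentum transition (default 10).
#' @param threshold Dominant-hotspot share threshold in percent.
#'
#' @return A `cumulative_curve` data frame with columns `step`, `label`, `n`,
#'   `median` (years, possibly fractional), `cumulative` (prefix sum of
#'   medians) and `low_n` (flag for single-observation steps); attribute
#'   `scenario`.
#' @export
cumulative_median_curve <- function(all_series,
                                    scenario = c("all", "dominant"),
                                    region_table = NULL,
                                    max_momentum = 10L,
                                    threshold = 50) {
  scenario <- match.arg(scenario)
  filt <- NULL
  if (scenario == "dominant") {
    if (is.null(region_table)) stopf("`region_table` is required for the dominant scenario")
    filt <- dominant_step_species(all_series, region_table,
                                  max_momentum = max_momentum, threshold = threshold)
  }
  rows <- list()
  for (k in seq_len(max_momentum)) {
    sf <- if (is.null(filt)) NULL else filt[[k]]
    if (!is.null(sf) && !length(sf)) break
    dd <- tryCatch(step_deltas(all_series, k, species_filter = sf),
                   error = function(e) NULL)
    if (is.null(dd)) break
    rows[[k]] <- data.frame(step = k, label = dd$label, n = dd$n,
                            median = ecdf_median(dd$values)$median,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) stopf("no momentum transition has a non-empty delta distribution")
  curve <- do.call(rbind, rows)
  curve$cumulative <- cumsum(curve$median)
  curve$low_n <- curve$n < 2L
  structure(curve, scenario = scenario, class = c("cumulative_curve", "data.frame"))
}

#' @export
print.cumulative_curve <- function(x, ...) {
  cat(sprintf("cumulative median spread curve, scenario '%s' (%d transitions)\n",
              attr(x, "scenario"), nrow(x)))
  print(as.data.frame(x))
  invisible(x)
}

#' Percentage deviation between the two scenarios
#'
#' Per momentum transition, the relative difference of the step medians of the
#' two scenarios, in percent of the reference (all-records) scenario:
#' `100 * |m_all - m_dom| / m_all`. When both medians are zero the deviation
#' is 0; when only the reference median is zero the deviation is undefined and
#' flagged.
#'
#' @param curve_all `cumulative_curve` for the all-records scenario (the
#'   denominator/reference).
#' @param curve_dom `cumulative_curve` for the dominant-hotspot scenario.
#' @return Data frame with `step`, `label`, `median_all`, `median_dominant`,
#'   `deviation_pct` and `undefined` (logical).
#' @export
scenario_deviation <- function(curve_all, curve_dom) {
  n <- min(nrow(curve_all), nrow(curve_dom))
  if (nrow(curve_all) != nrow(curve_dom)) {
    stopf("curves cover different numbers of transitions (%d vs %d)",
          nrow(curve_all), nrow(curve_dom))
  }
  m1 <- curve_all$median[seq_len(n)]
  m2 <- curve_dom$median[seq_len(n)]
  dev <- ifelse(m1 == 0 & m2 == 0, 0, 100 * abs(m1 - m2) / m1)
  undef <- m1 == 0 & m2 != 0
  dev[undef] <- NA_real_
  data.frame(step = curve_all$step[seq_len(n)],
             label = curve_all$label[seq_len(n)],
             median_all = m1, median_dominant = m2,
             deviation_pct = dev, undefined = undef,
             stringsAsFactors = FALSE)
}
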