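# The six-way migration-strategy decision tree and cohort summaries.

#' Strategy labels
#'
#' `LDM` long-distance geographic migrant (> 20 km), `SDM` short-distance
#' (<= 20 km), `VAC` vacillating migrant (>= 2 mid-summer returns),
#' `TRAD_ALT` traditional altitudinal migrant, `ABR_ALT` abbreviated
#' altitudinal migrant, `RESIDENT` geographic and altitudinal resident.
#'
#' @export
strategy_levels <- function() STRATEGIES

#' Classify one animal's migration strategy
#'
#' Decision order: a geographic migrant with >= 2 returns is `VAC`;
#' otherwise a migrant is `LDM` when its route distance exceeds
#' `long_distance_km` (exactly 20 km counts as short, logged) and `SDM`
#' when not; a geographic resident takes `TRAD_ALT`, `ABR_ALT` or
#' `RESIDENT` from its altitudinal pattern (a mixed pattern falls back to
#' `RESIDENT`, flagged). The geographic label always takes precedence over
#' any concurrent altitudinal pattern.
#'
#' @param geographic_migrant logical verdict (NSD migrant *and* summer
#'   range overlapping < 20% of winter).
#' @param n_vacillations integer return count (migrants).
#' @param distance_km reported route distance (migrants).
#' @param altitudinal_pattern one of the [classify_altitudinal()] patterns
#'   (residents).
#' @param cfg the `strategy` config section.
#' @return character label, with attribute `note` for edge cases.
#' @export
#' @examples
#' classify_strategy(TRUE, 0, 47.4, NA)        # "LDM"
#' classify_strategy(TRUE, 3, 11.4, NA)        # "VAC"
#' classify_strategy(FALSE, 0, NA, "abbreviated")  # "ABR_ALT"
classify_strategy <- function(geographic_migrant, n_vacillations,
                              distance_km, altitudinal_pattern,
                              cfg = default_config()$strategy) {
  note <- NULL
  label <- if (isTRUE(geographic_migrant)) {
    if (!is.na(n_vacillations) && n_vacillations >= 2) {
      "VAC"
    } else if (is.na(distance_km)) {
      stop("migrant lacks a route distance")
    } else if (distance_km > cfg$long_distance_km) {
      "LDM"
    } else {
      if (distance_km == cfg$long_distance_km) {
        note <- "distance exactly at the long/short cut; classed short"
      }
      "SDM"
    }
  } else {
    switch(as.character(altitudinal_pattern),
      traditional = "TRAD_ALT",
      abbreviated = "ABR_ALT",
      `altitudinal-resident` = "RESIDENT",
      mixed = {
        note <- "mixed altitudinal pattern; classed resident"
        "RESIDENT"
      },
      stop("resident lacks an altitudinal pattern")
    )
  }
  if (!is.null(note)) attr(label, "note") <- note
  label
}

#' Cohort summary statistics
#'
#' Median (linear-interpolated 50th percentile; even n gives the mean of
#' the two central order statistics), min, max and n for each numeric
#' column, optionally split by a grouping column. NAs are dropped
#' per-statistic.
#'
#' @param records per-animal data.frame.
#' @param value_cols names of numeric columns to summarize (default all
#'   numeric).
#' @param group_col optional name of a grouping column (e.g. migrant vs
#'   resident).
#' @return data.frame with columns `statistic`, `group`, `n`, `median`,
#'   `min`, `max`, `p33`, `p66`.
#' @export
summarize_cohort <- function(records, value_cols = NULL,
                             group_col = NULL) {
  if (is.null(value_cols)) {
    value_cols <- names(records)[vapply(records, is.numeric, logical(1))]
  }
  groups <- if (is.null(group_col)) {
    list(all = seq_len(nrow(records)))
  } else {
    split(seq_len(nrow(records)), records[[group_col]])
  }
  rows <- list()
  for (g in names(groups)) {
    for (v in value_cols) {
      x <- records[[v]][groups[[g]]]
      x <- x[!is.na(x)]
      if (!length(x)) next
      rows[[length(rows) + 1]] <- data.frame(
        statistic = v, group = g, n = length(x),
        median = stats::median(x), min = min(x), max = max(x),
        p33 = pctile(x, 0.33), p66 = pctile(x, 0.66))
    }
  }
  do.call(rbind, rows)
}
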