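# Seasonal 95% ranges, overlaps, band assignment and winter fidelity.

#' Estimate a seasonal range (95% UD isopleth)
#'
#' Fits the Brownian bridge UD to the fixes inside the season window(s) and
#' extracts the `ud_q` isopleth. sigma1 is estimated per season segment.
#' Returns NULL (with a warning) when the window holds fewer than 30 days
#' of data.
#'
#' @param track a `sheep_track`.
#' @param windows one `c(start, end)` date interval or a list of them
#'   (winter may wrap around the study span).
#' @param cfg the `bbmm` + `ranges` config sections (see
#'   [default_config()]).
#' @param q isopleth level (default `cfg$ranges$ud_q`).
#' @return a `range_polygon` with attributes `ud` (the `ud_surface`) and
#'   `sigma1_m`, or NULL if insufficient data.
#' @export
seasonal_range <- function(track, windows, cfg = default_config(),
                           q = cfg$ranges$ud_q) {
  if (!is.list(windows)) windows <- list(windows)
  day <- as.Date(track$t, tz = "UTC")
  sel <- Reduce(`|`, lapply(windows, function(w) day >= w[1] & day <= w[2]))
  n_days <- length(unique(day[sel]))
  if (n_days < cfg$ranges$min_window_days) {
    warning(track$animal_id[1], ": only ", n_days,
            " days in season window; range not estimated")
    return(NULL)
  }
  x <- track$x[sel]
  y <- track$y[sel]
  t <- track$t[sel]
  est <- estimate_sigma1(x, y, t, sigma2_m = cfg$bbmm$sigma2_m,
                         bracket = cfg$bbmm$sigma1_bracket)
  params <- bbmm_params(est$sigma1_m, cfg$bbmm$sigma2_m,
                        cfg$bbmm$max_bridge_gap_h)
  ud <- compute_ud(x, y, t, params, cell_m = cfg$bbmm$cell_m,
                   n_alpha = cfg$bbmm$n_alpha,
                   alpha_quad = cfg$bbmm$alpha_quad,
                   trunc_sd = cfg$bbmm$trunc_sd)
  poly <- isopleth(ud, q)
  attr(poly, "ud") <- ud
  attr(poly, "sigma1_m") <- est$sigma1_m
  poly
}

#' Overlap between two range polygons
#'
#' Cell-set intersection on the shared 50 m grid registration.
#'
#' @param a,b `range_polygon`s on the same grid.
#' @return list with `area_ha`, `pct_of_first` (percentage of `a` covered),
#'   `pct_of_second`.
#' @export
range_overlap <- function(a, b) {
  if (a$cell_m != b$cell_m) stop("grid registration mismatch")
  ka <- paste(a$ix, a$iy)
  kb <- paste(b$ix, b$iy)
  n_int <- sum(ka %in% kb)
  cell_area_ha <- (a$cell_m^2) / 1e4
  list(area_ha = n_int * cell_area_ha,
       pct_of_first = 100 * n_int / length(ka),
       pct_of_second = 100 * n_int / length(kb))
}

#' Geographic-migrant rule from summer-on-winter overlap
#'
#' An animal is a geographic migrant iff its summer range overlaps strictly
#' less than 20% of its winter range (exactly 20% counts as resident).
#'
#' @param summer_on_winter_pct percentage of the winter range covered by
#'   the summer range.
#' @param threshold_pct cut-off (default 20).
#' @return logical.
#' @export
#' @examples
#' is_geographic_migrant(9.7)   # TRUE
#' is_geographic_migrant(29.5)  # FALSE
#' is_geographic_migrant(20.0)  # FALSE (strict inequality)
is_geographic_migrant <- function(summer_on_winter_pct,
                                  threshold_pct = 20) {
  summer_on_winter_pct < threshold_pct
}

#' Partition animals into bands from winter ranges and co-movement
#'
#' Two animals share an edge when their winter ranges overlap by more than
#' `band_overlap_pct` of the smaller range (the same directional reading as
#' the fidelity rule) *and* their co-movement score exceeds
#' `co_movement_frac`, where co-movement is the fraction of time-matched
#' fix pairs (within 1 h, during the overlapping winter data) separated by
#' less than `proximity_m`. Bands are the connected components; the
#' partition does not depend on input order.
#'
#' @param winter_ranges named list of `range_polygon`s (one per animal).
#' @param tracks named list of `sheep_track`s (same names).
#' @param cfg the `ranges` config section.
#' @return data.frame with `animal_id` and integer `band` (components
#'   numbered by their lowest sorted animal id).
#' @export
assign_bands <- function(winter_ranges, tracks,
                         cfg = default_config()$ranges) {
  ids <- sort(names(winter_ranges))
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        ov <- range_overlap(winter_ranges[[ids[i]]],
                            winter_ranges[[ids[j]]])
        # percentage of the smaller range, as in the fidelity rule: a
        # member whose range is enlarged by excursions still shares the
        # band's core winter range
        if (max(ov$pct_of_first, ov$pct_of_second) <=
              cfg$band_overlap_pct) {
          next
        }
        sc <- co_movement(tracks[[ids[i]]], tracks[[ids[j]]],
                          proximity_m = cfg$proximity_m)
        if (!is.na(sc) && sc > cfg$co_movement_frac) {
          adj[i, j] <- adj[j, i] <- TRUE
        }
      }
    }
  }
  comp <- rep(0L, n)
  nb <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      nb <- nb + 1L
      queue <- i
      while (length(queue)) {
        k <- queue[[1]]
        queue <- queue[-1]
        if (comp[k] == 0L) {
          comp[k] <- nb
          queue <- c(queue, which(adj[k, ] & comp == 0L))
        }
      }
    }
  }
  data.frame(animal_id = ids, band = comp, row.names = NULL)
}

#' Co-movement score between two tracks
#'
#' Fraction of fix pairs matched within 1 h that are closer than
#' `proximity_m`.
#'
#' @param a,b `sheep_track`s.
#' @param proximity_m distance cut (m).
#' @return fraction in \[0, 1\], NA if no pairs match in time.
#' @export
co_movement <- function(a, b, proximity_m = 500) {
  ta <- as.numeric(a$t)
  tb <- as.numeric(b$t)
  j <- findInterval(ta, tb)
  j_lo <- pmax(j, 1)
  j_hi <- pmin(j + 1, length(tb))
  d_lo <- abs(tb[j_lo] - ta)
  d_hi <- abs(tb[j_hi] - ta)
  j_best <- ifelse(d_hi < d_lo, j_hi, j_lo)
  dt <- abs(tb[j_best] - ta)
  ok <- dt <= 3600
  if (!any(ok)) return(NA_real_)
  d <- sqrt((a$x[ok] - b$x[j_best[ok]])^2 + (a$y[ok] - b$y[j_best[ok]])^2)
  mean(d < proximity_m)
}

#' Winter-range fidelity across years
#'
#' An animal expresses fidelity iff every consecutive-year pair of winter
#' ranges overlaps by more than `threshold_pct` of the smaller range
#' (animals with three winters must pass both pairs).
#'
#' @param ranges_by_year list of `range_polygon`s in year order (>= 2).
#' @param threshold_pct overlap threshold (default 50).
#' @return logical.
#' @export
winter_fidelity <- function(ranges_by_year, threshold_pct = 50) {
  stopifnot(length(ranges_by_year) >= 2)
  for (i in seq_len(length(ranges_by_year) - 1)) {
    ov <- range_overlap(ranges_by_year[[i]], ranges_by_year[[i + 1]])
    if (max(ov$pct_of_first, ov$pct_of_second) <= threshold_pct) {
      return(FALSE)
    }
  }
  TRUE
}
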