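# Elevation-use series and altitudinal migration classification.

#' Daily and moving-window elevation series with seasonal statistics
#'
#' Daily mean elevation over the fixes of each calendar day; a 14-day
#' moving mean spanning days -7..+6 around each day (centred, so a step
#' change crosses its midpoint exactly on the step day); seasonal medians
#' and ranges over the per-fix elevations inside each season window.
#' The moving mean is NA across gaps longer than the window.
#'
#' @param track an elevation-annotated `sheep_track`.
#' @param windows a [season_windows()] result.
#' @param cfg the `altitude` config section.
#' @return object of class `elevation_series`: `daily` (date, mean_m,
#'   moving_m), `winter_median_m`, `summer_median_m`, `winter_range_m`,
#'   `summer_range_m`, `delta_m` (winter minus summer, negative when the
#'   summer is higher), `windows`.
#' @export
elevation_series <- function(track, windows,
                             cfg = default_config()$altitude) {
  ok <- !is.na(track$elev_m)
  if (!any(ok)) stop("track has no elevation annotations")
  day <- as.Date(track$t[ok], tz = "UTC")
  elev <- track$elev_m[ok]
  days <- seq(min(day), max(day), by = "day")
  daily <- rep(NA_real_, length(days))
  mn <- tapply(elev, day, mean)
  daily[match(as.Date(names(mn)), days)] <- mn
  before <- if (isTRUE(cfg$centred)) ceiling(cfg$window_days / 2) else
    cfg$window_days - 1
  after <- if (isTRUE(cfg$centred)) cfg$window_days - before - 1 else 0
  moving <- roll_mean_window(daily, before = before, after = after)

  season_fixes <- function(ivals) {
    if (!is.list(ivals)) ivals <- list(ivals)
    sel <- Reduce(`|`, lapply(ivals, function(w) day >= w[1] & day <= w[2]))
    elev[sel]
  }
  w_elev <- season_fixes(windows$winter)
  s_elev <- season_fixes(windows$summer)
  structure(list(
    animal_id = track$animal_id[1],
    daily = data.frame(date = days, mean_m = daily, moving_m = moving),
    winter_median_m = stats::median(w_elev),
    summer_median_m = stats::median(s_elev),
    winter_range_m = if (length(w_elev)) range(w_elev) else c(NA, NA),
    summer_range_m = if (length(s_elev)) range(s_elev) else c(NA, NA),
    delta_m = stats::median(w_elev) - stats::median(s_elev),
    windows = windows
  ), class = "elevation_series")
}

#' @export
print.elevation_series <- function(x, ...) {
  cat(sprintf(
    "<elevation_series> %s: winter median %.0f m, summer %.0f m (delta %+.1f m)\n",
    x$animal_id, x$winter_median_m, x$summer_median_m, x$delta_m))
  invisible(x)
}

#' Classify the altitudinal migration pattern
#'
#' Decision order: *traditional* iff the winter-to-summer median elevation
#' change exceeds 250 m in magnitude; else *abbreviated* iff all four
#' phase changes pass — the moving-mean minimum of the spring transition
#' sits > 150 m below both the winter and summer medians, and the fall
#' minimum sits > 100 m below both; else *altitudinal-resident* iff the
#' moving mean stays inside a 150 m envelope year-round; anything else is
#' *mixed* (flagged, treated as residency downstream). Spring extrema are
#' searched between 14 days before the winter end and 14 days after the
#' summer start; fall analogously.
#'
#' @param series an [elevation_series()] result.
#' @param cfg the `altitude` config section.
#' @return object of class `altitudinal_verdict`: `pattern` one of
#'   `"traditional"`, `"abbreviated"`, `"altitudinal-resident"`,
#'   `"mixed"`; `delta_m`; the four phase deltas (m).
#' @export
classify_altitudinal <- function(series,
                                 cfg = default_config()$altitude) {
  d <- series$daily
  wmed <- series$winter_median_m
  smed <- series$summer_median_m
  win <- series$windows
  pad <- cfg$phase_pad_days

  # winter may hold several intervals; phase windows attach to the interval
  # boundaries adjacent to summer
  w_ends <- vapply(win$winter, function(w) as.numeric(w[2]), numeric(1))
  w_starts <- vapply(win$winter, function(w) as.numeric(w[1]), numeric(1))
  summer <- win$summer
  winter_end <- as.Date(max(w_ends[w_ends <= as.numeric(summer[1])],
                            min(w_starts)), origin = "1970-01-01")
  after_summer <- w_starts[w_starts >= as.numeric(summer[2])]
  winter_start <- as.Date(if (length(after_summer)) min(after_summer)
                          else max(w_starts), origin = "1970-01-01")

  phase_min <- function(from, to) {
    sel <- d$date >= from & d$date <= to & !is.na(d$moving_m)
    if (!any(sel)) return(NA_real_)
    min(d$moving_m[sel])
  }
  spring_min <- phase_min(winter_end - pad, summer[1] + pad)
  fall_min <- phase_min(summer[2] - pad, winter_start + pad)

  deltas <- c(
    winter_minus_spring_min = wmed - spring_min,
    summer_minus_spring_min = smed - spring_min,
    summer_minus_fall_min = smed - fall_min,
    winter_minus_fall_min = wmed - fall_min
  )
  envelope <- diff(range(d$moving_m, na.rm = TRUE))

  pattern <- if (is.na(wmed) || is.na(smed)) {
    NA_character_
  } else if (abs(series$delta_m) > cfg$trad_delta_m) {
    "traditional"
  } else if (!any(is.na(deltas)) &&
               deltas[1] > cfg$abr_spring_delta_m &&
               deltas[2] > cfg$abr_spring_delta_m &&
               deltas[3] > cfg$abr_fall_delta_m &&
               deltas[4] > cfg$abr_fall_delta_m) {
    "abbreviated"
  } else if (envelope <= cfg$resident_envelope_m) {
    "altitudinal-resident"
  } else {
    "mixed"
  }
  structure(list(pattern = pattern, delta_m = series$delta_m,
                 phase_deltas_m = deltas, envelope_m = envelope,
                 spring_min_m = spring_min, fall_min_m = fall_min),
            class = "altitudinal_verdict")
}

#' @export
print.altitudinal_verdict <- function(x, ...) {
  cat(sprintf("<altitudinal_verdict> %s (delta %+.1f m)\n",
              x$pattern, x$delta_m))
  invisible(x)
}
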