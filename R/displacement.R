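# Net squared displacement and migration timing.
#
# The study's migration dates were picked by visual inspection of NSD
# curves; this module is the deterministic surrogate: a plateau detector on
# the smoothed daily NSD series with every constant exposed in the config,
# validated by simulator recovery rather than by matching eyeballs.

#' Compute a net squared displacement series
#'
#' The reference point is the first fix at/after `reference_date` (default
#' 15 March, pushed to capture + 7 days for animals collared later, when
#' they can be assumed still on their winter range). NSD is the squared
#' Euclidean distance from that point in km^2; the daily series is the
#' median NSD per calendar day smoothed with a centred 3-day rolling
#' median.
#'
#' @param track a `sheep_track`.
#' @param reference_date Date; defaults to 15 March of the first year (or
#'   capture + 7 days if later).
#' @return object of class `nsd_series`: `animal_id`, `ref` (x0, y0, date),
#'   `fixes` (t, nsd_km2), `daily` (date, nsd_km2, smoothed_km2).
#' @export
compute_nsd <- function(track, reference_date = NULL) {
  if (is.null(reference_date)) {
    yr <- format(as.Date(min(track$t), tz = "UTC"), "%Y")
    reference_date <- as.Date(paste0(yr, "-03-15"))
    cap <- attr(track, "capture_date")
    if (!is.null(cap) && cap + 7 > reference_date) {
      reference_date <- cap + 7
    }
  }
  after <- which(as.Date(track$t, tz = "UTC") >= reference_date)
  if (!length(after)) stop("no fix at or after the reference date")
  i0 <- after[1]
  if (as.Date(track$t[i0], tz = "UTC") > reference_date + 7) {
    stop("no fix within 7 days of the reference date")
  }
  x0 <- track$x[i0]
  y0 <- track$y[i0]
  sub <- as.data.frame(track)[after, ]
  nsd <- ((sub$x - x0)^2 + (sub$y - y0)^2) / 1e6
  day <- as.Date(sub$t, tz = "UTC")
  days <- seq(min(day), max(day), by = "day")
  daily <- rep(NA_real_, length(days))
  med <- tapply(nsd, day, stats::median)
  daily[match(as.Date(names(med)), days)] <- med
  structure(list(
    animal_id = track$animal_id[1],
    ref = list(x0 = x0, y0 = y0, date = reference_date),
    fixes = data.frame(t = sub$t, nsd_km2 = nsd),
    daily = data.frame(date = days, nsd_km2 = daily,
                       smoothed_km2 = roll_median(daily, 3))
  ), class = "nsd_series")
}

#' @export
print.nsd_series <- function(x, ...) {
  cat(sprintf("<nsd_series> %s: ref %s, %d fixes, peak %.1f km^2\n",
              x$animal_id, x$ref$date, nrow(x$fixes),
              max(x$fixes$nsd_km2)))
  invisible(x)
}

#' Detect a geographic migration from an NSD series
#'
#' Algorithm: (1) the winter radius `r_w` is the 95th percentile of
#' sqrt(NSD) over the 30 days following the reference date; (2) candidate
#' summer days have smoothed NSD above `plateau_frac` (default 0.5) of the
#' series' 95th percentile, in runs of at least `min_run_days`; (3) the
#' animal is a migrant iff the longest contiguous candidate run spans at
#' least 30 days *and* the plateau displacement (sqrt of the run's median
#' smoothed NSD) exceeds `min_separation_factor * r_w`; (4) spring dates
#' come from the first candidate run (end = the run's first day, start =
#' the last preceding day with smoothed NSD at or below `r_w^2`), fall
#' dates from the last run (start = the run's last day, end = the first
#' later day at or below `r_w^2` that stays below it for 30 days).
#'
#' @param series an [compute_nsd()] result covering >= 10 months.
#' @param cfg the `detector` section of [default_config()].
#' @return a `migration_event` (animal_id, spring/fall dates, durations,
#'   `truncated` flag, `n_vacillations = NA` until counted) or a list with
#'   `verdict = "resident"`.
#' @export
detect_migration <- function(series, cfg = default_config()$detector) {
  d <- series$daily
  if (nrow(d) < 300) stop("need >= 10 months of daily NSD")
  sm <- d$smoothed_km2
  w30 <- d$date <= series$ref$date + cfg$winter_radius_days
  early <- series$fixes$t <= as.POSIXct(
    paste(series$ref$date + cfg$winter_radius_days, "23:59:59"), tz = "UTC")
  r_w <- pctile(sqrt(series$fixes$nsd_km2[early]), 0.95)  # km
  thr <- cfg$plateau_frac * pctile(sm, 0.95)
  runs <- true_runs(sm > thr)
  runs <- runs[runs$length >= cfg$min_run_days, , drop = FALSE]
  resident <- list(verdict = "resident", animal_id = series$animal_id,
                   r_w_km = r_w)
  if (!nrow(runs)) return(resident)
  longest <- runs[which.max(runs$length), ]
  plateau_km <- sqrt(stats::median(sm[longest$start:longest$end],
                                   na.rm = TRUE))
  if (longest$length < cfg$migrant_run_days ||
      plateau_km <= cfg$min_separation_factor * r_w) {
    return(resident)
  }

  first <- runs[1, ]
  last <- runs[nrow(runs), ]
  spring_end <- d$date[first$start]
  before <- which(seq_len(nrow(d)) < first$start & !is.na(sm) &
                    sm <= r_w^2)
  spring_start <- if (length(before)) {
    d$date[max(before)]
  } else {
    d$date[1]
  }
  fall_start <- d$date[last$end]
  fall_end <- NULL
  truncated <- FALSE
  after <- which(seq_len(nrow(d)) > last$end & !is.na(sm) & sm <= r_w^2)
  for (i in after) {
    horizon <- i:min(i + 29, nrow(d))
    ok <- !is.na(sm[horizon]) & sm[horizon] <= r_w^2
    if (all(ok)) {
      if (length(horizon) < 30) {
        truncated <- TRUE
        fall_end <- NULL
      } else {
        fall_end <- d$date[i]
      }
      break
    }
  }
  if (is.null(fall_end) && !truncated) truncated <- TRUE
  structure(list(
    verdict = "migrant", animal_id = series$animal_id,
    spring_start = spring_start, spring_end = spring_end,
    fall_start = fall_start, fall_end = fall_end,
    spring_duration_d = max(1, as.numeric(spring_end - spring_start)),
    fall_duration_d = if (is.null(fall_end)) {
      NA_real_
    } else {
      max(1, as.numeric(fall_end - fall_start))
    },
    truncated = truncated, r_w_km = r_w, plateau_km = plateau_km,
    n_vacillations = NA_integer_
  ), class = "migration_event")
}

#' @export
print.migration_event <- function(x, ...) {
  cat(sprintf(
    "<migration_event> %s: spring %s to %s, fall %s to %s%s\n",
    x$animal_id, x$spring_start, x$spring_end, x$fall_start,
    if (is.null(x$fall_end)) "?" else format(x$fall_end),
    if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' Count vacillating returns to the winter range
#'
#' A return is a maximal interval strictly between the spring arrival and
#' the fall departure during which at least `min_return_fixes` consecutive
#' fixes fall inside the winter 95% range polygon.
#'
#' @param track a `sheep_track`.
#' @param event a `migration_event`.
#' @param winter_range the winter [isopleth()] polygon.
#' @param cfg the `detector` config section.
#' @return integer count.
#' @export
count_vacillations <- function(track, event, winter_range,
                               cfg = default_config()$detector) {
  day <- as.Date(track$t, tz = "UTC")
  mid <- day > event$spring_end & day < event$fall_start
  if (!any(mid)) return(0L)
  inside <- in_polygon(winter_range, track$x[mid], track$y[mid])
  runs <- true_runs(inside)
  sum(runs$length >= cfg$min_return_fixes)
}

#' Season windows shared by geographic residents
#'
#' Residents show no clear migration, so their summer is bounded by the
#' 66th percentile of the migrants' spring end dates and the 33rd
#' percentile of their fall start dates; winter analogously by the 66th
#' percentile of fall ends and the 33rd percentile of spring starts
#' (crossing the calendar-year boundary). Percentiles use linear
#' interpolation on day-of-year ordinals and are rounded half-up to whole
#' days.
#'
#' @param events list of `migration_event`s (>= 3).
#' @return list with `summer` and `winter` as `c(start, end)` Dates and
#'   `provenance = "resident-percentile"`.
#' @export
resident_seasons <- function(events) {
  events <- Filter(function(e) !is.null(e$fall_end), events)
  if (length(events) < 3) {
    stop("need >= 3 complete migrant events to derive resident seasons; ",
         "provide season windows manually")
  }
  doy <- function(d) as.numeric(format(d, "%j"))
  yr <- format(events[[1]]$spring_start, "%Y")
  from_doy <- function(j) as.Date(paste0(yr, "-01-01")) + round_half_up(j) - 1
  se <- vapply(events, function(e) doy(e$spring_end), numeric(1))
  fs <- vapply(events, function(e) doy(e$fall_start), numeric(1))
  fe <- vapply(events, function(e) doy(e$fall_end), numeric(1))
  ss <- vapply(events, function(e) doy(e$spring_start), numeric(1))
  list(
    summer = c(from_doy(pctile(se, 0.66)), from_doy(pctile(fs, 0.33))),
    winter = c(from_doy(pctile(fe, 0.66)),
               from_doy(pctile(ss, 0.33)) + 365),
    provenance = "resident-percentile"
  )
}

#' Per-animal season windows
#'
#' Migrants take their own event dates (winter = data start to spring
#' start plus fall end to data end; summer = spring end to fall start);
#' residents take the cohort percentile template from
#' [resident_seasons()], intersected with their data span.
#'
#' @param track a `sheep_track`.
#' @param event a `migration_event`, or anything with
#'   `verdict == "resident"`.
#' @param template a [resident_seasons()] result (needed for residents).
#' @return list with `winter` (list of date intervals), `summer` (one
#'   interval), `provenance`.
#' @export
season_windows <- function(track, event, template = NULL) {
  first <- as.Date(min(track$t), tz = "UTC")
  last <- as.Date(max(track$t), tz = "UTC")
  if (inherits(event, "migration_event")) {
    winter <- list(c(first, event$spring_start))
    if (!is.null(event$fall_end) && event$fall_end < last) {
      winter <- c(winter, list(c(event$fall_end, last)))
    }
    list(winter = winter,
         summer = c(event$spring_end, event$fall_start),
         provenance = "migrant-derived")
  } else {
    if (is.null(template)) {
      stop("resident season windows need a percentile template")
    }
    wrap_start <- template$winter[1]
    wrap_end <- template$winter[2] - 365
    winter <- list()
    if (wrap_end >= first) winter <- list(c(first, min(wrap_end, last)))
    if (wrap_start <= last) {
      winter <- c(winter, list(c(max(wrap_start, first), last)))
    }
    list(winter = winter,
         summer = c(max(template$summer[1], first),
                    min(template$summer[2], last)),
         provenance = "resident-percentile")
  }
}
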