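# Ingest, validation, cleaning and elevation annotation of collar fixes.

#' Default Movebank-style column mapping
#'
#' @return named list mapping internal fields to input column names.
#' @export
movebank_columns <- function() {
  list(animal_id = "individual-local-identifier",
       timestamp = "timestamp",
       lon = "location-long",
       lat = "location-lat",
       n_sats = "gps:satellite-count")
}

# element-wise tolerant UTC timestamp parsing: rows that match no known
# format become NA instead of aborting the whole file
#' @keywords internal
parse_timestamps <- function(s) {
  fmts <- c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
            "%Y/%m/%d %H:%M:%OS")
  out <- as.POSIXct(rep(NA_real_, length(s)), tz = "UTC",
                    origin = "1970-01-01")
  for (fmt in fmts) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(s[miss], tz = "UTC", format = fmt)
  }
  out
}

#' Read GPS collar fixes from delimited text
#'
#' Produces one time-sorted track per animal. Geographic coordinates are
#' reprojected to the metric CRS; rows whose timestamp or coordinates do not
#' parse are rejected record-by-record with a reason, and duplicate
#' timestamps within an animal keep the first record (the rest are flagged).
#'
#' @param path delimited text file.
#' @param crs metric CRS id, e.g. `"EPSG:32609"`.
#' @param columns column mapping as in [movebank_columns()]. Use fields
#'   `x`/`y` instead of `lon`/`lat` if the file already holds projected
#'   metres.
#' @param sep field separator (default `,`).
#' @param nominal_interval_h programmed fix interval (h).
#' @param capture_dates optional named vector/list of capture `Date`s per
#'   animal id.
#' @return list of [as_track()] objects, one per animal.
#' @export
read_fixes <- function(path, crs = "EPSG:32609",
                       columns = movebank_columns(), sep = ",",
                       nominal_interval_h = 2, capture_dates = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  geographic <- !is.null(columns$lon)
  need <- c(columns$animal_id, columns$timestamp,
            if (geographic) c(columns$lon, columns$lat)
            else c(columns$x, columns$y))
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("input lacks mapped columns: ", paste(missing_cols, collapse = ", "))
  }

  id <- raw[[columns$animal_id]]
  t <- parse_timestamps(raw[[columns$timestamp]])
  if (geographic) {
    c1 <- suppressWarnings(as.numeric(raw[[columns$lon]]))
    c2 <- suppressWarnings(as.numeric(raw[[columns$lat]]))
  } else {
    c1 <- suppressWarnings(as.numeric(raw[[columns$x]]))
    c2 <- suppressWarnings(as.numeric(raw[[columns$y]]))
  }
  sats <- if (!is.null(columns$n_sats) && columns$n_sats %in% names(raw)) {
    suppressWarnings(as.numeric(raw[[columns$n_sats]]))
  } else {
    rep(NA_real_, nrow(raw))
  }

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(t)] <- "unparseable_timestamp"
  bad_coord <- is.na(reason) & (!is.finite(c1) | !is.finite(c2))
  reason[bad_coord] <- "unparseable_coordinate"
  ok <- is.na(reason)
  if (!any(ok)) stop("no valid records in ", path)

  df <- data.frame(animal_id = id, t = t, n_sats = sats,
                   stringsAsFactors = FALSE)
  if (geographic) {
    df$lon <- c1
    df$lat <- c2
    xy <- data.frame(x = rep(NA_real_, nrow(df)), y = NA_real_)
    xy[ok, ] <- lonlat_to_utm(c1[ok], c2[ok], crs)
    df$x <- xy$x
    df$y <- xy$y
  } else {
    df$x <- c1
    df$y <- c2
    df$lon <- NA_real_
    df$lat <- NA_real_
  }
  df$elev_m <- NA_real_
  df$qc_flag <- reason

  lapply(split(seq_len(nrow(df)), df$animal_id), function(idx) {
    sub <- df[idx, , drop = FALSE]
    rej <- sub[!is.na(sub$qc_flag), , drop = FALSE]
    sub <- sub[is.na(sub$qc_flag), , drop = FALSE]
    cd <- if (!is.null(capture_dates)) {
      as.Date(capture_dates[[sub$animal_id[1]]])
    } else {
      NULL
    }
    tr <- as_track(sub, crs = crs, capture_date = cd,
                   nominal_interval_h = nominal_interval_h)
    attr(tr, "rejected") <- rbind(attr(tr, "rejected"), rej)
    tr
  })
}

#' Write cleaned fixes (retained + rejected) as delimited text
#'
#' @param tracks list of tracks.
#' @param path output CSV; rejected fixes appear with their `qc_flag` set.
#' @export
write_fixes <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    rbind(as.data.frame(tr), rejected_fixes(tr))
  })
  out <- do.call(rbind, rows)
  out$t <- format(out$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Clean a track
#'
#' Applies, in order: (1) removal of fixes within `post_capture_days` of the
#' capture date (capture effects); (2) removal of fixes with
#' `n_sats <= min_sats_exclusive` (poor satellite geometry); (3) a forward
#' speed filter dropping any fix whose straight-line speed from the previous
#' *retained* fix exceeds `max_speed_kmh`, so a removed spike is never used
#' as the reference for the next fix. Every removal is recorded with a
#' reason in [rejected_fixes()]. If fewer than `min_fixes` fixes survive the
#' animal is flagged unusable (see [is_unusable()]) but no error is raised.
#'
#' If the satellite column is entirely missing that filter is skipped with a
#' warning (older collars do not report it).
#'
#' @param track a `sheep_track`.
#' @param capture_date Date of capture; defaults to the track's attribute.
#' @param cfg the `cleaning` section of [default_config()].
#' @return the cleaned track.
#' @export
clean_track <- function(track, capture_date = NULL,
                        cfg = default_config()$cleaning) {
  capture_date <- capture_date %||% attr(track, "capture_date")
  keep <- as.Date(track$t, tz = "UTC") >=
    capture_date + cfg$post_capture_days
  track <- track_keep(track, keep, "post_capture_window")

  if (all(is.na(track$n_sats))) {
    if (nrow(track)) {
      warning("track ", track$animal_id[1],
              ": no satellite counts; satellite filter skipped")
    }
  } else {
    keep <- is.na(track$n_sats) | track$n_sats > cfg$min_sats_exclusive
    track <- track_keep(track, keep, "low_satellite_count")
  }

  # forward speed filter against the previous retained fix
  n <- nrow(track)
  if (n > 1) {
    keep <- rep(TRUE, n)
    ref <- 1
    for (i in 2:n) {
      dt_h <- as.numeric(difftime(track$t[i], track$t[ref], units = "hours"))
      d_km <- sqrt((track$x[i] - track$x[ref])^2 +
                     (track$y[i] - track$y[ref])^2) / 1000
      if (dt_h > 0 && d_km / dt_h > cfg$max_speed_kmh) {
        keep[i] <- FALSE
      } else {
        ref <- i
      }
    }
    track <- track_keep(track, keep, "speed_exceeds_max")
  }

  if (nrow(track) < cfg$min_fixes) attr(track, "unusable") <- TRUE
  track
}

#' Is a track's time coverage adequate for a full migration cycle?
#'
#' TRUE iff the data start at least 30 days before the spring migration and
#' end at least 90 days after the fall migration. Residents (NULL dates) are
#' adequate whenever the track spans at least a year.
#'
#' @param track a `sheep_track`.
#' @param spring_start,fall_end migration `Date`s, or NULL for residents.
#' @return logical.
#' @export
coverage_adequate <- function(track, spring_start, fall_end) {
  first <- as.Date(min(track$t), tz = "UTC")
  last <- as.Date(max(track$t), tz = "UTC")
  if (is.null(spring_start) || is.null(fall_end)) {
    return(as.numeric(last - first) >= 365)
  }
  first <= spring_start - 30 && last >= fall_end + 90
}

#' Annotate a track with DEM elevations
#'
#' Nearest-cell sampling, no interpolation. Fixes outside the DEM keep
#' `elev_m = NA` and get a `outside_dem` qc flag (they stay in the track but
#' are excluded from elevation analyses).
#'
#' @param track a `sheep_track`.
#' @param dem a [dem_raster()].
#' @return the track with `elev_m` filled.
#' @export
annotate_elevation <- function(track, dem) {
  track$elev_m <- dem_lookup(dem, track$x, track$y)
  out <- is.na(track$elev_m)
  if (any(out)) {
    track$qc_flag[out] <- "outside_dem"
  }
  bad <- !is.na(track$elev_m) &
    (track$elev_m < -430 | track$elev_m > 9000)
  if (any(bad)) stop("implausible DEM elevations encountered")
  track
}
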