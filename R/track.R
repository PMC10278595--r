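# The track container: one animal's ordered GPS fixes in a metric CRS.
#
# A `sheep_track` is a data.frame with one row per retained fix and columns
#   animal_id, t (POSIXct UTC), x, y (m), lon, lat (degrees, if known),
#   n_sats (integer, may be NA), elev_m (m, NA until annotated),
#   qc_flag (NA for clean fixes)
# plus attributes: capture_date (Date), crs, nominal_interval_h, and
# `rejected`, a data.frame of dropped fixes with their qc_flag reasons, so
# that retained + rejected always accounts for every input record.

#' Construct a track from a fix data.frame
#'
#' @param df data.frame with at least `animal_id`, `t`, `x`, `y`.
#' @param crs metric CRS id.
#' @param capture_date Date of collaring (defaults to the first fix's date).
#' @param nominal_interval_h programmed fix interval in hours (1 or 2).
#' @param dedupe collapse duplicate timestamps to the first record, flagging
#'   the rest (default TRUE).
#' @return a `sheep_track`.
#' @export
as_track <- function(df, crs = "EPSG:32609", capture_date = NULL,
                     nominal_interval_h = 2, dedupe = TRUE) {
  need <- c("animal_id", "t", "x", "y")
  stopifnot(all(need %in% names(df)))
  if (!inherits(df$t, "POSIXct")) stop("column t must be POSIXct")
  for (col in c("lon", "lat", "n_sats", "elev_m")) {
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  }
  if (is.null(df$qc_flag)) df$qc_flag <- NA_character_
  df <- df[order(df$t), , drop = FALSE]
  rejected <- df[0, , drop = FALSE]
  if (dedupe && anyDuplicated(df$t)) {
    dup <- duplicated(df$t)
    rej <- df[dup, , drop = FALSE]
    rej$qc_flag <- "duplicate_timestamp"
    rejected <- rej
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df,
            class = c("sheep_track", "data.frame"),
            capture_date = capture_date %||%
              as.Date(df$t[1], tz = "UTC"),
            crs = crs,
            nominal_interval_h = nominal_interval_h,
            rejected = rejected,
            unusable = FALSE)
}

#' @export
print.sheep_track <- function(x, ...) {
  cat(sprintf(
    "<sheep_track> %s: %d fixes (%d rejected), %s to %s, CRS %s\n",
    x$animal_id[1], nrow(x), nrow(attr(x, "rejected")),
    format(min(x$t), "%Y-%m-%d"), format(max(x$t), "%Y-%m-%d"),
    attr(x, "crs")))
  invisible(x)
}

#' Fixes rejected during ingest/cleaning
#' @param track a `sheep_track`.
#' @return data.frame of dropped fixes with `qc_flag` reasons.
#' @export
rejected_fixes <- function(track) attr(track, "rejected")

#' Was the animal flagged unusable by cleaning?
#' @param track a `sheep_track`.
#' @export
is_unusable <- function(track) isTRUE(attr(track, "unusable"))

# carry attributes through subsetting done inside the package
#' @keywords internal
track_keep <- function(track, keep, reason) {
  rej <- as.data.frame(track)[!keep, , drop = FALSE]
  if (nrow(rej)) rej$qc_flag <- reason
  out <- as.data.frame(track)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attrs <- attributes(track)
  structure(out,
            class = c("sheep_track", "data.frame"),
            capture_date = attrs$capture_date,
            crs = attrs$crs,
            nominal_interval_h = attrs$nominal_interval_h,
            rejected = rbind(attrs$rejected, rej),
            unusable = attrs$unusable)
}

#' @keywords internal
track_window <- function(track, from_date, to_date) {
  d <- as.Date(track$t, tz = "UTC")
  as.data.frame(track)[d >= from_date & d <= to_date, , drop = FALSE]
}
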