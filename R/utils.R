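# Small numeric helpers shared across modules.

#' Round half away from zero
#'
#' Base [round()] rounds halves to even; date arithmetic in this package
#' follows the plain "round half up" convention so that e.g. an interpolated
#' percentile of 1.98 days becomes 2 days.
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, halves away from zero.
#' @keywords internal
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Linear-interpolated percentile (type 7)
#'
#' @param x numeric vector (NAs dropped).
#' @param p probability in \[0, 1\].
#' @keywords internal
pctile <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 7, na.rm = TRUE))
}

#' Centred rolling median that tolerates missing days
#'
#' @param x numeric vector on a regular (e.g. daily) grid, NA for gaps.
#' @param k odd window width.
#' @return vector of window medians; NA where the window holds no data.
#' @keywords internal
roll_median <- function(x, k = 3) {
  stopifnot(k %% 2 == 1)
  h <- (k - 1) / 2
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- x[max(1, i - h):min(n, i + h)]
    if (any(!is.na(w))) out[i] <- stats::median(w, na.rm = TRUE)
  }
  out
}

#' Asymmetric rolling mean over a day grid
#'
#' Window covers `before` days behind up to `after` days ahead of each day
#' (inclusive), mirroring a 14-day moving window centred between days -7 and
#' +6.
#'
#' @keywords internal
roll_mean_window <- function(x, before = 7, after = 6) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- x[max(1, i - before):min(n, i + after)]
    if (any(!is.na(w))) out[i] <- mean(w, na.rm = TRUE)
  }
  out
}

#' Maximal runs of TRUE in a logical vector
#'
#' @param x logical vector (NA treated as FALSE).
#' @return data.frame with columns `start`, `end`, `length` (indices).
#' @keywords internal
true_runs <- function(x) {
  x <- !is.na(x) & x
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

#' Derive a reproducible child seed from a master seed
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @keywords internal
child_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1103L + i * 12721L) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
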