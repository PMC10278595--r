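# Diagnostic figures: NSD curves and elevation-use profiles.

#' Plot a net squared displacement series
#'
#' Daily median NSD (points) with the smoothed series (line) and, when a
#' migration event is supplied, the detected spring/fall dates as dashed
#' verticals — the standard way to eyeball a migrant's plateau.
#'
#' @param series a [compute_nsd()] result.
#' @param event optional `migration_event`.
#' @return a ggplot object.
#' @export
plot_nsd <- function(series, event = NULL) {
  d <- series$daily
  p <- ggplot2::ggplot(d, ggplot2::aes(x = date)) +
    ggplot2::geom_point(ggplot2::aes(y = nsd_km2),
                        size = 0.4, colour = "grey55", na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = smoothed_km2),
                       colour = "steelblue", na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = expression(NSD ~ (km^2)),
                  title = series$animal_id) +
    ggplot2::theme_minimal()
  if (inherits(event, "migration_event")) {
    dates <- c(event$spring_start, event$spring_end, event$fall_start,
               event$fall_end)
    p <- p + ggplot2::geom_vline(xintercept = as.numeric(dates),
                                 linetype = "dashed", colour = "tomato")
  }
  p
}

#' Plot an elevation-use profile
#'
#' Daily mean elevations with the 14-day moving mean and the seasonal
#' medians as horizontal references.
#'
#' @param series an [elevation_series()] result.
#' @return a ggplot object.
#' @export
plot_elevation <- function(series) {
  d <- series$daily
  ggplot2::ggplot(d, ggplot2::aes(x = date)) +
    ggplot2::geom_point(ggplot2::aes(y = mean_m),
                        size = 0.4, colour = "grey55", na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = moving_m),
                       colour = "darkgreen", na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = c(series$winter_median_m,
                                       series$summer_median_m),
                        linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "elevation (m)",
                  title = series$animal_id) +
    ggplot2::theme_minimal()
}
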