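# Migration corridors, route distances and stopover sites.

#' Estimate a migration corridor UD
#'
#' Brownian bridge UD over the fixes inside the migration window padded by
#' 24 h on both sides (the padding anchors the bridges to the seasonal
#' ranges). The 95% isopleth is attached.
#'
#' @param track a `sheep_track`.
#' @param event a `migration_event`.
#' @param season `"spring"` or `"fall"`.
#' @param cfg full [default_config()]-shaped config.
#' @return object of class `corridor`: `animal_id`, `season`, `ud`
#'   (`ud_surface`), `poly95` (`range_polygon`), `route_distance_km`.
#' @export
corridor_ud <- function(track, event, season = c("spring", "fall"),
                        cfg = default_config()) {
  season <- match.arg(season)
  if (season == "fall" && is.null(event$fall_end)) {
    stop("fall migration not dated (truncated series)")
  }
  win <- if (season == "spring") {
    c(event$spring_start, event$spring_end)
  } else {
    c(event$fall_start, event$fall_end)
  }
  pad_s <- cfg$corridors$pad_h * 3600
  t_lo <- as.POSIXct(paste(win[1], "00:00:00"), tz = "UTC") - pad_s
  t_hi <- as.POSIXct(paste(win[2], "23:59:59"), tz = "UTC") + pad_s
  sel <- track$t >= t_lo & track$t <= t_hi
  if (sum(sel) < 4) stop("fewer than 4 fixes in the padded corridor window")
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
  structure(list(animal_id = track$animal_id[1], season = season,
                 ud = ud, poly95 = isopleth(ud, cfg$ranges$ud_q),
                 sigma1_m = est$sigma1_m,
                 route_distance_km = route_distance(track, event, season),
                 window = win),
            class = "corridor")
}

#' @export
print.corridor <- function(x, ...) {
  cat(sprintf("<corridor> %s %s: %.1f km, 95%% area %.1f ha\n",
              x$animal_id, x$season, x$route_distance_km,
              x$poly95$area_ha))
  invisible(x)
}

#' Route distance of a migration leg
#'
#' Cumulative straight-line step length over the time-ordered fixes with
#' dates inside the migration window (no padding). The detector brackets
#' each leg with one boundary day spent inside the adjacent residence
#' range (the spring start date is the last day still at winter, the fall
#' end date the first day back), so that residence-side boundary day
#' contributes only its departure (spring) or arrival (fall) fix — a full
#' day of residence jitter is foraging, not route. A single-fix window
#' returns 0 with a warning.
#'
#' @param track a `sheep_track`.
#' @param event a `migration_event`.
#' @param season `"spring"` or `"fall"`.
#' @return distance in km.
#' @export
route_distance <- function(track, event, season = c("spring", "fall")) {
  season <- match.arg(season)
  win <- if (season == "spring") {
    c(event$spring_start, event$spring_end)
  } else {
    c(event$fall_start, event$fall_end)
  }
  day <- as.Date(track$t, tz = "UTC")
  idx <- which(day >= win[1] & day <= win[2])
  if (length(idx) >= 2 && length(unique(day[idx])) > 1) {
    d <- day[idx]
    if (season == "spring") {
      idx <- idx[max(which(d == d[1])):length(idx)]
    } else {
      idx <- idx[1:min(which(d == d[length(d)]))]
    }
  }
  if (length(idx) < 2) {
    warning("migration window holds < 2 fixes; distance 0")
    return(0)
  }
  x <- track$x[idx]
  y <- track$y[idx]
  sum(sqrt(diff(x)^2 + diff(y)^2)) / 1000
}

#' The per-animal reported migration distance
#'
#' The study reports one distance per female; which leg supplies it is a
#' config choice (default the spring leg, falling back to fall when spring
#' is missing).
#'
#' @param spring_km,fall_km leg distances (NA when missing).
#' @param rule `"spring"`, `"fall"`, `"max"` or `"mean"`.
#' @return km.
#' @export
reported_distance <- function(spring_km, fall_km, rule = "spring") {
  v <- switch(rule,
    spring = if (!is.na(spring_km)) spring_km else fall_km,
    fall = if (!is.na(fall_km)) fall_km else spring_km,
    max = max(spring_km, fall_km, na.rm = TRUE),
    mean = mean(c(spring_km, fall_km), na.rm = TRUE),
    stop("unknown distance rule: ", rule))
  v
}

# connected components of a cell set (rook adjacency)
#' @keywords internal
cell_components <- function(ix, iy) {
  n <- length(ix)
  key <- paste(ix, iy)
  idx <- stats::setNames(seq_len(n), key)
  comp <- rep(0L, n)
  nc <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    nc <- nc + 1L
    queue <- s
    comp[s] <- nc
    while (length(queue)) {
      k <- queue[[1]]
      queue <- queue[-1]
      nb <- idx[c(paste(ix[k] + 1, iy[k]), paste(ix[k] - 1, iy[k]),
                  paste(ix[k], iy[k] + 1), paste(ix[k], iy[k] - 1))]
      nb <- nb[!is.na(nb)]
      nb <- nb[comp[nb] == 0L]
      if (length(nb)) {
        comp[nb] <- nc
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

# minimum edge-to-edge distance between two cell sets (m)
#' @keywords internal
cellset_gap_m <- function(a_ix, a_iy, b_ix, b_iy, cell_m) {
  dx <- outer(a_ix, b_ix, function(p, q) pmax(abs(p - q) - 1, 0))
  dy <- outer(a_iy, b_iy, function(p, q) pmax(abs(p - q) - 1, 0))
  min(sqrt((dx * cell_m)^2 + (dy * cell_m)^2))
}

#' Extract stopover sites from a migration corridor
#'
#' (1) Take the `stopover_q` (default 10%) isopleth of the corridor UD;
#' (2) split it into connected components; (3) drop components that
#' intersect the animal's summer or winter 95% range; (4) compute each
#' component's occupancy as the sum of inter-fix intervals whose midpoint
#' fix lies inside, and drop components under `stopover_min_h` (12 h);
#' (5) iteratively merge surviving components whose nearest cell edges are
#' closer than `stopover_merge_m` (300 m) until stable. The result is
#' deterministic and independent of component order.
#'
#' @param corridor a [corridor_ud()] result.
#' @param track the animal's `sheep_track`.
#' @param winter_range,summer_range the seasonal 95% `range_polygon`s.
#' @param cfg the `corridors` config section.
#' @return list of `stopover_site`s: cell sets with `occupancy_h`,
#'   `centroid`, `area_ha`.
#' @export
extract_stopovers <- function(corridor, track, winter_range, summer_range,
                              cfg = default_config()$corridors) {
  top <- isopleth(corridor$ud, cfg$stopover_q)
  cell_m <- top$cell_m
  comp <- cell_components(top$ix, top$iy)
  sets <- lapply(seq_len(max(comp, 0)), function(k) {
    list(ix = top$ix[comp == k], iy = top$iy[comp == k])
  })

  # (3) drop components touching either seasonal range
  range_keys <- c(paste(winter_range$ix, winter_range$iy),
                  paste(summer_range$ix, summer_range$iy))
  sets <- Filter(function(s) {
    !any(paste(s$ix, s$iy) %in% range_keys)
  }, sets)
  if (!length(sets)) return(list())

  # (4) occupancy by interval midpoints, fixes in the padded window
  t_lo <- as.POSIXct(paste(corridor$window[1], "00:00:00"), tz = "UTC") -
    86400
  t_hi <- as.POSIXct(paste(corridor$window[2], "23:59:59"), tz = "UTC") +
    86400
  sel <- which(track$t >= t_lo & track$t <= t_hi)
  tx <- track$x[sel]
  ty <- track$y[sel]
  ts <- as.numeric(track$t[sel])
  # half-interval weight on each side of every fix
  w_h <- (c(0, diff(ts)) + c(diff(ts), 0)) / 2 / 3600
  fix_key <- paste(floor(tx / cell_m), floor(ty / cell_m))
  occupancy <- function(s) {
    sum(w_h[fix_key %in% paste(s$ix, s$iy)])
  }
  sets <- Filter(function(s) occupancy(s) >= cfg$stopover_min_h, sets)
  if (!length(sets)) return(list())

  # (5) merge nearest-border distances < stopover_merge_m, to fixed point
  repeat {
    merged <- FALSE
    if (length(sets) > 1) {
      for (i in 1:(length(sets) - 1)) {
        for (j in (i + 1):length(sets)) {
          if (cellset_gap_m(sets[[i]]$ix, sets[[i]]$iy,
                            sets[[j]]$ix, sets[[j]]$iy, cell_m) <
                cfg$stopover_merge_m) {
            sets[[i]] <- list(ix = c(sets[[i]]$ix, sets[[j]]$ix),
                              iy = c(sets[[i]]$iy, sets[[j]]$iy))
            sets[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }

  lapply(sets, function(s) {
    structure(list(
      ix = s$ix, iy = s$iy, cell_m = cell_m,
      occupancy_h = occupancy(s),
      area_ha = length(s$ix) * cell_m^2 / 1e4,
      centroid = c(x = mean((s$ix + 0.5) * cell_m),
                   y = mean((s$iy + 0.5) * cell_m))
    ), class = "stopover_site")
  })
}

#' @export
print.stopover_site <- function(x, ...) {
  cat(sprintf("<stopover_site> %.1f ha, %.1f h occupancy at (%.0f, %.0f)\n",
              x$area_ha, x$occupancy_h, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Combine the corridors of a band's migrants
#'
#' Cell-wise mean of the member corridor UDs on the shared grid
#' registration, renormalized; the 95% isopleth is attached. A single
#' member returns its own corridor unchanged (idempotent).
#'
#' @param corridors list of [corridor_ud()] results (>= 1).
#' @param q isopleth level for the combined polygon.
#' @return list with `ud` (a `ud_surface` on the union grid) and `poly95`.
#' @export
band_corridor <- function(corridors, q = 0.95) {
  stopifnot(length(corridors) >= 1)
  uds <- lapply(corridors, `[[`, "ud")
  cell <- uds[[1]]$cell_m
  if (!all(vapply(uds, function(u) u$cell_m == cell, logical(1)))) {
    stop("grid registration mismatch")
  }
  x0 <- min(vapply(uds, `[[`, numeric(1), "x0"))
  y0 <- min(vapply(uds, `[[`, numeric(1), "y0"))
  nx <- max(vapply(uds, function(u) (u$x0 - x0) / cell + u$nx, numeric(1)))
  ny <- max(vapply(uds, function(u) (u$y0 - y0) / cell + u$ny, numeric(1)))
  z <- matrix(0, nx, ny)
  for (u in uds) {
    i0 <- (u$x0 - x0) / cell
    j0 <- (u$y0 - y0) / cell
    z[(i0 + 1):(i0 + u$nx), (j0 + 1):(j0 + u$ny)] <-
      z[(i0 + 1):(i0 + u$nx), (j0 + 1):(j0 + u$ny)] + u$z
  }
  z <- z / sum(z)
  ud <- structure(list(x0 = x0, y0 = y0, nx = nx, ny = ny, cell_m = cell,
                       z = z,
                       n_fixes = sum(vapply(uds, `[[`, numeric(1),
                                            "n_fixes")),
                       n_bridges = sum(vapply(uds, `[[`, numeric(1),
                                              "n_bridges")),
                       params = uds[[1]]$params),
                  class = "ud_surface")
  list(ud = ud, poly95 = isopleth(ud, q))
}
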