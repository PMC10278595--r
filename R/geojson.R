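# Minimal GeoJSON output for cell-set geometries.

# merge a cell set into row-run rectangles (fewer polygons than one square
# per cell)
cell_rectangles <- function(ix, iy, cell_m) {
  o <- order(iy, ix)
  ix <- ix[o]
  iy <- iy[o]
  newrun <- c(TRUE, diff(ix) != 1 | diff(iy) != 0)
  run_id <- cumsum(newrun)
  lapply(split(seq_along(ix), run_id), function(idx) {
    x0 <- ix[idx[1]] * cell_m
    x1 <- (ix[idx[length(idx)]] + 1) * cell_m
    y0 <- iy[idx[1]] * cell_m
    y1 <- (iy[idx[1]] + 1) * cell_m
    list(list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)))
  })
}

#' Write cell-set geometries (ranges, corridors, stopovers) as GeoJSON
#'
#' Each geometry becomes a MultiPolygon feature of cell-run rectangles in
#' lon/lat (WGS84), with `q`, `area_ha` and occupancy properties where
#' available.
#'
#' @param geoms named list of `range_polygon` / `stopover_site` objects.
#' @param path output `.geojson` file.
#' @param crs the metric CRS the cell indices refer to.
#' @export
write_geojson <- function(geoms, path, crs = "EPSG:32609") {
  features <- lapply(seq_along(geoms), function(k) {
    g <- geoms[[k]]
    rects <- cell_rectangles(g$ix, g$iy, g$cell_m)
    rects_ll <- lapply(rects, function(poly) {
      ring <- do.call(rbind, poly[[1]])
      ll <- utm_to_lonlat(ring[, 1], ring[, 2], crs)
      list(lapply(seq_len(nrow(ll)), function(i) {
        c(round(ll$lon[i], 6), round(ll$lat[i], 6))
      }))
    })
    props <- list(name = names(geoms)[k] %||% paste0("geom", k),
                  area_ha = g$area_ha)
    if (!is.null(g$q)) props$q <- g$q
    if (!is.null(g$occupancy_h)) props$occupancy_h <- g$occupancy_h
    list(type = "Feature", properties = props,
         geometry = list(type = "MultiPolygon", coordinates = rects_ll))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
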