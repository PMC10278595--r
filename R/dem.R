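# Digital elevation model: a minimal single-band metric grid.
#
# The container mirrors what the pipeline needs from a 20 m elevation
# product: origin, square cell size, a value matrix and a nodata sentinel.
# On disk it round-trips through the plain-text ESRI ASCII grid format
# (.asc), which any GIS reads.

#' Construct a DEM raster
#'
#' @param z numeric matrix of elevations (m); `z[i, j]` is the cell whose
#'   centre is at `xmin + (i - 0.5) * cell_m`, `ymin + (j - 0.5) * cell_m`
#'   (column index j increases northwards).
#' @param xmin,ymin lower-left corner of the grid (m).
#' @param cell_m cell size (m), > 0.
#' @param crs CRS identifier the coordinates live in.
#' @return object of class `dem_raster`.
#' @export
dem_raster <- function(z, xmin, ymin, cell_m, crs = "EPSG:32609") {
  stopifnot(is.matrix(z), cell_m > 0)
  structure(
    list(z = z, xmin = xmin, ymin = ymin, cell_m = cell_m,
         nx = nrow(z), ny = ncol(z), crs = crs),
    class = "dem_raster"
  )
}

#' @export
print.dem_raster <- function(x, ...) {
  cat(sprintf("<dem_raster> %d x %d cells of %g m, origin (%.0f, %.0f)\n",
              x$nx, x$ny, x$cell_m, x$xmin, x$ymin))
  cat(sprintf("  elevation range: %.1f to %.1f m\n",
              min(x$z, na.rm = TRUE), max(x$z, na.rm = TRUE)))
  invisible(x)
}

#' Build a synthetic DEM
#'
#' Three archetypes used by the track simulator: `flat` (constant 1500 m),
#' `ramp` (linear in x), and `ridge` (a one-dimensional Gaussian ridge
#' running north-south, high enough and steep enough to support both the
#' traditional and the abbreviated altitudinal movement archetypes).
#'
#' @param kind `"flat"`, `"ramp"` or `"ridge"`.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in metres; must cover
#'   every coordinate that will be sampled.
#' @param cell_m cell size in metres (default 20, matching the national
#'   20 m product).
#' @param base base elevation (m).
#' @param slope ramp slope (m elevation per m of x) for `kind = "ramp"`.
#' @param crest ridge height above `base` (m) for `kind = "ridge"`.
#' @param ridge_x x coordinate of the ridge crest line (m); default the
#'   extent midline.
#' @param ridge_width Gaussian half-width of the ridge (m).
#' @param crs CRS identifier.
#' @return a [dem_raster()].
#' @export
#' @examples
#' d <- make_dem("ridge", c(0, 4000, 0, 4000), cell_m = 40)
#' range(d$z)
make_dem <- function(kind = c("flat", "ramp", "ridge"),
                     extent, cell_m = 20, base = 700, slope = 0.01,
                     crest = 1100, ridge_x = NULL, ridge_width = 1500,
                     crs = "EPSG:32609") {
  kind <- match.arg(kind)
  nx <- ceiling((extent[2] - extent[1]) / cell_m)
  ny <- ceiling((extent[4] - extent[3]) / cell_m)
  xc <- extent[1] + (seq_len(nx) - 0.5) * cell_m
  yc <- extent[3] + (seq_len(ny) - 0.5) * cell_m
  z <- switch(kind,
    flat = matrix(1500, nx, ny),
    ramp = matrix(base + slope * xc, nx, ny),
    ridge = {
      if (is.null(ridge_x)) ridge_x <- (extent[1] + extent[2]) / 2
      matrix(base + crest * exp(-(xc - ridge_x)^2 / (2 * ridge_width^2)),
             nx, ny)
    }
  )
  dem_raster(z, extent[1], extent[3], cell_m, crs)
}

#' Nearest-cell elevation lookup
#'
#' No interpolation: each point takes the value of the cell containing it,
#' matching the granularity of the 20 m source product. Points outside the
#' grid return NA.
#'
#' @param dem a [dem_raster()].
#' @param x,y point coordinates (m).
#' @return numeric vector of elevations (m), NA outside the DEM.
#' @export
dem_lookup <- function(dem, x, y) {
  i <- floor((x - dem$xmin) / dem$cell_m) + 1
  j <- floor((y - dem$ymin) / dem$cell_m) + 1
  ok <- i >= 1 & i <= dem$nx & j >= 1 & j <= dem$ny &
    is.finite(x) & is.finite(y)
  out <- rep(NA_real_, length(x))
  out[ok] <- dem$z[cbind(i[ok], j[ok])]
  out
}

#' Write a DEM as an ESRI ASCII grid
#'
#' @param dem a [dem_raster()].
#' @param path output file (conventionally `.asc`).
#' @param nodata sentinel written for NA cells.
#' @export
write_dem_asc <- function(dem, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", dem$nx),
    sprintf("nrows %d", dem$ny),
    sprintf("xllcorner %.6f", dem$xmin),
    sprintf("yllcorner %.6f", dem$ymin),
    sprintf("cellsize %.6f", dem$cell_m),
    sprintf("NODATA_value %g", nodata)
  ), con)
  z <- dem$z
  z[is.na(z)] <- nodata
  # rows from north to south
  for (j in rev(seq_len(dem$ny))) {
    writeLines(paste(formatC(z[, j], format = "g", digits = 10),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Write a utilization distribution as an ESRI ASCII grid
#'
#' Cell values are probability mass per 50 m cell.
#'
#' @param ud a `ud_surface` from [compute_ud()].
#' @param path output file (conventionally `.asc`).
#' @export
write_ud_asc <- function(ud, path) {
  write_dem_asc(dem_raster(ud$z, ud$x0, ud$y0, ud$cell_m), path)
}

#' Read an ESRI ASCII grid DEM
#'
#' @param path `.asc` file.
#' @param crs CRS identifier to attach.
#' @return a [dem_raster()].
#' @export
read_dem_asc <- function(path, crs = "EPSG:32609") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  nx <- as.integer(hdr$ncols)
  ny <- as.integer(hdr$nrows)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nx * ny) stop("ASCII grid size mismatch")
  z <- matrix(NA_real_, nx, ny)
  for (j in seq_len(ny)) {
    z[, ny - j + 1] <- vals[((j - 1) * nx + 1):(j * nx)]
  }
  if (!is.null(hdr$nodata_value)) z[z == hdr$nodata_value] <- NA
  dem_raster(z, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, crs)
}
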