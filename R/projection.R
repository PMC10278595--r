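# Geographic <-> metric coordinate transforms.
#
# All pipeline geometry lives in a single metric CRS (a UTM zone) so that
# areas come out in hectares and distances in metres.  The transverse
# Mercator forward/inverse below follows the Krueger series in terms of the
# third flattening (the formulation used by GeographicLib), which is accurate
# to well under a millimetre across a UTM zone; the inverse recovers latitude
# from the conformal latitude by fixed-point iteration.

# WGS84
.wgs84 <- list(a = 6378137, f = 1 / 298.257223563)

.tm_consts <- local({
  f <- .wgs84$f
  n <- f / (2 - f)
  A <- .wgs84$a / (1 + n) * (1 + n^2 / 4 + n^4 / 64 + n^6 / 256)
  alpha <- c(
    n / 2 - 2 * n^2 / 3 + 5 * n^3 / 16 + 41 * n^4 / 180,
    13 * n^2 / 48 - 3 * n^3 / 5 + 557 * n^4 / 1440,
    61 * n^3 / 240 - 103 * n^4 / 140,
    49561 * n^4 / 161280
  )
  beta <- c(
    n / 2 - 2 * n^2 / 3 + 37 * n^3 / 96 - n^4 / 360,
    n^2 / 48 + n^3 / 15 - 437 * n^4 / 1440,
    17 * n^3 / 480 - 37 * n^4 / 840,
    4397 * n^4 / 161280
  )
  e <- sqrt(f * (2 - f))
  list(n = n, A = A, alpha = alpha, beta = beta, e = e, k0 = 0.9996,
       FE = 500000, FN_south = 10000000)
})

#' Parse a UTM CRS identifier
#'
#' Accepts `"EPSG:326xx"` (northern hemisphere) and `"EPSG:327xx"`
#' (southern); returns zone and hemisphere.
#' @keywords internal
parse_utm_crs <- function(crs) {
  m <- regmatches(crs, regexec("^EPSG:(32[67])([0-9]{2})$", crs))[[1]]
  if (length(m) != 3) {
    stop("unsupported CRS '", crs, "'; expected a UTM code like EPSG:32609")
  }
  list(zone = as.integer(m[3]), north = m[2] == "326")
}

#' Project lon/lat (WGS84 degrees) to UTM metres
#'
#' @param lon,lat numeric vectors in degrees.
#' @param crs UTM CRS id such as `"EPSG:32609"`.
#' @return data.frame with columns `x`, `y` in metres.
#' @export
#' @examples
#' lonlat_to_utm(-129.8, 59.3, "EPSG:32609")
lonlat_to_utm <- function(lon, lat, crs) {
  z <- parse_utm_crs(crs)
  cc <- .tm_consts
  lam0 <- (z$zone * 6 - 183) * pi / 180
  phi <- lat * pi / 180
  lam <- lon * pi / 180 - lam0
  e <- cc$e
  # conformal latitude
  t0 <- sinh(atanh(sin(phi)) - e * atanh(e * sin(phi)))
  xi_p <- atan2(t0, cos(lam))
  eta_p <- asinh(sin(lam) / sqrt(t0^2 + cos(lam)^2))
  xi <- xi_p
  eta <- eta_p
  for (j in 1:4) {
    xi  <- xi  + cc$alpha[j] * sin(2 * j * xi_p) * cosh(2 * j * eta_p)
    eta <- eta + cc$alpha[j] * cos(2 * j * xi_p) * sinh(2 * j * eta_p)
  }
  x <- cc$FE + cc$k0 * cc$A * eta
  y <- cc$k0 * cc$A * xi + if (z$north) 0 else cc$FN_south
  data.frame(x = x, y = y)
}

#' Inverse-project UTM metres to lon/lat (WGS84 degrees)
#'
#' @param x,y numeric vectors in metres.
#' @param crs UTM CRS id such as `"EPSG:32609"`.
#' @return data.frame with columns `lon`, `lat` in degrees.
#' @export
utm_to_lonlat <- function(x, y, crs) {
  z <- parse_utm_crs(crs)
  cc <- .tm_consts
  lam0 <- (z$zone * 6 - 183) * pi / 180
  if (!z$north) y <- y - cc$FN_south
  xi <- y / (cc$k0 * cc$A)
  eta <- (x - cc$FE) / (cc$k0 * cc$A)
  xi_p <- xi
  eta_p <- eta
  for (j in 1:4) {
    xi_p  <- xi_p  - cc$beta[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    eta_p <- eta_p - cc$beta[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }
  tau_p <- sin(xi_p) / sqrt(sinh(eta_p)^2 + cos(xi_p)^2)
  lam <- atan2(sinh(eta_p), cos(xi_p))
  chi <- atan(tau_p)
  e <- cc$e
  # latitude from conformal latitude, fixed point (converges in ~5 steps)
  phi <- chi
  for (k in 1:10) {
    phi_new <- 2 * atan(tan(pi / 4 + chi / 2) *
                          ((1 + e * sin(phi)) / (1 - e * sin(phi)))^(e / 2)) -
      pi / 2
    if (max(abs(phi_new - phi)) < 1e-14) {
      phi <- phi_new
      break
    }
    phi <- phi_new
  }
  data.frame(lon = (lam + lam0) * 180 / pi, lat = phi * 180 / pi)
}
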