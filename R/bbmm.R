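# Brownian bridge movement model, from first principles.
#
# Between two fixes z_a at time t_a and z_b at t_b (gap T seconds) the
# animal's position at relative time alpha in [0, 1] is modelled as a
# circular Gaussian with
#   mean     (1 - alpha) z_a + alpha z_b
#   variance T alpha (1 - alpha) sigma1^2 + ((1-alpha)^2 + alpha^2) sigma2^2
# where sigma1 (m / sqrt(s)) scales the Brownian motion variance rate and
# sigma2 (m) is the location-error SD. The utilization distribution is the
# time integral of that density over the bridge, averaged over all bridges.
#
# Numerics: the alpha integral is evaluated by a configurable quadrature
# (midpoint or Gauss-Legendre, n_alpha nodes); the spatial accumulation into
# 50 m cells uses the exact separable Gaussian cell integral (differences of
# pnorm at the cell edges), truncated at trunc_sd standard deviations.

#' Brownian bridge parameters
#'
#' @param sigma1_m motion-variance smoothing parameter, m per sqrt(second).
#' @param sigma2_m location-error SD in metres (default 30).
#' @param max_bridge_gap_h bridges across gaps longer than this are skipped.
#' @return object of class `bbmm_params`.
#' @export
bbmm_params <- function(sigma1_m, sigma2_m = 30, max_bridge_gap_h = 24) {
  stopifnot(sigma1_m > 0, sigma2_m >= 0)
  structure(list(sigma1_m = sigma1_m, sigma2_m = sigma2_m,
                 max_bridge_gap_h = max_bridge_gap_h),
            class = "bbmm_params")
}

#' Quadrature nodes and weights on \[0, 1\]
#' @keywords internal
alpha_nodes <- function(n_alpha, rule = c("midpoint", "gauss")) {
  rule <- match.arg(rule)
  if (rule == "midpoint") {
    list(x = (seq_len(n_alpha) - 0.5) / n_alpha,
         w = rep(1 / n_alpha, n_alpha))
  } else {
    g <- pracma::gaussLegendre(n_alpha, 0, 1)
    list(x = g$x, w = g$w)
  }
}

#' Define a UD grid covering a set of fixes
#'
#' Origin is snapped *down* to a multiple of the cell size, so the seasonal
#' and corridor grids of one animal align cell-for-cell and cell sets can be
#' intersected by integer index.
#'
#' @param x,y fix coordinates (m).
#' @param pad_m padding added around the bounding box (m).
#' @param cell_m cell size (m, default 50).
#' @return list with `x0`, `y0`, `nx`, `ny`, `cell_m`.
#' @export
ud_grid <- function(x, y, pad_m, cell_m = 50) {
  x0 <- floor((min(x) - pad_m) / cell_m) * cell_m
  y0 <- floor((min(y) - pad_m) / cell_m) * cell_m
  nx <- ceiling((max(x) + pad_m - x0) / cell_m)
  ny <- ceiling((max(y) + pad_m - y0) / cell_m)
  list(x0 = x0, y0 = y0, nx = nx, ny = ny, cell_m = cell_m)
}

#' Accumulate one bridge's density into a grid
#'
#' Returns the cell-mass increment (summing to 1 up to Gaussian truncation)
#' contributed by the bridge between fixes `a` and `b`.
#'
#' @param xa,ya,xb,yb endpoint coordinates (m).
#' @param gap_s gap in seconds (> 0).
#' @param params a [bbmm_params()].
#' @param grid a [ud_grid()].
#' @param n_alpha number of time-integration nodes.
#' @param alpha_quad `"midpoint"` or `"gauss"`.
#' @param trunc_sd Gaussian truncation radius in SDs.
#' @return `nx` by `ny` matrix of cell masses.
#' @export
bridge_density <- function(xa, ya, xb, yb, gap_s, params, grid,
                           n_alpha = 10, alpha_quad = "midpoint",
                           trunc_sd = 6) {
  stopifnot(gap_s > 0)
  accumulate_bridges(c(xa, xb), c(ya, yb), c(0, gap_s), 1L,
                     params$sigma1_m, params$sigma2_m, grid,
                     alpha_nodes(n_alpha, alpha_quad), trunc_sd,
                     average = FALSE)
}

# Accumulation kernel shared by bridge_density / compute_ud. The matrix is
# created and modified inside one frame so R updates it in place instead of
# copying it for every bridge.
#' @keywords internal
accumulate_bridges <- function(x, y, ts, idx, s1, s2, grid, nodes,
                               trunc_sd, average = TRUE) {
  cell <- grid$cell_m
  z <- matrix(0, grid$nx, grid$ny)
  an <- nodes$x
  aw <- nodes$w
  for (i in idx) {
    xa <- x[i]; ya <- y[i]; xb <- x[i + 1]; yb <- y[i + 1]
    gap_s <- ts[i + 1] - ts[i]
    for (k in seq_along(an)) {
      a <- an[k]
      mux <- (1 - a) * xa + a * xb
      muy <- (1 - a) * ya + a * yb
      s <- sqrt(gap_s * a * (1 - a) * s1^2 + ((1 - a)^2 + a^2) * s2^2)
      r <- trunc_sd * s
      ilo <- max(1L, floor((mux - r - grid$x0) / cell) + 1L)
      ihi <- min(grid$nx, floor((mux + r - grid$x0) / cell) + 1L)
      jlo <- max(1L, floor((muy - r - grid$y0) / cell) + 1L)
      jhi <- min(grid$ny, floor((muy + r - grid$y0) / cell) + 1L)
      if (ilo > ihi || jlo > jhi) next
      ex <- grid$x0 + (seq.int(ilo - 1L, ihi)) * cell
      ey <- grid$y0 + (seq.int(jlo - 1L, jhi)) * cell
      px <- diff(stats::pnorm(ex, mux, s))
      py <- diff(stats::pnorm(ey, muy, s))
      z[ilo:ihi, jlo:jhi] <- z[ilo:ihi, jlo:jhi] + aw[k] * outer(px, py)
    }
  }
  if (average) z / length(idx) else z
}

#' Estimate the motion-variance parameter sigma1 by leave-one-out likelihood
#'
#' Every even-positioned fix is withheld and scored under the bridge density
#' implied by its two neighbours; sigma1 maximizes the summed log-likelihood
#' via golden-section search on a log-spaced bracket. If all fixes coincide
#' the likelihood is flat in sigma1 and the lower search bound is returned
#' with a degeneracy flag.
#'
#' @param x,y,t fix coordinates (m) and POSIXct times (strictly increasing).
#' @param sigma2_m location-error SD (m).
#' @param bracket search interval for sigma1 (m/sqrt(s)).
#' @param tol relative search tolerance.
#' @return list with `sigma1_m`, `logLik`, `degenerate`, and a `profile`
#'   data.frame (sigma1 grid and log-likelihood) for diagnostics.
#' @export
estimate_sigma1 <- function(x, y, t, sigma2_m = 30,
                            bracket = c(0.05, 500), tol = 1e-4) {
  stopifnot(length(x) >= 3, !is.unsorted(as.numeric(t), strictly = TRUE))
  ts <- as.numeric(t)
  n <- length(x)
  mid <- seq(2, n - 1, by = 2)
  lo <- mid - 1
  hi <- mid + 1
  Tt <- ts[hi] - ts[lo]
  al <- (ts[mid] - ts[lo]) / Tt
  mx <- (1 - al) * x[lo] + al * x[hi]
  my <- (1 - al) * y[lo] + al * y[hi]
  d2 <- (x[mid] - mx)^2 + (y[mid] - my)^2
  base_var <- ((1 - al)^2 + al^2) * sigma2_m^2

  ll <- function(log_s1) {
    v <- Tt * al * (1 - al) * exp(2 * log_s1) + base_var
    sum(-log(2 * pi * v) - d2 / (2 * v))
  }

  if (all(d2 < 1e-12) || all(Tt * al * (1 - al) < 1e-12)) {
    return(list(sigma1_m = bracket[1], logLik = ll(log(bracket[1])),
                degenerate = TRUE,
                profile = data.frame(sigma1_m = bracket[1],
                                     logLik = ll(log(bracket[1])))))
  }

  gr <- (sqrt(5) - 1) / 2
  a <- log(bracket[1])
  b <- log(bracket[2])
  c1 <- b - gr * (b - a)
  c2 <- a + gr * (b - a)
  f1 <- ll(c1)
  f2 <- ll(c2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- c1
      c1 <- c2
      f1 <- f2
      c2 <- a + gr * (b - a)
      f2 <- ll(c2)
    } else {
      b <- c2
      c2 <- c1
      f2 <- f1
      c1 <- b - gr * (b - a)
      f1 <- ll(c1)
    }
  }
  s1 <- exp((a + b) / 2)
  prof_grid <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = 41))
  profile <- data.frame(sigma1_m = prof_grid,
                        logLik = vapply(log(prof_grid), ll, numeric(1)))
  degenerate <- abs(s1 - bracket[1]) / bracket[1] < 10 * tol
  list(sigma1_m = s1, logLik = ll(log(s1)), degenerate = degenerate,
       profile = profile)
}

#' Compute a utilization distribution for a track segment
#'
#' Mean of all non-skipped bridge increments on a 50 m grid padded by at
#' least `3 * (sigma1 * sqrt(max gap) + sigma2)` around the fixes' bounding
#' box. Total mass is 1 within truncation tolerance (1e-6).
#'
#' @param x,y,t fix coordinates and POSIXct times.
#' @param params a [bbmm_params()].
#' @param grid optional [ud_grid()]; built automatically if NULL.
#' @param cell_m cell size when building the grid.
#' @param n_alpha,alpha_quad,trunc_sd quadrature settings (see
#'   [default_config()]).
#' @return object of class `ud_surface`: the grid plus `z`, the cell-mass
#'   matrix, `n_fixes` and `params`.
#' @export
compute_ud <- function(x, y, t, params, grid = NULL, cell_m = 50,
                       n_alpha = 10, alpha_quad = "midpoint",
                       trunc_sd = 6) {
  stopifnot(length(x) >= 2)
  ts <- as.numeric(t)
  o <- order(ts)
  x <- x[o]; y <- y[o]; ts <- ts[o]
  gaps <- diff(ts)
  use <- gaps > 0 & gaps <= params$max_bridge_gap_h * 3600
  if (!any(use)) stop("all bridges skipped: no usable fix pairs")
  if (is.null(grid)) {
    pad <- 3 * (params$sigma1_m * sqrt(max(gaps[use])) + params$sigma2_m)
    grid <- ud_grid(x, y, pad_m = pad, cell_m = cell_m)
  }
  nodes <- alpha_nodes(n_alpha, alpha_quad)
  idx <- which(use)
  z <- accumulate_bridges(x, y, ts, idx, params$sigma1_m, params$sigma2_m,
                          grid, nodes, trunc_sd, average = TRUE)
  structure(c(grid, list(z = z, n_fixes = length(x),
                         n_bridges = length(idx), params = params)),
            class = "ud_surface")
}

#' @export
print.ud_surface <- function(x, ...) {
  cat(sprintf(
    "<ud_surface> %d x %d cells of %g m, %d fixes, %d bridges, mass %.8f\n",
    x$nx, x$ny, x$cell_m, x$n_fixes, x$n_bridges, sum(x$z)))
  invisible(x)
}

#' Total probability mass of a UD
#' @param ud a `ud_surface`.
#' @export
ud_mass <- function(ud) sum(ud$z)

#' Extract a quantile isopleth from a UD
#'
#' Cells are sorted by density (descending, ties broken by row-major index)
#' and the smallest prefix whose cumulative mass reaches `q` of the total is
#' kept. The polygon is the union of those cells; with 50 m cells the area
#' is 0.25 ha per cell.
#'
#' @param ud a `ud_surface`.
#' @param q mass fraction in (0, 1), e.g. 0.95 for a seasonal range.
#' @return object of class `range_polygon`: global integer cell indices
#'   (`ix = floor(x / cell)`), `cell_m`, `q`, `area_ha`.
#' @export
isopleth <- function(ud, q) {
  stopifnot(q > 0, q < 1)
  zv <- as.vector(ud$z)                 # column-major; index = row-major in
  ord <- order(-zv, seq_along(zv))      # (i, j) with i fastest -> stable ties
  cum <- cumsum(zv[ord])
  n <- which(cum >= q * sum(zv))[1]
  sel <- ord[seq_len(n)]
  i <- ((sel - 1) %% ud$nx) + 1
  j <- ((sel - 1) %/% ud$nx) + 1
  cell_area_ha <- (ud$cell_m^2) / 1e4
  structure(list(
    ix = as.integer(ud$x0 / ud$cell_m + i - 1),
    iy = as.integer(ud$y0 / ud$cell_m + j - 1),
    cell_m = ud$cell_m,
    q = q,
    area_ha = cell_area_ha * n
  ), class = "range_polygon")
}

#' @export
print.range_polygon <- function(x, ...) {
  cat(sprintf("<range_polygon> q=%.2f, %d cells, %.2f ha\n",
              x$q, length(x$ix), x$area_ha))
  invisible(x)
}

#' Are points inside a range polygon?
#'
#' @param poly a `range_polygon`.
#' @param x,y coordinates (m) in the shared CRS.
#' @return logical vector.
#' @export
in_polygon <- function(poly, x, y) {
  key <- paste(floor(x / poly$cell_m), floor(y / poly$cell_m))
  key %in% paste(poly$ix, poly$iy)
}
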