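# Shared fixtures. The two expensive simulations (the 60-track recovery
# suite and the 9-band study-structure scenario) are computed once per test
# run and cached.

.cache <- new.env(parent = emptyenv())

# 60 simulated animals, 10 per strategy, seeds 1-60, analyzed with default
# thresholds
recovery_results <- function() {
  if (is.null(.cache$recovery)) {
    suite <- recovery_suite()
    res <- suppressWarnings(analyze_cohort(
      lapply(suite, `[[`, "track"),
      lapply(suite, `[[`, "dem"),
      do_bands = FALSE))
    .cache$recovery <- list(suite = suite, res = res)
  }
  .cache$recovery
}

# the 16-female / 9-band scenario
mimic_results <- function() {
  if (is.null(.cache$mimic)) {
    sims <- simulate_scenario(study_cohort_scenario(), seed = 42)
    res <- suppressWarnings(analyze_cohort(
      lapply(sims$animals, `[[`, "track"),
      sims$dems, do_bands = TRUE))
    .cache$mimic <- list(sims = sims, res = res)
  }
  .cache$mimic
}

# Independent brute-force BBMM oracle: dense midpoint time-quadrature over
# the whole grid with the per-cell Gaussian integral evaluated in closed
# form (no truncation window, no shared code with the package's
# accumulator).
oracle_ud <- function(x, y, t, sigma1, sigma2, grid, n_alpha = 4000) {
  ts <- as.numeric(t)
  z <- matrix(0, grid$nx, grid$ny)
  ex <- grid$x0 + (0:grid$nx) * grid$cell_m
  ey <- grid$y0 + (0:grid$ny) * grid$cell_m
  nb <- 0
  for (i in seq_len(length(x) - 1)) {
    T_s <- ts[i + 1] - ts[i]
    if (T_s <= 0 || T_s > 24 * 3600) next
    nb <- nb + 1
    for (k in seq_len(n_alpha)) {
      a <- (k - 0.5) / n_alpha
      mux <- (1 - a) * x[i] + a * x[i + 1]
      muy <- (1 - a) * y[i] + a * y[i + 1]
      s <- sqrt(T_s * a * (1 - a) * sigma1^2 +
                  ((1 - a)^2 + a^2) * sigma2^2)
      z <- z + outer(diff(pnorm(ex, mux, s)),
                     diff(pnorm(ey, muy, s))) / n_alpha
    }
  }
  z / nb
}

wiggly_track <- function(n = 12, step = 350, seed = 20) {
  set.seed(seed)
  th <- cumsum(runif(n - 1, -0.8, 0.8))
  x <- c(0, cumsum(step * cos(th)))
  y <- c(0, cumsum(step * sin(th)))
  t <- as.POSIXct("2018-01-01", tz = "UTC") + (0:(n - 1)) * 7200
  list(x = x, y = y, t = t)
}

# a small track built by hand: n fixes at interval_h, positions supplied
toy_track <- function(x, y, start = "2018-01-01", interval_h = 2,
                      id = "toy", n_sats = NULL) {
  t <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC") +
    (seq_along(x) - 1) * interval_h * 3600
  df <- data.frame(animal_id = id, t = t, x = x, y = y)
  if (!is.null(n_sats)) df$n_sats <- n_sats
  as_track(df, capture_date = as.Date(start) - 30)
}

# hand-built corridor + track + ranges for exact stopover-rule tests.
# Two dwell blobs sit on a west-east route; their centre-to-centre gap and
# per-blob dwell hours are configurable. Ranges sit at the route ends.
toy_stopover_fixture <- function(gap_cells = 60, dwell_a_h = 24,
                                 dwell_b_h = 24) {
  cell <- 50
  nx <- 140
  ny <- 21
  z <- matrix(0, nx, ny)
  jmid <- 11
  bx_a <- 30
  bx_b <- 30 + gap_cells
  # a low-density travel route with two dense plus-shaped dwell blobs whose
  # ten cells hold just over 10% of the mass, so the 10% isopleth is
  # exactly the two blobs
  z[cbind(seq_len(nx), jmid)] <- 0.0063
  plus <- function(cx) {
    z[cx, jmid] <<- 0.0164
    z[cbind(cx + c(-1, 1, 0, 0), jmid + c(0, 0, -1, 1))] <<- 0.0082
  }
  plus(bx_a)
  plus(bx_b)
  z <- z / sum(z)
  ud <- structure(list(x0 = 0, y0 = 0, nx = nx, ny = ny, cell_m = cell,
                       z = z, n_fixes = 0, n_bridges = 1,
                       params = bbmm_params(5)),
                  class = "ud_surface")
  # track: dwell in blob a, travel, dwell in blob b
  pos_a <- c((bx_a - 0.5) * cell, (jmid - 0.5) * cell)
  pos_b <- c((bx_b - 0.5) * cell, (jmid - 0.5) * cell)
  n_a <- max(1, round(dwell_a_h / 2))
  n_b <- max(1, round(dwell_b_h / 2))
  xs <- c(rep(pos_a[1], n_a), rep(pos_b[1], n_b))
  ys <- c(rep(pos_a[2], n_a), rep(pos_b[2], n_b))
  tr <- toy_track(xs, ys, start = "2018-06-02")
  corridor <- structure(list(
    animal_id = "toy", season = "spring", ud = ud,
    poly95 = isopleth(ud, 0.95), sigma1_m = 5, route_distance_km = 5,
    window = c(as.Date("2018-06-01"), as.Date("2018-06-09"))),
    class = "corridor")
  mk_range <- function(ix0) {
    structure(list(ix = rep(ix0 + 0:2, 3),
                   iy = rep(jmid + (-1:1), each = 3),
                   cell_m = cell, q = 0.95, area_ha = 9 * 0.25),
              class = "range_polygon")
  }
  list(corridor = corridor, track = tr,
       winter = mk_range(2), summer = mk_range(nx - 5))
}
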