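test_that("bridge densities match the dense-quadrature oracle", {
  tr <- wiggly_track(12)
  p <- bbmm_params(6, 30)
  ud <- compute_ud(tr$x, tr$y, tr$t, p, n_alpha = 400,
                   alpha_quad = "gauss")
  grid <- ud[c("x0", "y0", "nx", "ny", "cell_m")]
  zo <- oracle_ud(tr$x, tr$y, tr$t, 6, 30, grid)
  expect_lt(max(abs(ud$z - zo)), 1e-6)
})

test_that("a single bridge agrees with the oracle and integrates to one", {
  p <- bbmm_params(4, 30)
  g <- ud_grid(c(0, 420), c(0, 130), pad_m = 900, cell_m = 50)
  z <- bridge_density(0, 0, 420, 130, 7200, p, g, n_alpha = 400,
                      alpha_quad = "gauss")
  t2 <- as.POSIXct("2018-01-01", tz = "UTC") + c(0, 7200)
  zo <- oracle_ud(c(0, 420), c(0, 130), t2, 4, 30, g)
  expect_lt(max(abs(z - zo)), 1e-6)
  expect_lt(abs(sum(z) - 1), 1e-6)
})

test_that("a stationary bridge with tiny sigma1 is a location-error blob", {
  # with z_a = z_b and sigma1 -> 0 the bridge reduces to a centred mixture
  # of Gaussians whose SD runs from sigma2/sqrt(2) (mid-bridge) to sigma2
  # (endpoints): a blob the size of the location error
  p <- bbmm_params(1e-6, 30)
  g <- ud_grid(0, 0, pad_m = 400, cell_m = 50)
  z <- bridge_density(0, 0, 0, 0, 7200, p, g)
  expect_lt(abs(sum(z) - 1), 1e-9)
  ex <- g$x0 + (0:g$nx) * 50
  ey <- g$y0 + (0:g$ny) * 50
  blob <- function(s) outer(diff(pnorm(ex, 0, s)), diff(pnorm(ey, 0, s)))
  lo <- blob(30)
  hi <- blob(30 / sqrt(2))
  # the peak cell lies between the two limiting Gaussians
  pk <- which(z == max(z), arr.ind = TRUE)[1, ]
  expect_gte(z[pk[1], pk[2]], lo[pk[1], pk[2]])
  expect_lte(z[pk[1], pk[2]], hi[pk[1], pk[2]])
  # symmetry about the fix
  expect_equal(z, z[rev(seq_len(g$nx)), rev(seq_len(g$ny))],
               tolerance = 1e-12)
  # and the exact alpha-mixture reproduces it
  mix <- Reduce(`+`, lapply((1:10 - 0.5) / 10, function(a) {
    blob(30 * sqrt((1 - a)^2 + a^2)) / 10
  }))
  expect_lt(max(abs(z - mix)), 1e-10)
})

test_that("every UD carries unit mass at default settings", {
  for (s in 1:3) {
    set.seed(s)
    n <- 120
    t <- as.POSIXct("2018-01-01", tz = "UTC") + (0:(n - 1)) * 7200
    x <- cumsum(rnorm(n, 0, 300))
    y <- cumsum(rnorm(n, 0, 300))
    ud <- compute_ud(x, y, t, bbmm_params(5, 30))
    expect_lt(abs(ud_mass(ud) - 1), 1e-6)
  }
})

test_that("two-fix track UD equals its single bridge density", {
  p <- bbmm_params(5, 30)
  t2 <- as.POSIXct("2018-01-01", tz = "UTC") + c(0, 7200)
  ud <- compute_ud(c(0, 300), c(0, 100), t2, p)
  grid <- ud[c("x0", "y0", "nx", "ny", "cell_m")]
  z1 <- bridge_density(0, 0, 300, 100, 7200, p, grid)
  expect_equal(ud$z, z1)
})

test_that("bridges across long gaps are skipped", {
  t <- as.POSIXct("2018-01-01", tz = "UTC") +
    c(0, 7200, 7200 + 30 * 3600, 7200 + 30 * 3600 + 7200)
  ud <- compute_ud(c(0, 100, 5000, 5100), c(0, 0, 0, 0), t,
                   bbmm_params(5, 30))
  expect_equal(ud$n_bridges, 2)
  expect_error(compute_ud(c(0, 100), c(0, 0),
                          as.POSIXct("2018-01-01", tz = "UTC") +
                            c(0, 48 * 3600), bbmm_params(5, 30)),
               "skipped")
})

test_that("isopleths have closed forms, nest, and grow with q", {
  z <- matrix(1 / 100, 10, 10)
  ud <- structure(list(x0 = 0, y0 = 0, nx = 10, ny = 10, cell_m = 50,
                       z = z, n_fixes = 0, n_bridges = 1,
                       params = bbmm_params(5)),
                  class = "ud_surface")
  i95 <- isopleth(ud, 0.95)
  expect_equal(length(i95$ix), 95)
  expect_equal(i95$area_ha, 23.75)
  i10 <- isopleth(ud, 0.10)
  expect_equal(length(i10$ix), 10)
  expect_equal(i10$area_ha, 2.5)

  set.seed(30)
  n <- 200
  t <- as.POSIXct("2018-01-01", tz = "UTC") + (0:(n - 1)) * 7200
  x <- cumsum(rnorm(n, 0, 250))
  y <- cumsum(rnorm(n, 0, 250))
  ud2 <- compute_ud(x, y, t, bbmm_params(4, 30))
  i50 <- isopleth(ud2, 0.5)
  i95 <- isopleth(ud2, 0.95)
  expect_true(all(paste(i50$ix, i50$iy) %in% paste(i95$ix, i95$iy)))
  qs <- c(0.2, 0.5, 0.8, 0.95)
  areas <- vapply(qs, function(q) isopleth(ud2, q)$area_ha, numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("doubling the grid padding barely moves isopleth areas", {
  set.seed(31)
  n <- 300
  t <- as.POSIXct("2018-01-01", tz = "UTC") + (0:(n - 1)) * 7200
  x <- 455000 + cumsum(rnorm(n, 0, 200))
  y <- 6573000 + cumsum(rnorm(n, 0, 200))
  p <- bbmm_params(4, 30)
  ud1 <- compute_ud(x, y, t, p)
  pad <- 3 * (p$sigma1_m * sqrt(7200) + p$sigma2_m)
  g2 <- ud_grid(x, y, pad_m = 2 * pad, cell_m = 50)
  ud2 <- compute_ud(x, y, t, p, grid = g2)
  for (q in c(0.5, 0.95)) {
    a1 <- isopleth(ud1, q)$area_ha
    a2 <- isopleth(ud2, q)$area_ha
    expect_lt(abs(a2 - a1) / a1, 0.005)
  }
})

test_that("sigma1 estimation recovers, flags degeneracy, and is
           translation invariant", {
  set.seed(40)
  n <- 400
  t <- as.POSIXct("2018-01-01", tz = "UTC") + (0:(n - 1)) * 7200
  x <- cumsum(rnorm(n, 0, 6 * sqrt(7200))) + rnorm(n, 0, 30)
  y <- cumsum(rnorm(n, 0, 6 * sqrt(7200))) + rnorm(n, 0, 30)
  est <- estimate_sigma1(x, y, t, 30)
  expect_false(est$degenerate)
  expect_lt(abs(est$sigma1_m - 6) / 6, 0.2)
  est2 <- estimate_sigma1(x + 1e5, y - 2e5, t, 30)
  expect_equal(est2$sigma1_m, est$sigma1_m, tolerance = 1e-6)

  flat <- estimate_sigma1(rep(0, 10), rep(0, 10),
                          as.POSIXct("2018-01-01", tz = "UTC") +
                            (0:9) * 7200, 30)
  expect_true(flat$degenerate)
})

test_that("UD mode lands on the residence centroid", {
  for (s in 1:3) {
    cfg <- sim_config("RESIDENT", seed = 100 + s)
    sim <- simulate_track(cfg)
    tr <- sim$track
    sel <- as.Date(tr$t) <= as.Date("2018-04-01")
    est <- estimate_sigma1(tr$x[sel], tr$y[sel], tr$t[sel], 30)
    ud <- compute_ud(tr$x[sel], tr$y[sel], tr$t[sel],
                     bbmm_params(est$sigma1_m, 30))
    peak <- which(ud$z == max(ud$z), arr.ind = TRUE)[1, ]
    px <- ud$x0 + (peak[1] - 0.5) * 50
    py <- ud$y0 + (peak[2] - 0.5) * 50
    expect_lt(abs(px - cfg$winter_centroid[1]), 200)
    expect_lt(abs(py - cfg$winter_centroid[2]), 200)
  }
})
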