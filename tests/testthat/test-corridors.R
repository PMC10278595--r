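test_that("route distance has its closed forms", {
  # one fix per day at (0,0), (3,4), (6,8) km
  tr <- toy_track(c(0, 3000, 6000), c(0, 4000, 8000),
                  start = "2018-06-10", interval_h = 24)
  ev <- structure(list(spring_start = as.Date("2018-06-10"),
                       spring_end = as.Date("2018-06-12"),
                       fall_start = as.Date("2018-09-01"),
                       fall_end = as.Date("2018-09-05")),
                  class = "migration_event")
  expect_equal(route_distance(tr, ev, "spring"), 10)
  expect_warning(d0 <- route_distance(tr, ev, "fall"), "distance 0")
  expect_equal(d0, 0)
})

test_that("the residence-side boundary day adds no foraging distance", {
  # day 1: twelve jittery fixes at winter; days 2-3: the actual leg
  xs <- c(rep(c(0, 400), 6), 5000, 10000)
  ys <- c(rep(c(0, 400), 6), 0, 0)
  t <- as.POSIXct("2018-06-10 00:00:00", tz = "UTC") +
    c((0:11) * 7200, 86400, 2 * 86400)
  tr <- as_track(data.frame(animal_id = "z", t = t, x = xs, y = ys),
                 capture_date = as.Date("2018-05-01"))
  ev <- structure(list(spring_start = as.Date("2018-06-10"),
                       spring_end = as.Date("2018-06-12")),
                  class = "migration_event")
  # only the last day-1 fix seeds the path: 400 -> 5000 -> 10000 on y = 0
  # after the (400,400) fix, i.e. hypot(4600,400) + 5000
  expect_equal(route_distance(tr, ev, "spring"),
               (sqrt(4600^2 + 400^2) + 5000) / 1000)
})

test_that("reported distance falls back across legs", {
  expect_equal(reported_distance(12.5, 14, "spring"), 12.5)
  expect_equal(reported_distance(NA, 14, "spring"), 14)
  expect_equal(reported_distance(12.5, 14, "max"), 14)
  expect_equal(reported_distance(12, 14, "mean"), 13)
})

test_that("simulated route distance tracks the planted polyline", {
  cfg <- sim_config("LDM", seed = 6)
  sim <- simulate_track(cfg)
  tr <- suppressWarnings(clean_track(sim$track))
  ev <- detect_migration(compute_nsd(tr))
  d <- route_distance(tr, ev, "spring")
  # planted dogleg length: separation plus the perpendicular detour
  half <- cfg$separation_m / 2
  detour <- 0.07 * cfg$separation_m
  polyline_km <- 2 * sqrt(half^2 + detour^2) / 1000
  # noise-inflation correction: the 24 h stopover dwell contributes pure
  # jitter steps; each has per-axis SD sqrt(2(1-rho)) * dwell_sd plus
  # sqrt(2) * GPS error, and a 2D Gaussian step's mean length is
  # sd * sqrt(pi / 2)
  rho <- exp(-2 / cfg$ou_tau_h)
  step_sd <- sqrt(2 * (1 - rho) * cfg$jitter$dwell^2 +
                    2 * cfg$loc_error_sd_m^2)
  dwell_km <- (cfg$stopover_dwell_h / cfg$fix_interval_h) *
    step_sd * sqrt(pi / 2) / 1000
  expect_lt(abs(d - (polyline_km + dwell_km)), 0.05 * polyline_km)
})

test_that("corridor UDs include the padding fixes and carry unit mass", {
  sim <- simulate_track(sim_config("SDM", seed = 18))
  tr <- suppressWarnings(clean_track(sim$track))
  ev <- detect_migration(compute_nsd(tr))
  co <- corridor_ud(tr, ev, "spring")
  expect_lt(abs(ud_mass(co$ud) - 1), 1e-6)
  day <- as.Date(tr$t, tz = "UTC")
  n_inside <- sum(day >= ev$spring_start & day <= ev$spring_end)
  expect_gt(co$ud$n_fixes, n_inside)
  # the corridor contains virtually all fixes of the leg
  leg <- day >= ev$spring_start & day <= ev$spring_end
  frac_in <- mean(in_polygon(co$poly95, tr$x[leg], tr$y[leg]))
  expect_gte(frac_in, 0.99)
})

test_that("stopover extraction follows the 10%/12 h/300 m rules exactly", {
  # two 24 h dwells 2.85 km apart -> two sites
  f <- toy_stopover_fixture(gap_cells = 60)
  sites <- extract_stopovers(f$corridor, f$track, f$winter, f$summer)
  expect_length(sites, 2)
  expect_true(all(vapply(sites, `[[`, 1, "occupancy_h") >= 12))

  # nearest borders 250 m apart -> merged into one site
  f <- toy_stopover_fixture(gap_cells = 8)
  sites <- extract_stopovers(f$corridor, f$track, f$winter, f$summer)
  expect_length(sites, 1)
  expect_equal(sites[[1]]$occupancy_h, 48, tolerance = 0.1)

  # a 6 h dwell fails the 12 h screen
  f <- toy_stopover_fixture(gap_cells = 60, dwell_b_h = 6)
  sites <- extract_stopovers(f$corridor, f$track, f$winter, f$summer)
  expect_length(sites, 1)

  # components that touch a seasonal range are discarded: move the winter
  # range onto the first blob
  f <- toy_stopover_fixture(gap_cells = 60)
  f$winter$ix <- 28 + rep(0:2, 3)
  f$winter$iy <- 9 + rep(0:2, each = 3)
  sites <- extract_stopovers(f$corridor, f$track, f$winter, f$summer)
  expect_length(sites, 1)

  # retained sites are >= 300 m from each other
  f <- toy_stopover_fixture(gap_cells = 60)
  sites <- extract_stopovers(f$corridor, f$track, f$winter, f$summer)
  gap <- thinhorn:::cellset_gap_m(sites[[1]]$ix, sites[[1]]$iy,
                                  sites[[2]]$ix, sites[[2]]$iy, 50)
  expect_gte(gap, 300)
})

test_that("a non-stop migration yields no stopovers", {
  cfg <- sim_config("SDM", seed = 19, n_stopovers_spring = 0,
                    n_stopovers_fall = 0)
  sim <- simulate_track(cfg)
  tr <- suppressWarnings(clean_track(sim$track))
  ev <- detect_migration(compute_nsd(tr))
  win <- season_windows(tr, ev)
  w <- seasonal_range(tr, win$winter)
  s <- seasonal_range(tr, win$summer)
  co <- corridor_ud(tr, ev, "spring")
  expect_length(extract_stopovers(co, tr, w, s), 0)
})

test_that("band corridors are idempotent and cover member routes", {
  m <- mimic_results()
  # band 3: two long-distance migrants sharing a route
  ids <- grep("^b03", names(m$res$details), value = TRUE)
  cors <- lapply(m$res$details[ids], function(d) d$corridors$spring)
  expect_length(cors, 2)
  single <- band_corridor(cors[1])
  expect_equal(single$ud$z / sum(single$ud$z),
               cors[[1]]$ud$z / sum(cors[[1]]$ud$z), tolerance = 1e-12)
  two_same <- band_corridor(list(cors[[1]], cors[[1]]))
  expect_equal(sort(paste(two_same$poly95$ix, two_same$poly95$iy)),
               sort(paste(single$poly95$ix, single$poly95$iy)))

  comb <- band_corridor(cors)
  union_keys <- unique(c(paste(cors[[1]]$poly95$ix, cors[[1]]$poly95$iy),
                         paste(cors[[2]]$poly95$ix, cors[[2]]$poly95$iy)))
  covered <- mean(union_keys %in% paste(comb$poly95$ix, comb$poly95$iy))
  expect_gte(covered, 0.9)
})

test_that("band members share their stopover sites", {
  m <- mimic_results()
  det <- m$res$details
  shared <- c()
  for (b in c("b03", "b07", "b08")) {
    ids <- grep(paste0("^", b), names(det), value = TRUE)
    if (length(ids) != 2) next
    for (season in c("spring", "fall")) {
      s1 <- det[[ids[1]]]$stopovers[[season]]
      s2 <- det[[ids[2]]]$stopovers[[season]]
      if (!length(s1) && !length(s2)) next
      # sites match when their centroids are within 300 m
      match_one <- function(a, bs) {
        any(vapply(bs, function(b2) {
          sqrt(sum((a$centroid - b2$centroid)^2)) < 300
        }, logical(1)))
      }
      hits <- c(vapply(s1, match_one, logical(1), bs = s2),
                vapply(s2, match_one, logical(1), bs = s1))
      shared <- c(shared, hits)
    }
  }
  expect_gte(mean(shared), 0.8)
})
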