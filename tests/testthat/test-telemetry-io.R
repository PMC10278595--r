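write_fix_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(c(paste("individual-local-identifier", "timestamp",
                     "location-long", "location-lat", sep = ","),
               lines), path)
  path
}

test_that("read_fixes rejects bad records and sorts per animal", {
  # one row with an empty latitude -> 2 retained, 1 flagged
  p <- write_fix_csv(c(
    "f1,2018-02-01 00:00:00,-129.80,59.30",
    "f1,2018-02-01 02:00:00,-129.81,",
    "f1,2018-02-01 04:00:00,-129.82,59.31"))
  tr <- read_fixes(p, crs = "EPSG:32609")[["f1"]]
  expect_equal(nrow(tr), 2)
  expect_equal(nrow(rejected_fixes(tr)), 1)
  expect_equal(rejected_fixes(tr)$qc_flag, "unparseable_coordinate")

  # out-of-order rows come back strictly time-ascending
  p <- write_fix_csv(c(
    "f1,2018-02-01 04:00:00,-129.82,59.31",
    "f1,2018-02-01 00:00:00,-129.80,59.30",
    "f1,2018-02-01 02:00:00,-129.81,59.30"))
  tr <- read_fixes(p)[["f1"]]
  expect_true(!is.unsorted(tr$t, strictly = TRUE))

  # two interleaved animals split into tracks matching a manual partition
  lines <- c(
    "a,2018-02-01 00:00:00,-129.80,59.30",
    "b,2018-02-01 00:00:00,-129.90,59.40",
    "a,2018-02-01 02:00:00,-129.81,59.30",
    "b,2018-02-01 02:00:00,-129.91,59.40",
    "a,2018-02-01 04:00:00,-129.82,59.31")
  manual_counts <- table(vapply(strsplit(lines, ","), `[[`, "", 1))
  tracks <- read_fixes(write_fix_csv(lines))
  expect_named(tracks, c("a", "b"))
  expect_equal(unname(vapply(tracks, nrow, integer(1))),
               as.vector(manual_counts))

  # zero valid records is a hard error
  p <- write_fix_csv("f1,not-a-time,-129.80,59.30")
  expect_error(read_fixes(p), "no valid records")
})

test_that("duplicate timestamps keep the first record and flag the rest", {
  tr <- toy_track(c(0, 0, 100), c(0, 50, 0))
  df <- rbind(as.data.frame(tr), as.data.frame(tr)[2, ])
  tr2 <- as_track(df)
  expect_equal(nrow(tr2), 3)
  expect_equal(rejected_fixes(tr2)$qc_flag, "duplicate_timestamp")
})

test_that("cleaning applies the capture window, satellite and speed rules", {
  # satellite boundary: n_sats = 2 is removed (<= 2), 8 and 9 retained
  tr <- toy_track(c(0, 10, 20), c(0, 0, 0), n_sats = c(8, 2, 9))
  cl <- clean_track(tr, cfg = modifyList(default_config()$cleaning,
                                         list(min_fixes = 1)))
  expect_equal(nrow(cl), 2)
  expect_true("low_satellite_count" %in% rejected_fixes(cl)$qc_flag)

  # speed boundary: 21 km in 1 h exceeds 20 km/h
  t <- as.POSIXct("2018-01-01", tz = "UTC") + c(0, 3600)
  tr <- as_track(data.frame(animal_id = "s", t = t, x = c(0, 21000),
                            y = 0), capture_date = as.Date("2017-12-01"))
  cl <- suppressWarnings(
    clean_track(tr, cfg = modifyList(default_config()$cleaning,
                                     list(min_fixes = 1))))
  expect_equal(nrow(cl), 1)
  expect_true("speed_exceeds_max" %in% rejected_fixes(cl)$qc_flag)

  # fixes within 7 days of capture are dropped
  tr <- toy_track(rep(0, 5), rep(0, 5), start = "2018-01-01",
                  interval_h = 48)
  attr(tr, "capture_date") <- as.Date("2018-01-01")
  cl <- suppressWarnings(
    clean_track(tr, cfg = modifyList(default_config()$cleaning,
                                     list(min_fixes = 1))))
  expect_true(all(as.Date(cl$t) >= as.Date("2018-01-08")))
})

test_that("planted teleportation spikes are exactly the fixes flagged", {
  cfg <- sim_config("RESIDENT", seed = 9, n_spikes = 10)
  sim <- simulate_track(cfg)
  cl <- suppressWarnings(clean_track(sim$track))
  rej <- rejected_fixes(cl)
  spikes <- rej[rej$qc_flag == "speed_exceeds_max", ]
  expect_equal(sort(spikes$t), sort(sim$track$t[sim$truth$corrupted_idx]))
  expect_equal(nrow(spikes), 10)
})

test_that("cleaning is idempotent and loses no fixes silently", {
  cfg <- sim_config("RESIDENT", seed = 10, n_spikes = 5)
  sim <- simulate_track(cfg)
  n_in <- nrow(sim$track)
  cl <- suppressWarnings(clean_track(sim$track))
  expect_equal(nrow(cl) + nrow(rejected_fixes(cl)), n_in)
  cl2 <- suppressWarnings(clean_track(cl))
  expect_equal(as.data.frame(cl2), as.data.frame(cl))
})

test_that("too few surviving fixes flags the animal, not an error", {
  tr <- toy_track(seq(0, 1000, by = 100), rep(0, 11))
  cl <- suppressWarnings(clean_track(tr))
  expect_true(is_unusable(cl))
})

test_that("coverage adequacy uses -30/+90 day bounds", {
  mk <- function(first, last) {
    toy_track(c(0, 1), c(0, 0), start = first,
              interval_h = as.numeric(as.Date(last) -
                                        as.Date(first)) * 24)
  }
  spring <- as.Date("2018-06-10")
  fall <- as.Date("2018-09-08")
  # ends 89 days after fall end -> inadequate
  expect_false(coverage_adequate(mk("2018-05-01", fall + 89), spring, fall))
  # 31 days before spring and 91 after fall -> adequate
  expect_true(coverage_adequate(mk(spring - 31, fall + 91), spring, fall))
  # residents: adequate iff they span a year
  expect_true(coverage_adequate(mk("2018-01-01", "2019-01-02"),
                                NULL, NULL))
  expect_false(coverage_adequate(mk("2018-01-01", "2018-06-01"),
                                 NULL, NULL))
})

test_that("a cohort of 18 with 2 truncated tracks leaves 16 adequate", {
  spring <- as.Date("2018-06-10")
  fall <- as.Date("2018-09-08")
  tracks <- c(
    lapply(1:16, function(i) toy_track(c(0, 1), c(0, 0),
                                       start = "2018-02-01",
                                       interval_h = 330 * 24)),
    lapply(1:2, function(i) toy_track(c(0, 1), c(0, 0),
                                      start = "2018-02-01",
                                      interval_h = 24 * as.numeric(
                                        fall + 89 - as.Date("2018-02-01")))))
  ok <- vapply(tracks, coverage_adequate, logical(1),
               spring_start = spring, fall_end = fall)
  expect_equal(sum(ok), 16)
})

test_that("elevation annotation matches the DEM exactly", {
  flat <- make_dem("flat", c(0, 2000, 0, 2000))
  tr <- toy_track(c(100, 500, 1500), c(100, 900, 1900))
  expect_equal(annotate_elevation(tr, flat)$elev_m, rep(1500, 3))

  ramp <- make_dem("ramp", c(0, 200000, 0, 2000), cell_m = 100,
                   base = 0, slope = 0.01)
  tr <- toy_track(150000, 1000)
  # cell containing x = 150,000 has centre 150,050 -> 1500.5 m
  expect_equal(annotate_elevation(tr, ramp)$elev_m, 1500.5)

  # random points on a ridge DEM match an independent per-point lookup
  dem <- make_dem("ridge", c(0, 8000, 0, 4000), cell_m = 20,
                  ridge_x = 4000)
  set.seed(11)
  x <- runif(200, 10, 7990)
  y <- runif(200, 10, 3990)
  oracle <- 700 + 1100 * exp(-((floor(x / 20) + 0.5) * 20 - 4000)^2 /
                               (2 * 1500^2))
  tr <- toy_track(x, y)
  expect_equal(annotate_elevation(tr, dem)$elev_m, oracle)

  # a fix outside the DEM is flagged, not fatal
  tr <- toy_track(c(100, 9000), c(100, 100))
  out <- annotate_elevation(tr, make_dem("flat", c(0, 2000, 0, 2000)))
  expect_true(is.na(out$elev_m[2]))
  expect_equal(out$qc_flag[2], "outside_dem")
})

test_that("DEM round-trips through the ASCII grid format", {
  dem <- make_dem("ridge", c(1000, 3000, 2000, 3500), cell_m = 50)
  path <- tempfile(fileext = ".asc")
  write_dem_asc(dem, path)
  back <- read_dem_asc(path)
  expect_equal(back$z, dem$z, tolerance = 1e-8)
  expect_equal(back$xmin, dem$xmin)
  expect_equal(back$cell_m, dem$cell_m)
})
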