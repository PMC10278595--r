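test_that("NSD has its closed forms", {
  # stationary animal: NSD identically zero
  tr <- toy_track(rep(1000, 40), rep(2000, 40), start = "2018-03-15")
  nsd <- compute_nsd(tr, as.Date("2018-03-15"))
  expect_true(all(nsd$fixes$nsd_km2 == 0))

  # 3-4-5 triangle fixes: 0, 25, 100 km^2
  tr <- toy_track(c(0, 3000, 6000), c(0, 4000, 8000),
                  start = "2018-03-15")
  nsd <- compute_nsd(tr, as.Date("2018-03-15"))
  expect_equal(nsd$fixes$nsd_km2, c(0, 25, 100))

  # reference fix must exist within 7 days
  tr <- toy_track(c(0, 1), c(0, 0), start = "2018-05-01")
  expect_error(compute_nsd(tr, as.Date("2018-04-01")), "within 7 days")
})

test_that("NSD plateau height matches the squared separation", {
  # a single summer's OU wander shifts one animal's plateau by a few
  # percent, so the check aggregates over seeds
  ratios <- vapply(1:5, function(s) {
    cfg <- sim_config("LDM", seed = s)
    sim <- simulate_track(cfg)
    nsd <- compute_nsd(suppressWarnings(clean_track(sim$track)))
    ev <- detect_migration(nsd)
    expect_s3_class(ev, "migration_event")
    ev$plateau_km^2 / (cfg$separation_m / 1000)^2
  }, numeric(1))
  expect_lt(abs(median(ratios) - 1), 0.05)
})

test_that("the detector separates migrants from residents", {
  res <- simulate_track(sim_config("RESIDENT", seed = 52))
  out <- detect_migration(compute_nsd(suppressWarnings(
    clean_track(res$track))))
  expect_equal(out$verdict, "resident")

  mig <- simulate_track(sim_config("SDM", seed = 13))
  ev <- detect_migration(compute_nsd(suppressWarnings(
    clean_track(mig$track))))
  expect_s3_class(ev, "migration_event")
  for (f in c("spring_start", "spring_end", "fall_start", "fall_end")) {
    expect_lte(abs(as.numeric(ev[[f]] - mig$truth[[f]])), 3)
  }
})

test_that("detection is invariant to rigid motions of the coordinates", {
  sim <- simulate_track(sim_config("SDM", seed = 14))
  tr <- suppressWarnings(clean_track(sim$track))
  ev <- detect_migration(compute_nsd(tr))
  th <- 0.7
  rot <- tr
  x0 <- 400000
  y0 <- 6500000
  rot$x <- x0 + cos(th) * (tr$x - x0) - sin(th) * (tr$y - y0) + 50000
  rot$y <- y0 + sin(th) * (tr$x - x0) + cos(th) * (tr$y - y0) - 20000
  ev2 <- detect_migration(compute_nsd(rot))
  expect_equal(ev2$spring_start, ev$spring_start)
  expect_equal(ev2$spring_end, ev$spring_end)
  expect_equal(ev2$fall_start, ev$fall_start)
  expect_equal(ev2$fall_end, ev$fall_end)
})

test_that("doubling fix frequency shifts dates by at most a day", {
  quiet <- list(winter = 1, summer = 1, leg = 1, dwell = 1, excursion = 1)
  ev <- lapply(c(2, 1), function(h) {
    cfg <- sim_config("SDM", seed = 15, fix_interval_h = h,
                      loc_error_sd_m = 0, jitter = quiet)
    detect_migration(compute_nsd(suppressWarnings(
      clean_track(simulate_track(cfg)$track))))
  })
  for (f in c("spring_start", "spring_end", "fall_start", "fall_end")) {
    expect_lte(abs(as.numeric(ev[[1]][[f]] - ev[[2]][[f]])), 1)
  }
})

test_that("season windows tile the year around the migration legs", {
  sim <- simulate_track(sim_config("LDM", seed = 4))
  tr <- suppressWarnings(clean_track(sim$track))
  ev <- detect_migration(compute_nsd(tr))
  win <- season_windows(tr, ev)
  expect_equal(win$provenance, "migrant-derived")
  # each season is at least 30 days and winter/summer never overlap
  expect_gte(as.numeric(win$summer[2] - win$summer[1]), 30)
  for (w in win$winter) {
    expect_gte(as.numeric(w[2] - w[1]), 30)
    expect_true(w[2] <= win$summer[1] || w[1] >= win$summer[2])
  }
  # winter + migrations + summer cover every day of the track span
  days <- seq(as.Date(min(tr$t)), as.Date(max(tr$t)), by = "day")
  covered <- rep(FALSE, length(days))
  mark <- function(a, b) covered[days >= a & days <= b] <<- TRUE
  for (w in win$winter) mark(w[1], w[2])
  mark(win$summer[1], win$summer[2])
  mark(ev$spring_start, ev$spring_end)
  mark(ev$fall_start, ev$fall_end)
  expect_true(all(covered))
})

test_that("vacillations are counted from winter-range re-entries", {
  sim <- simulate_track(sim_config("VAC", seed = 23))
  tr <- suppressWarnings(clean_track(sim$track))
  ev <- detect_migration(compute_nsd(tr))
  win <- season_windows(tr, ev)
  wr <- suppressWarnings(seasonal_range(tr, win$winter))
  expect_equal(count_vacillations(tr, ev, wr), 3)

  # a monotone plateau has no re-entries
  sim2 <- simulate_track(sim_config("SDM", seed = 16))
  tr2 <- suppressWarnings(clean_track(sim2$track))
  ev2 <- detect_migration(compute_nsd(tr2))
  wr2 <- suppressWarnings(seasonal_range(tr2,
                                         season_windows(tr2, ev2)$winter))
  expect_equal(count_vacillations(tr2, ev2, wr2), 0)
})

test_that("resident season percentiles interpolate and round half-up", {
  mk_event <- function(ss, se, fs, fe) {
    structure(list(verdict = "migrant", animal_id = "x",
                   spring_start = as.Date(ss), spring_end = as.Date(se),
                   fall_start = as.Date(fs), fall_end = as.Date(fe),
                   truncated = FALSE), class = "migration_event")
  }
  d <- as.Date("2018-06-10")
  # dates {d, d+3, d+6}: P33 lands at d + 1.98 -> rounds to d + 2
  ev <- list(mk_event(d, d + 10, "2018-09-01", "2018-09-10"),
             mk_event(d + 3, d + 13, "2018-09-04", "2018-09-13"),
             mk_event(d + 6, d + 16, "2018-09-07", "2018-09-16"))
  rs <- resident_seasons(ev)
  expect_equal(rs$winter[2] - 365, d + 2)          # P33 of spring starts
  expect_equal(rs$summer[1], d + 10 + 4)           # P66 = +3.96 -> +4
  expect_equal(rs$summer[2], as.Date("2018-09-01") + 2)

  # identical dates collapse to those dates
  ev_same <- list(mk_event(d, d + 5, "2018-09-01", "2018-09-08"),
                  mk_event(d, d + 5, "2018-09-01", "2018-09-08"),
                  mk_event(d, d + 5, "2018-09-01", "2018-09-08"))
  rs2 <- resident_seasons(ev_same)
  expect_equal(rs2$summer, c(d + 5, as.Date("2018-09-01")))

  expect_error(resident_seasons(ev[1:2]), ">= 3")
})
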