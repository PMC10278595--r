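# Seeded ground-truthed track simulator.
#
# Movement model: a piecewise itinerary of residence, travel and dwell
# segments defines a mean path mu(t); the animal's true position is
# mu(t) + J(t) * U(t), where U is a unit-variance Ornstein-Uhlenbeck process
# (band-wide, so band members co-move) and J(t) the segment's jitter SD;
# band members add an independent small OU offset; observed positions add
# Gaussian location error (default 30 m SD). Elevation behaviour is realized
# by routing the itinerary across a synthetic DEM (flat, ramp or Gaussian
# ridge), so the DEM-extraction path is exercised end-to-end.
#
# Six archetypes are built in, mirroring the observed strategy taxonomy:
# long-distance (> 20 km) and short-distance geographic migrants, vacillating
# migrants (>= 2 mid-summer returns to the winter range), traditional
# (low winter / high summer, |delta| > 250 m) and abbreviated (high winter
# and summer with spring/fall descents) altitudinal migrants, and residents.

STRATEGIES <- c("LDM", "SDM", "VAC", "TRAD_ALT", "ABR_ALT", "RESIDENT")

#' Simulation configuration for one animal (or one band)
#'
#' Defaults encode the study conditions the simulator emulates: 2 h fixes
#' over one annual cycle starting 1 Feb, 30 m location error, spring
#' migration departing around 10 Jun and lasting 4-8 days, fall migration
#' around 1 Sep lasting 5-10 days (fall legs cover the first ~45% of the
#' return quickly, then stage at stopovers), winter/summer residence jitter
#' of 500/1000 m for geographic migrants, and a Gaussian-ridge DEM for the
#' altitudinal archetypes with ~390 m of relief between the traditional
#' migrant's seasonal sites.
#'
#' @param strategy one of `"LDM"`, `"SDM"`, `"VAC"`, `"TRAD_ALT"`,
#'   `"ABR_ALT"`, `"RESIDENT"`.
#' @param seed integer master seed; every draw derives from it.
#' @param winter_centroid metric coordinates of the winter (or year-round)
#'   range centre.
#' @param separation_m winter-to-summer centroid separation; defaults to
#'   30 km (LDM), 12 km (SDM/VAC), 900 m (TRAD_ALT), 0 otherwise.
#' @param bearing_deg migration bearing, degrees clockwise from north.
#' @param n_stopovers_spring,n_stopovers_fall planted stopovers per leg.
#' @param stopover_dwell_h dwell at each stopover (h).
#' @param n_vacillations number of mid-summer returns (VAC only, >= 2).
#' @param fix_interval_h programmed fix interval (h).
#' @param start,end simulation span (Dates or strings).
#' @param loc_error_sd_m GPS error SD (m).
#' @param jitter named list of residence/leg/dwell jitter SDs (m).
#' @param ou_tau_h relaxation time of the residence OU process (h).
#' @param dem_kind `"flat"`, `"ramp"` or `"ridge"`; chosen by strategy when
#'   NULL.
#' @param dropout_frac fraction of fixes dropped uniformly at random, to
#'   emulate missed fixes.
#' @param n_spikes number of planted teleportation errors (60 km) for
#'   speed-filter tests.
#' @param animal_id id string.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(strategy, seed,
                       winter_centroid = c(455000, 6573000),
                       separation_m = NULL, bearing_deg = 35,
                       n_stopovers_spring = 1, n_stopovers_fall = 2,
                       stopover_dwell_h = 24,
                       n_vacillations = if (strategy == "VAC") 3 else 0,
                       fix_interval_h = 2,
                       start = "2018-02-01", end = "2019-01-31",
                       loc_error_sd_m = 30,
                       jitter = NULL, ou_tau_h = 6,
                       dem_kind = NULL, dropout_frac = 0, n_spikes = 0,
                       animal_id = sprintf("sim%03d", seed)) {
  strategy <- match.arg(strategy, STRATEGIES)
  separation_m <- separation_m %||% switch(strategy,
    LDM = 30000, SDM = 12000, VAC = 12000, TRAD_ALT = 900,
    ABR_ALT = 0, RESIDENT = 0)
  if (strategy == "LDM" && separation_m <= 20000) {
    stop("long-distance strategy needs > 20 km separation")
  }
  if (strategy %in% c("SDM", "VAC") &&
      (separation_m > 20000 || separation_m < 2000)) {
    stop("short-distance strategy needs a 2-20 km separation")
  }
  if (strategy == "VAC" && n_vacillations < 2) {
    stop("a vacillating migrant returns at least twice")
  }
  if (strategy != "VAC") n_vacillations <- 0
  jitter <- modify_config(list(
    winter = if (strategy %in% c("TRAD_ALT", "ABR_ALT")) 350
             else if (strategy == "RESIDENT") 400 else 500,
    summer = if (strategy %in% c("TRAD_ALT", "ABR_ALT")) 350
             else if (strategy == "RESIDENT") 400 else 1000,
    leg = 80, dwell = 60, excursion = 200
  ), jitter %||% list())
  dem_kind <- dem_kind %||%
    if (strategy %in% c("TRAD_ALT", "ABR_ALT")) "ridge" else "flat"
  structure(list(
    strategy = strategy, seed = as.integer(seed),
    winter_centroid = winter_centroid, separation_m = separation_m,
    bearing_deg = bearing_deg,
    n_stopovers_spring = n_stopovers_spring,
    n_stopovers_fall = n_stopovers_fall,
    stopover_dwell_h = stopover_dwell_h,
    n_vacillations = n_vacillations,
    fix_interval_h = fix_interval_h,
    start = as.Date(start), end = as.Date(end),
    loc_error_sd_m = loc_error_sd_m, jitter = jitter,
    ou_tau_h = ou_tau_h, dem_kind = dem_kind,
    dropout_frac = dropout_frac, n_spikes = n_spikes,
    animal_id = animal_id,
    # ridge geometry (m relative to the winter centroid x)
    ridge = list(base = 700, crest = 1100, width = 1500,
                 winter_offset = switch(strategy, TRAD_ALT = 1950, 0),
                 spring_low_offset = 1313, fall_low_offset = -1151)
  ), class = "sim_config")
}

# --- itinerary -------------------------------------------------------------

seg <- function(t0, t1, type, p0, p1 = p0, sd = 60) {
  if (t1 <= t0) stop("infeasible schedule: segment ends before it starts")
  data.frame(t0 = t0, t1 = t1, type = type,
             x0 = p0[1], y0 = p0[2], x1 = p1[1], y1 = p1[2], sd = sd)
}

# Travel legs visit stopovers at fixed route fractions.  Spring stopovers
# sit mid-route; fall stopovers sit in the lower-NSD half (closer to the
# winter range), with ~45% of the return covered in the first day.
leg_segments <- function(t_dep, t_arr, from, to, waypt, stop_fracs,
                         dwell_h, jit, first_day_frac = NA) {
  path <- rbind(from, waypt, to)
  cum <- c(0, cumsum(sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)))
  total <- cum[length(cum)]
  at_frac <- function(f) {
    d <- f * total
    i <- findInterval(d, cum, rightmost.closed = TRUE)
    i <- min(i, nrow(path) - 1)
    w <- (d - cum[i]) / (cum[i + 1] - cum[i])
    path[i, ] * (1 - w) + path[i + 1, ] * w
  }
  fr <- sort(unique(c(0, stop_fracs, 1)))
  dwell_s <- dwell_h * 3600 * (length(fr) - 2)
  travel_s <- as.numeric(t_arr - t_dep, units = "secs") - dwell_s
  if (travel_s <= 0) stop("infeasible schedule: dwells exceed leg duration")
  out <- NULL
  cursor <- t_dep
  # optional fast first hop covering a fixed fraction in one day
  share <- diff(fr)
  tshare <- share / sum(share)
  if (!is.na(first_day_frac) && length(share) > 1) {
    # compress time of the first hop to one day, stretch the rest
    t1 <- pmin(86400, travel_s * tshare[1])
    rest <- travel_s - t1
    tshare <- c(t1, rest * share[-1] / sum(share[-1])) / travel_s
  }
  for (i in seq_len(length(fr) - 1)) {
    a <- at_frac(fr[i])
    b <- at_frac(fr[i + 1])
    t_end <- cursor + travel_s * tshare[i]
    out <- rbind(out, seg(cursor, t_end, "travel", a, b, jit$leg))
    cursor <- t_end
    if (i < length(fr) - 1) {
      t_end <- cursor + dwell_h * 3600
      out <- rbind(out, seg(cursor, t_end, "stopover", b, sd = jit$dwell))
      cursor <- t_end
    }
  }
  list(segs = out,
       stopover_xy = if (length(fr) > 2) {
         t(vapply(fr[-c(1, length(fr))], at_frac, numeric(2)))
       } else {
         matrix(numeric(0), 0, 2)
       })
}

#' @keywords internal
build_itinerary <- function(cfg) {
  # all date jitters derive from the config seed (shared across a band)
  rs <- local({
    set.seed(child_seed(cfg$seed, 77))
    list(spring_dep = sample(-5:5, 1), spring_dur = sample(4:8, 1),
         fall_dep = sample(-5:5, 1), fall_dur = sample(5:10, 1))
  })
  t0 <- as.POSIXct(paste(cfg$start, "00:00:00"), tz = "UTC")
  t_end <- as.POSIXct(paste(cfg$end, "23:59:59"), tz = "UTC")
  yr <- format(cfg$start, "%Y")
  at <- function(mmdd, off_d = 0, hh = "06:00:00") {
    as.POSIXct(paste0(yr, "-", mmdd, " ", hh), tz = "UTC") + off_d * 86400
  }
  W <- cfg$winter_centroid
  jit <- cfg$jitter
  truth <- list(strategy = cfg$strategy, winter_centroid = W,
                summer_centroid = W, spring_start = NULL, spring_end = NULL,
                fall_start = NULL, fall_end = NULL,
                n_vacillations = cfg$n_vacillations,
                spring_stopovers = matrix(numeric(0), 0, 2),
                fall_stopovers = matrix(numeric(0), 0, 2))

  if (cfg$strategy %in% c("LDM", "SDM", "VAC")) {
    th <- cfg$bearing_deg * pi / 180
    S <- W + cfg$separation_m * c(sin(th), cos(th))
    perp <- c(cos(th), -sin(th))
    waypt <- (W + S) / 2 + 0.07 * cfg$separation_m * perp
    truth$summer_centroid <- S

    sp_dep <- at("06-10", rs$spring_dep)
    sp_arr <- sp_dep + rs$spring_dur * 86400
    fa_dep <- at("09-01", rs$fall_dep)
    fa_arr <- fa_dep + rs$fall_dur * 86400

    spring <- leg_segments(sp_dep, sp_arr, W, S, waypt,
                           stop_fracs = if (cfg$n_stopovers_spring > 0) {
                             seq(0.35, 0.6,
                                 length.out = cfg$n_stopovers_spring)
                           } else {
                             numeric(0)
                           },
                           dwell_h = cfg$stopover_dwell_h, jit = jit)
    # fall fractions measured from the summer end: route runs S -> W, so a
    # fraction g along it sits at 1 - g of the distance from the winter
    # range; keep stopovers in the near-winter half.
    fall <- leg_segments(fa_dep, fa_arr, S, W, waypt,
                         stop_fracs = if (cfg$n_stopovers_fall > 0) {
                           seq(0.45, 0.7,
                               length.out = cfg$n_stopovers_fall)
                         } else {
                           numeric(0)
                         },
                         dwell_h = cfg$stopover_dwell_h, jit = jit,
                         first_day_frac = 0.45)
    segs <- rbind(
      seg(t0, sp_dep, "residence", W, sd = jit$winter),
      spring$segs
    )
    cursor <- sp_arr
    if (cfg$n_vacillations > 0) {
      for (k in seq_len(cfg$n_vacillations)) {
        r_dep <- sp_arr + (1 + 7 * k) * 86400
        segs <- rbind(segs,
          seg(cursor, r_dep, "residence", S, sd = jit$summer),
          seg(r_dep, r_dep + 0.5 * 86400, "travel", S, W, jit$leg),
          seg(r_dep + 0.5 * 86400, r_dep + 2 * 86400, "return_dwell", W,
              sd = jit$dwell),
          seg(r_dep + 2 * 86400, r_dep + 2.5 * 86400, "travel", W, S,
              jit$leg))
        cursor <- r_dep + 2.5 * 86400
      }
    }
    segs <- rbind(segs,
      seg(cursor, fa_dep, "residence", S, sd = jit$summer),
      fall$segs,
      seg(fa_arr, t_end, "residence", W, sd = jit$winter))
    truth$spring_start <- as.Date(sp_dep, tz = "UTC")
    truth$spring_end <- as.Date(sp_arr, tz = "UTC")
    truth$fall_start <- as.Date(fa_dep, tz = "UTC")
    truth$fall_end <- as.Date(fa_arr, tz = "UTC")
    truth$spring_stopovers <- spring$stopover_xy
    truth$fall_stopovers <- fall$stopover_xy
  } else if (cfg$strategy == "TRAD_ALT") {
    # winter low on the ridge flank, summer higher up; slow 20-day drifts
    S <- W + c(-cfg$separation_m, 0)
    truth$summer_centroid <- S
    up0 <- at("06-05", rs$spring_dep)
    up1 <- up0 + 20 * 86400
    dn0 <- at("09-05", rs$fall_dep)
    dn1 <- dn0 + 20 * 86400
    segs <- rbind(
      seg(t0, up0, "residence", W, sd = jit$winter),
      seg(up0, up1, "travel", W, S, jit$leg * 3),
      seg(up1, dn0, "residence", S, sd = jit$summer),
      seg(dn0, dn1, "travel", S, W, jit$leg * 3),
      seg(dn1, t_end, "residence", W, sd = jit$winter))
  } else if (cfg$strategy == "ABR_ALT") {
    SL <- W + c(cfg$ridge$spring_low_offset, 0)
    FL <- W + c(cfg$ridge$fall_low_offset, 0)
    d0 <- at("05-05", rs$spring_dep)
    a0 <- at("06-12", rs$spring_dep)   # start of the gradual ascent
    a1 <- a0 + 26 * 86400
    f0 <- at("09-03", rs$fall_dep)
    f1 <- at("09-28", rs$fall_dep)
    segs <- rbind(
      seg(t0, d0, "residence", W, sd = jit$winter),
      seg(d0, d0 + 0.5 * 86400, "travel", W, SL, jit$leg),
      seg(d0 + 0.5 * 86400, a0, "excursion", SL, sd = jit$excursion),
      seg(a0, a1, "travel", SL, W, jit$leg * 3),
      seg(a1, f0, "residence", W, sd = jit$summer),
      seg(f0, f0 + 0.5 * 86400, "travel", W, FL, jit$leg),
      seg(f0 + 0.5 * 86400, f1, "excursion", FL, sd = jit$excursion),
      seg(f1, f1 + 0.5 * 86400, "travel", FL, W, jit$leg),
      seg(f1 + 0.5 * 86400, t_end, "residence", W, sd = jit$winter))
  } else {
    segs <- seg(t0, t_end, "residence", W, sd = jit$winter)
  }
  rownames(segs) <- NULL
  list(segs = segs, truth = truth)
}

# mean path at arbitrary times
itinerary_mu <- function(segs, tt) {
  ts <- as.numeric(tt)
  s0 <- as.numeric(segs$t0)
  s1 <- as.numeric(segs$t1)
  i <- findInterval(ts, s0)
  i[i < 1] <- 1
  w <- (ts - s0[i]) / pmax(s1[i] - s0[i], 1)
  w <- pmin(pmax(w, 0), 1)
  cbind(segs$x0[i] + w * (segs$x1[i] - segs$x0[i]),
        segs$y0[i] + w * (segs$y1[i] - segs$y0[i]),
        segs$sd[i])
}

# unit-variance OU sampled at (possibly irregular) times
unit_ou <- function(tt, tau_s, seed) {
  set.seed(seed)
  n <- length(tt)
  dt <- diff(as.numeric(tt))
  x <- numeric(n)
  y <- numeric(n)
  x[1] <- stats::rnorm(1)
  y[1] <- stats::rnorm(1)
  rho <- exp(-dt / tau_s)
  sd_inc <- sqrt(1 - rho^2)
  ex <- stats::rnorm(n - 1)
  ey <- stats::rnorm(n - 1)
  for (i in 2:n) {
    x[i] <- rho[i - 1] * x[i - 1] + sd_inc[i - 1] * ex[i - 1]
    y[i] <- rho[i - 1] * y[i - 1] + sd_inc[i - 1] * ey[i - 1]
  }
  cbind(x, y)
}

# --- public simulators -----------------------------------------------------

#' Simulate one GPS track with known ground truth
#'
#' Deterministic given the config's seed. The returned ground truth records
#' the true strategy, migration dates, seasonal centroids, stopover centres
#' and any planted corrupt fixes; it is emitted for validation only and is
#' never consumed by the pipeline.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `track` (a [as_track()] object) and `truth`.
#' @export
#' @examples
#' sim <- simulate_track(sim_config("RESIDENT", seed = 51))
#' sim$track
simulate_track <- function(cfg) {
  out <- simulate_band(1, cfg, spread_m = 0)[[1]]
  out
}

#' Simulate a band of co-moving animals
#'
#' All members follow the same itinerary and share one band-level latent
#' movement process, so they "move together" the way a band does; each
#' member adds an independent offset process with stationary SD
#' `spread_m / 2` and independent observation noise. With `member_cfgs` a
#' band may mix strategies (partial migration): members then share the
#' latent process and the winter centroid but follow their own itineraries.
#'
#' @param n_animals number of members (ignored when `member_cfgs` given).
#' @param cfg band-level [sim_config()]; its seed drives the shared path.
#' @param spread_m typical member offset from the band path (m).
#' @param member_cfgs optional list of per-member configs.
#' @return list of `list(track, truth)` per member.
#' @export
simulate_band <- function(n_animals, cfg, spread_m = 100,
                          member_cfgs = NULL) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  if (is.null(member_cfgs)) {
    member_cfgs <- replicate(n_animals, cfg, simplify = FALSE)
    for (i in seq_len(n_animals)) {
      member_cfgs[[i]]$animal_id <-
        if (n_animals == 1) {
          cfg$animal_id
        } else {
          paste0(cfg$animal_id, letters[i])
        }
    }
  }
  n <- length(member_cfgs)
  t0 <- as.POSIXct(paste(cfg$start, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(cfg$end, "23:59:59"), tz = "UTC")
  tt <- seq(t0, t1, by = cfg$fix_interval_h * 3600)
  U <- unit_ou(tt, cfg$ou_tau_h * 3600, child_seed(cfg$seed, 1))

  lapply(seq_len(n), function(m) {
    mc <- member_cfgs[[m]]
    it <- build_itinerary(mc)
    mu <- itinerary_mu(it$segs, tt)
    if (spread_m > 0) {
      O <- unit_ou(tt, 2 * 3600, child_seed(cfg$seed, 100 + m)) *
        (spread_m / 2)
    } else {
      O <- matrix(0, length(tt), 2)
    }
    set.seed(child_seed(cfg$seed, 200 + m))
    x <- mu[, 1] + mu[, 3] * U[, 1] + O[, 1] +
      stats::rnorm(length(tt), 0, mc$loc_error_sd_m)
    y <- mu[, 2] + mu[, 3] * U[, 2] + O[, 2] +
      stats::rnorm(length(tt), 0, mc$loc_error_sd_m)
    corrupted <- integer(0)
    if (mc$n_spikes > 0) {
      cand <- seq(20, length(tt) - 20)
      corrupted <- sort(sample(cand, mc$n_spikes))
      # keep spikes non-adjacent so each is judged against a clean reference
      while (any(diff(corrupted) < 3)) {
        corrupted <- sort(sample(cand, mc$n_spikes))
      }
      th <- stats::runif(mc$n_spikes, 0, 2 * pi)
      x[corrupted] <- x[corrupted] + 60000 * cos(th)
      y[corrupted] <- y[corrupted] + 60000 * sin(th)
    }
    keep <- rep(TRUE, length(tt))
    if (mc$dropout_frac > 0) {
      keep <- stats::runif(length(tt)) > mc$dropout_frac
      keep[corrupted] <- TRUE
    }
    df <- data.frame(animal_id = mc$animal_id, t = tt[keep],
                     x = x[keep], y = y[keep])
    truth <- it$truth
    truth$corrupted_idx <- match(corrupted, which(keep))
    truth$animal_id <- mc$animal_id
    list(track = as_track(df, crs = "EPSG:32609",
                          capture_date = mc$start,
                          nominal_interval_h = mc$fix_interval_h),
         truth = truth)
  })
}

#' Build the DEM matching a simulation config
#'
#' Covers the given tracks (or the config's centroids) with a 2 km pad;
#' ridge geometry follows the config so the altitudinal archetypes see the
#' intended relief.
#'
#' @param cfg a [sim_config()].
#' @param tracks optional list of tracks to cover.
#' @param cell_m DEM cell size (m, default 20).
#' @return a [dem_raster()].
#' @export
sim_dem <- function(cfg, tracks = NULL, cell_m = 20) {
  if (!is.null(tracks)) {
    xs <- unlist(lapply(tracks, function(tr) range(tr$x)))
    ys <- unlist(lapply(tracks, function(tr) range(tr$y)))
  } else {
    xs <- cfg$winter_centroid[1] + c(-1, 1) * (cfg$separation_m + 3000)
    ys <- cfg$winter_centroid[2] + c(-1, 1) * (cfg$separation_m + 3000)
  }
  pad <- 2000
  extent <- c(min(xs) - pad, max(xs) + pad, min(ys) - pad, max(ys) + pad)
  if (cfg$dem_kind == "ridge") {
    make_dem("ridge", extent, cell_m = cell_m, base = cfg$ridge$base,
             crest = cfg$ridge$crest, ridge_width = cfg$ridge$width,
             ridge_x = cfg$winter_centroid[1] - cfg$ridge$winter_offset)
  } else if (cfg$dem_kind == "ramp") {
    make_dem("ramp", extent, cell_m = cell_m)
  } else {
    make_dem("flat", extent, cell_m = cell_m)
  }
}
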