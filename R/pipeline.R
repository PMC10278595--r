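# End-to-end orchestration: cleaning -> NSD -> ranges -> corridors ->
# elevation -> strategy labels -> cohort summaries.

#' Analyze a cohort of tracks
#'
#' Two passes: first every animal is cleaned, elevation-annotated and run
#' through the NSD migration detector; the migrants' dates then define the
#' percentile season template for residents, after which seasonal ranges,
#' the overlap-based migrant confirmation, vacillation counts, corridors,
#' stopovers, elevation series and the final strategy label are computed
#' per animal.
#'
#' @param tracks list of `sheep_track`s (raw; cleaning is applied here).
#' @param dem a [dem_raster()] or a list of them, one per animal (named or
#'   positional).
#' @param cfg full [default_config()]-shaped config.
#' @param capture_dates optional named list of capture dates.
#' @param do_bands also compute the band partition (default TRUE).
#' @param resident_template optional [resident_seasons()]-shaped override
#'   used when fewer than 3 migrants are available.
#' @return object of class `cohort_analysis`: `records` (per-animal
#'   data.frame), `details` (per-animal list: event, windows, ranges,
#'   corridors, stopovers, elevation), `bands`, `template`, `summary`.
#' @export
analyze_cohort <- function(tracks, dem, cfg = default_config(),
                           capture_dates = NULL, do_bands = TRUE,
                           resident_template = NULL) {
  if (!length(tracks)) stop("no tracks supplied")
  get_dem <- function(i, id) {
    if (inherits(dem, "dem_raster")) return(dem)
    dem[[if (!is.null(names(dem)) && id %in% names(dem)) id else i]]
  }

  # pass 1: clean, annotate, detect
  prepped <- vector("list", length(tracks))
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    id <- tr$animal_id[1]
    cap <- if (!is.null(capture_dates)) as.Date(capture_dates[[id]]) else
      NULL
    tr <- clean_track(tr, capture_date = cap, cfg = cfg$cleaning)
    if (is_unusable(tr)) {
      prepped[[i]] <- list(id = id, track = tr, usable = FALSE)
      next
    }
    tr <- annotate_elevation(tr, get_dem(i, id))
    nsd <- compute_nsd(tr)
    ev <- detect_migration(nsd, cfg = cfg$detector)
    prepped[[i]] <- list(id = id, track = tr, usable = TRUE, nsd = nsd,
                         event = ev)
  }

  migrant_events <- Filter(function(e) inherits(e, "migration_event"),
                           lapply(prepped, `[[`, "event"))
  template <- resident_template
  if (is.null(template)) {
    complete <- Filter(function(e) !is.null(e$fall_end), migrant_events)
    if (length(complete) >= 3) template <- resident_seasons(complete)
  }

  # pass 2: ranges, corridors, elevation, labels
  details <- list()
  rows <- list()
  for (p in prepped) {
    if (!p$usable) {
      rows[[p$id]] <- data.frame(
        animal_id = p$id, usable = FALSE, nsd_verdict = NA_character_,
        geographic_migrant = NA, spring_start = as.Date(NA),
        spring_end = as.Date(NA), fall_start = as.Date(NA),
        fall_end = as.Date(NA), spring_duration_d = NA_real_,
        fall_duration_d = NA_real_, n_vacillations = NA_integer_,
        winter_area_ha = NA_real_, summer_area_ha = NA_real_,
        overlap_area_ha = NA_real_, overlap_pct = NA_real_,
        spring_km = NA_real_, fall_km = NA_real_, distance_km = NA_real_,
        n_stopovers_spring = NA_integer_, n_stopovers_fall = NA_integer_,
        winter_median_m = NA_real_, summer_median_m = NA_real_,
        delta_elev_m = NA_real_, alt_pattern = NA_character_,
        strategy = NA_character_, stringsAsFactors = FALSE)
      next
    }
    tr <- p$track
    ev <- p$event
    is_nsd_migrant <- inherits(ev, "migration_event")
    win <- season_windows(tr, ev, template = template)
    winter <- seasonal_range(tr, win$winter, cfg = cfg)
    summer <- seasonal_range(tr, win$summer, cfg = cfg)

    overlap_pct <- overlap_ha <- NA_real_
    if (!is.null(winter) && !is.null(summer)) {
      ov <- range_overlap(summer, winter)
      overlap_pct <- ov$pct_of_second   # % of the winter range
      overlap_ha <- ov$area_ha
    }
    n_vac <- NA_integer_
    if (is_nsd_migrant && !is.null(winter)) {
      n_vac <- count_vacillations(tr, ev, winter, cfg = cfg$detector)
    }
    # overlap rule confirms the NSD verdict; a vacillating migrant's
    # summer window necessarily revisits the winter range, so >= 2 returns
    # keep migrant status regardless of the inflated overlap
    geographic <- is_nsd_migrant && !is.na(overlap_pct) &&
      (is_geographic_migrant(overlap_pct,
                             cfg$ranges$migrant_overlap_pct) ||
         (!is.na(n_vac) && n_vac >= 2))

    spring_km <- fall_km <- NA_real_
    corridors <- list()
    stopovers <- list(spring = list(), fall = list())
    if (geographic) {
      for (season in c("spring", "fall")) {
        if (season == "fall" && is.null(ev$fall_end)) next
        co <- corridor_ud(tr, ev, season, cfg = cfg)
        corridors[[season]] <- co
        if (season == "spring") spring_km <- co$route_distance_km else
          fall_km <- co$route_distance_km
        if (!is.null(winter) && !is.null(summer)) {
          stopovers[[season]] <- extract_stopovers(
            co, tr, winter, summer, cfg = cfg$corridors)
        }
      }
    }
    distance_km <- if (geographic) {
      reported_distance(spring_km, fall_km, cfg$corridors$distance_leg)
    } else {
      NA_real_
    }

    elev <- elevation_series(tr, win, cfg = cfg$altitude)
    alt <- classify_altitudinal(elev, cfg = cfg$altitude)
    label <- classify_strategy(geographic, n_vac, distance_km,
                               alt$pattern, cfg = cfg$strategy)

    rows[[p$id]] <- data.frame(
      animal_id = p$id, usable = TRUE,
      nsd_verdict = if (is_nsd_migrant) "migrant" else "resident",
      geographic_migrant = geographic,
      spring_start = if (is_nsd_migrant) ev$spring_start else
        as.Date(NA),
      spring_end = if (is_nsd_migrant) ev$spring_end else as.Date(NA),
      fall_start = if (is_nsd_migrant) ev$fall_start else as.Date(NA),
      fall_end = if (is_nsd_migrant && !is.null(ev$fall_end)) {
        ev$fall_end
      } else {
        as.Date(NA)
      },
      spring_duration_d = if (is_nsd_migrant) ev$spring_duration_d else
        NA_real_,
      fall_duration_d = if (is_nsd_migrant) ev$fall_duration_d else
        NA_real_,
      n_vacillations = n_vac,
      winter_area_ha = if (is.null(winter)) NA_real_ else winter$area_ha,
      summer_area_ha = if (is.null(summer)) NA_real_ else summer$area_ha,
      overlap_area_ha = overlap_ha, overlap_pct = overlap_pct,
      spring_km = spring_km, fall_km = fall_km,
      distance_km = distance_km,
      n_stopovers_spring = if (geographic) {
        length(stopovers$spring)
      } else {
        NA_integer_
      },
      n_stopovers_fall = if (geographic && !is.null(ev$fall_end)) {
        length(stopovers$fall)
      } else {
        NA_integer_
      },
      winter_median_m = elev$winter_median_m,
      summer_median_m = elev$summer_median_m,
      delta_elev_m = elev$delta_m,
      alt_pattern = alt$pattern,
      strategy = as.character(label),
      stringsAsFactors = FALSE
    )
    details[[p$id]] <- list(track = tr, event = ev, windows = win,
                            winter_range = winter, summer_range = summer,
                            corridors = corridors, stopovers = stopovers,
                            elevation = elev, alt_verdict = alt,
                            nsd = p$nsd)
  }
  records <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  bands <- NULL
  if (do_bands) {
    wr <- Filter(Negate(is.null),
                 lapply(details, `[[`, "winter_range"))
    if (length(wr) >= 1) {
      trs <- lapply(details[names(wr)], `[[`, "track")
      bands <- assign_bands(wr, trs, cfg = cfg$ranges)
    }
  }

  summary <- summarize_cohort(
    records[records$usable %in% TRUE, , drop = FALSE],
    value_cols = intersect(
      c("winter_area_ha", "summer_area_ha", "overlap_pct", "distance_km",
        "n_vacillations", "n_stopovers_spring", "n_stopovers_fall",
        "winter_median_m", "summer_median_m", "delta_elev_m"),
      names(records)),
    group_col = "geographic_migrant")

  structure(list(records = records, details = details, bands = bands,
                 template = template, summary = summary, cfg = cfg),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d animals\n", nrow(x$records)))
  tab <- table(x$records$strategy, useNA = "ifany")
  for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Run the full pipeline from files or a simulation scenario
#'
#' With `fixes`/`dem` paths, reads collar data and the DEM, analyzes the
#' cohort and writes every output (cleaned fixes, per-animal migration
#' events, strategy table, cohort summary, season template, bands, NSD
#' plots data, range/corridor/stopover GeoJSON) plus a run manifest to
#' `outdir`. With a `scenario`, simulates it first (seeded) and also writes
#' the ground truth. Deterministic given config + seed.
#'
#' @param fixes path to a delimited fix file (see [read_fixes()]).
#' @param dem path to an ESRI ASCII grid DEM, or a [dem_raster()].
#' @param scenario alternatively, a scenario list from
#'   [study_cohort_scenario()] or `list(bands = ...)`.
#' @param outdir output directory (created).
#' @param cfg full config (see [default_config()] / [read_config()]).
#' @param seed integer seed recorded in the manifest and used for any
#'   simulation.
#' @param columns column mapping for `fixes`.
#' @return the `cohort_analysis`, invisibly; outputs land in `outdir`.
#' @export
run_pipeline <- function(fixes = NULL, dem = NULL, scenario = NULL,
                         outdir, cfg = default_config(), seed = 1,
                         columns = movebank_columns()) {
  if (is.null(scenario) == is.null(fixes)) {
    stop("supply either a fixes file or a scenario, not both")
  }
  truth <- NULL
  if (!is.null(scenario)) {
    sims <- simulate_scenario(scenario, seed = seed)
    tracks <- lapply(sims$animals, `[[`, "track")
    truth <- lapply(sims$animals, `[[`, "truth")
    dem_in <- sims$dems
  } else {
    if (is.null(dem)) stop("a DEM is required")
    tracks <- read_fixes(fixes, crs = cfg$crs, columns = columns)
    dem_in <- if (inherits(dem, "dem_raster")) dem else
      read_dem_asc(dem, crs = cfg$crs)
  }
  if (!length(tracks)) stop("no input animals")

  res <- analyze_cohort(tracks, dem_in, cfg = cfg)

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE,
                     na = "")
  }
  recs <- res$records
  for (col in c("spring_start", "spring_end", "fall_start", "fall_end")) {
    if (col %in% names(recs)) recs[[col]] <- format(recs[[col]])
  }
  num <- vapply(recs, is.numeric, logical(1))
  recs[num] <- lapply(recs[num], function(v) round_half_up(v * 10) / 10)
  wr(recs, "animals.csv")
  wr(res$summary, "cohort_summary.csv")
  if (!is.null(res$bands)) wr(res$bands, "bands.csv")
  write_fixes(lapply(res$details, `[[`, "track"),
              file.path(outdir, "cleaned_fixes.csv"))

  for (id in names(res$details)) {
    det <- res$details[[id]]
    wr(det$nsd$daily, paste0(id, "_nsd.csv"))
    wr(det$elevation$daily, paste0(id, "_elevation.csv"))
    gj <- file.path(outdir, paste0(id, "_ranges.geojson"))
    polys <- Filter(Negate(is.null),
                    list(winter = det$winter_range,
                         summer = det$summer_range))
    cors <- lapply(det$corridors, `[[`, "poly95")
    stps <- c(det$stopovers$spring, det$stopovers$fall)
    if (length(polys) || length(cors) || length(stps)) {
      write_geojson(c(polys, cors, stps), gj, crs = cfg$crs)
    }
  }

  if (!is.null(truth)) {
    jsonlite::write_json(
      lapply(truth, function(tt) {
        tt$spring_stopovers <- NULL
        tt$fall_stopovers <- NULL
        lapply(tt, function(v) if (inherits(v, "Date")) format(v) else v)
      }),
      file.path(outdir, "ground_truth.json"), auto_unbox = TRUE,
      null = "null")
  }

  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, cfg_file)
  manifest <- list(
    package = "thinhorn",
    version = as.character(utils::packageVersion("thinhorn")),
    r_version = R.version.string,
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    n_animals = nrow(res$records),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(res)
}
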