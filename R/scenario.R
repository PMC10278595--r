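# Multi-band simulation scenarios.

#' Simulate a multi-band scenario
#'
#' A scenario lists bands; each band gives its member strategies (one
#' shared strategy or a mixed vector for partial migration), an optional
#' separation and bearing, and gets its own winter centroid on a spatial
#' layout grid and its own DEM (ridge when any member is an altitudinal
#' strategy). All randomness derives from `seed`.
#'
#' @param scenario list with `bands` = list of
#'   `list(strategies, separation_m = NULL, bearing_deg = NULL)` and
#'   optional `spread_m` (member offset, default 100).
#' @param seed master seed.
#' @return list with `animals` (list of `list(track, truth)`, with
#'   `truth$band` set), `dems` (named per animal id), `band_of` (named
#'   vector).
#' @export
simulate_scenario <- function(scenario, seed = 1) {
  bands <- scenario$bands
  spread <- scenario$spread_m %||% 100
  n_b <- length(bands)
  # band layout: coarse grid, 25 km spacing
  gx <- ((seq_len(n_b) - 1) %% 3) * 25000
  gy <- ((seq_len(n_b) - 1) %/% 3) * 25000
  animals <- list()
  dems <- list()
  band_of <- character(0)
  for (b in seq_len(n_b)) {
    bd <- bands[[b]]
    strategies <- bd$strategies
    centre <- c(455000 + gx[b], 6573000 + gy[b])
    bearing <- bd$bearing_deg %||% ((b * 40) %% 360)
    bseed <- child_seed(seed, b)
    member_cfgs <- lapply(seq_along(strategies), function(m) {
      sim_config(strategies[m], seed = bseed,
                 winter_centroid = centre,
                 separation_m = if (strategies[m] %in%
                                      c("LDM", "SDM", "VAC")) {
                   bd$separation_m %||% NULL
                 } else {
                   NULL
                 },
                 bearing_deg = bearing,
                 animal_id = sprintf("b%02d_%s%d", b,
                                     tolower(strategies[m]), m))
    })
    band_cfg <- member_cfgs[[1]]
    sims <- simulate_band(length(member_cfgs), band_cfg,
                          spread_m = if (length(member_cfgs) > 1) spread
                                     else 0,
                          member_cfgs = member_cfgs)
    # one DEM per band, ridge if any member needs relief
    alt_members <- strategies %in% c("TRAD_ALT", "ABR_ALT")
    dem_cfg <- member_cfgs[[if (any(alt_members)) which(alt_members)[1]
                            else 1]]
    bdem <- sim_dem(dem_cfg, tracks = lapply(sims, function(s) s$track))
    for (s in sims) {
      id <- s$truth$animal_id
      s$truth$band <- b
      animals[[id]] <- s
      dems[[id]] <- bdem
      band_of[id] <- b
    }
  }
  list(animals = animals, dems = dems, band_of = band_of)
}

#' A sixteen-female, nine-band study-cohort scenario
#'
#' Mirrors the observed band structure and strategy mix of the collared
#' cohort in [cassiar_females()]: five long-distance migrants (with the band of three
#' showing partial migration: one migrant, two abbreviated altitudinal
#' migrants), five short-distance migrants, two vacillating migrants in
#' one band, and two more abbreviated altitudinal migrants; separations
#' follow the reported route distances.
#'
#' @param spread_m member offset from the band path (m).
#' @return a scenario list for [simulate_scenario()].
#' @export
study_cohort_scenario <- function(spread_m = 100) {
  list(spread_m = spread_m, bands = list(
    list(strategies = "LDM", separation_m = 46000),
    list(strategies = "LDM", separation_m = 40000),
    list(strategies = c("LDM", "LDM"), separation_m = 30000),
    list(strategies = c("LDM", "ABR_ALT", "ABR_ALT"),
         separation_m = 26000),
    list(strategies = "SDM", separation_m = 17000),
    list(strategies = c("SDM", "SDM"), separation_m = 14500),
    list(strategies = c("VAC", "VAC"), separation_m = 11000),
    list(strategies = c("SDM", "SDM"), separation_m = 7700),
    list(strategies = c("ABR_ALT", "ABR_ALT"))
  ))
}

#' The 60-track strategy-recovery suite
#'
#' Ten independent single-animal scenarios per strategy, seeds 1-60
#' (seed k drives animal k), default generator settings.
#'
#' @return list of `list(track, truth, dem)` of length 60.
#' @export
recovery_suite <- function() {
  out <- list()
  for (k in 1:60) {
    strat <- STRATEGIES[ceiling(k / 10)]
    cfg <- sim_config(strat, seed = k)
    sim <- simulate_track(cfg)
    sim$dem <- sim_dem(cfg, tracks = list(sim$track))
    out[[sim$truth$animal_id]] <- sim
  }
  out
}
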