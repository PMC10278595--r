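#' Default pipeline configuration
#'
#' Every threshold used anywhere in the pipeline lives here, named, with the
#' field defaults used for Stone's sheep collar data. Override any subset via
#' the `...` arguments of [run_pipeline()] or by editing a YAML file read with
#' [read_config()].
#'
#' The groups are:
#' \describe{
#'   \item{cleaning}{post-capture exclusion window (days), satellite-count
#'     cut (fixes with `n_sats <= min_sats_exclusive` are dropped), speed cut
#'     (km/h), and the minimum fix count below which an animal is flagged
#'     unusable.}
#'   \item{detector}{net-squared-displacement migration detector: fraction of
#'     the 95th percentile of smoothed NSD that defines plateau candidate
#'     days, the multiple of the winter radius a plateau must exceed, the
#'     minimum run length (days) for a candidate run to be considered at all,
#'     the minimum contiguous run length that makes an animal a migrant, and
#'     the minimum number of consecutive fixes inside the winter range that
#'     counts as one vacillating return.}
#'   \item{bbmm}{Brownian bridge estimator: location-error SD (m), UD cell
#'     size (m), number of time-integration steps per bridge and quadrature
#'     rule, the gap (h) beyond which a bridge is skipped, the Gaussian
#'     truncation radius (in SDs), and the sigma1 search bracket (m/sqrt(s)).}
#'   \item{ranges}{isopleth level for seasonal ranges, the summer-on-winter
#'     overlap percentage below which an animal is a geographic migrant,
#'     band-edge thresholds (winter overlap %, co-movement fraction,
#'     proximity m), and the winter-fidelity overlap threshold.}
#'   \item{corridors}{isopleth level for stopover extraction, minimum
#'     occupancy (h), merge distance between site borders (m), and which
#'     migration leg supplies the per-animal reported route distance
#'     (`"spring"`, `"fall"`, `"max"`, or `"mean"`).}
#'   \item{altitude}{moving-window length (days) and whether it is centred,
#'     the traditional-migration elevation change (m), the spring and fall
#'     descent thresholds (m) of the abbreviated pattern, and the whole-year
#'     envelope (m) inside which an animal is an altitudinal resident.}
#'   \item{strategy}{the long/short migration distance cut-off (km).}
#' }
#'
#' @return nested named list of settings.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$detector$plateau_frac
default_config <- function() {
  list(
    crs = "EPSG:32609",
    cleaning = list(
      post_capture_days  = 7,
      min_sats_exclusive = 2,
      max_speed_kmh      = 20,
      min_fixes          = 100
    ),
    detector = list(
      reference_mmdd        = "03-15",
      plateau_frac          = 0.5,
      min_separation_factor = 2,
      min_run_days          = 3,
      migrant_run_days      = 30,
      winter_radius_days    = 30,
      min_return_fixes      = 6
    ),
    bbmm = list(
      sigma2_m       = 30,
      cell_m         = 50,
      n_alpha        = 10,
      alpha_quad     = "midpoint",
      max_bridge_gap_h = 24,
      trunc_sd       = 6,
      sigma1_bracket = c(0.05, 500)
    ),
    ranges = list(
      ud_q                = 0.95,
      migrant_overlap_pct = 20,
      band_overlap_pct    = 70,
      co_movement_frac    = 0.5,
      proximity_m         = 500,
      fidelity_overlap_pct = 50,
      min_window_days     = 30
    ),
    corridors = list(
      stopover_q      = 0.10,
      stopover_min_h  = 12,
      stopover_merge_m = 300,
      pad_h           = 24,
      distance_leg    = "spring"
    ),
    altitude = list(
      window_days        = 14,
      centred            = TRUE,
      trad_delta_m       = 250,
      abr_spring_delta_m = 150,
      abr_fall_delta_m   = 100,
      resident_envelope_m = 150,
      phase_pad_days     = 14
    ),
    strategy = list(
      long_distance_km = 20
    )
  )
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override [default_config()]; everything else
#' keeps its default, so a config file only needs the thresholds it changes.
#'
#' @param path YAML file.
#' @return nested named list as in [default_config()].
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  modify_config(default_config(), user)
}

#' @keywords internal
modify_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}
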