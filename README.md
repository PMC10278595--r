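# thinhorn

Migration-strategy classification for GPS-collared mountain ungulates.

Partially migratory mountain sheep populations mix several movement
strategies: geographic migrants that commute between distinct winter and
summer ranges (long-distance if the route exceeds 20 km), *vacillating*
migrants that return to the winter range two or more times mid-summer,
altitudinal migrants that move mainly in elevation (traditional: low
winter / high summer, |Δ median elevation| > 250 m; abbreviated: high
winter *and* summer with > 150 m spring and > 100 m fall descents), and
residents. `thinhorn` turns raw collar fixes plus a digital elevation
model into that six-way label per animal, along with everything the label
rests on:

* **Cleaning** — capture-effect window, ≤ 2-satellite cut, 20 km/h
  forward speed filter; every rejection keeps its reason.
* **Timing** — net squared displacement (NSD) per fix,
  `NSD_i = ((x_i − x_0)² + (y_i − y_0)²)`, daily medians smoothed by a
  3-day rolling median, and a deterministic plateau detector for spring
  and fall migration dates; resident season windows from the migrant
  cohort's 66th/33rd date percentiles.
* **Brownian bridge movement model**, implemented from first principles:
  between fixes the position at relative time α is Gaussian with mean
  `(1−α)z_a + αz_b` and variance `Tα(1−α)σ₁² + ((1−α)²+α²)σ₂²`;
  σ₁ is a leave-one-out maximum-likelihood estimate, σ₂ = 30 m, densities
  accumulate on a registered 50 m grid with exact per-cell Gaussian
  integrals, and quantile isopleths give ranges (95%) and stopover cores
  (10%).
* **Ranges & bands** — seasonal 95% ranges, summer-on-winter overlap
  (< 20% ⇒ geographic migrant), band partition (> 70% winter overlap +
  co-movement), winter fidelity (> 50% across years).
* **Corridors & stopovers** — migration-window UDs padded ±24 h, route
  distances, top-10% stopover sites screened at 12 h occupancy and merged
  below 300 m edge distance.
* **Elevation** — nearest-cell DEM extraction, 14-day moving means,
  seasonal medians, and the traditional/abbreviated/resident decision.
* **Simulator** — seeded, ground-truthed tracks for all six strategies
  (Ornstein–Uhlenbeck residence jitter, bridge-like travel legs, planted
  stopovers and vacillations, band-level co-movement, synthetic DEMs), so
  every stage has a recovery test.

## Worked example

```r
library(thinhorn)

# simulate a two-female short-distance-migrant band and classify it
sims <- simulate_scenario(
  list(bands = list(list(strategies = c("SDM", "SDM"),
                         separation_m = 12000))), seed = 1)
res <- analyze_cohort(lapply(sims$animals, `[[`, "track"), sims$dems)
res$records[, c("animal_id", "strategy", "distance_km", "overlap_pct",
                "n_stopovers_spring", "n_stopovers_fall")]
#>   animal_id strategy distance_km overlap_pct n_stopovers_spring n_stopovers_fall
#> 1  b01_sdm1      SDM    10.27084           0                  1                2
#> 2  b01_sdm2      SDM    10.78249           0                  1                2
```

Both members are labelled short-distance migrants: their ~10.5 km
detected routes sit below the 20 km long-distance cut, their summer
ranges share 0% of their winter range (far under the 20% migrant
threshold), and the one spring and two fall stopovers planted by the
simulator are recovered exactly.

The published 16-female summary table ships as a fixture and runs through
the same rules:

```r
tab <- cassiar_classified()
table(tab$strategy)
#> ABR_ALT     LDM     SDM     VAC
#>       4       5       5       2
median(tab$distance_km[tab$migrant])   # 16.25 -> prints 16.3 at 1 dp
```

`run_pipeline()` drives the whole chain from a fix CSV + ESRI ASCII DEM
(or a simulation scenario) and writes per-animal tables, cohort
summaries, band assignments, GeoJSON ranges/corridors/stopovers and a run
manifest. A thin command-line wrapper lives at
`inst/scripts/thinhorn-run.R`.

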