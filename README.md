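# trawlwatch

Tools for assessing **fisher self-reported data in small-scale bottom-trawl
fisheries**: cleaning smartphone GPS tracks, inferring trawling activity,
computing per-trip discard proportions, rasterizing effort and discards onto
a 500 m grid, and comparing fisher- versus observer-derived maps with a
similarity-in-means index. Because fleets of this kind rarely release raw
data, the package includes a first-class synthetic fleet simulator with
complete ground truth (tracks, haul intervals, weights, discard proportions,
reporting errors), so the whole pipeline is testable end to end.

It is aimed at fisheries scientists and movement ecologists working with
self-reported or observer-collected vessel tracks at a fixed reporting
cadence (here 3 minutes).

## The core quantities

* **Discard proportion** per trip: `Dp = (Tc − Cc) / Tc`, where `Tc` is the
  total catch weight (sum over hauls) and `Cc` the retained commercial
  weight (sum over species). `0 ≤ Dp ≤ 1`, with violations raised as data
  errors.
* **Trawling classification**: a random forest on step distance, turning
  angle and cyclic time of day, trained on haul-overlay labels and evaluated
  with vessel-disjoint splits; accuracy = correctly classified fixes / all
  fixes.
* **Effort raster**: trawling fixes per 500 m cell × 3 minutes; unfished
  cells are missing, not zero. **Discard raster**: record-weighted mean of
  trip `Dp` per cell.
* **Similarity in means**: per cell `s = 1 − |mA − mB|` where `mA`, `mB` are
  3×3 neighbourhood means of the two maps (min–max normalized to [0, 1]);
  the index is the mean of `s` over valid cells, 0 = opposite local usage,
  1 = identical.

## Worked example

```r
library(trawlwatch)

cfg   <- fleet_config(n_vessels = 4, trips_per_vessel_range = c(8, 10), seed = 42)
fleet <- simulate_fleet(cfg)
fleet
#> <sim_fleet: 35 trips, 4 vessels, 8,830 fixes>

reported <- inject_reporting_errors(fleet, cfg)   # realistic reporting gaps
reported
#> <reported_fleet: 35 trips (33 with track, 28 with catch), 23 injected defects>

cleaned <- clean_pipeline(reported$tracks, cleaning_config_from_fleet(cfg))
cleaned$report
#> <cleaning_report: 33 trips, 31 accepted>
#>   fixes: 7828 in, 7700 retained (60 flagged); removed: 16 dup, 56 out-of-area, 28 land, 28 speed, 0 gap
```

Train the trawling classifier on two vessels and evaluate on the held-out
two (vessel-disjoint, so no autocorrelation leakage):

```r
labels <- do.call(rbind, lapply(cleaned$trajectories, label_from_hauls,
                                hauls = fleet$hauls, source = "truth"))
ds  <- build_activity_dataset(cleaned$trajectories, labels)
sp  <- split_by_vessel(ds, n_train = 2, seed = 42)
mod <- train_classifier(sp$train, seed = 42)
evaluate_classifier(mod, sp$test, sp$train_vessels, sp$test_vessels)
#> <accuracy_report: 3838/3840 fixes correct, accuracy 0.999>
#>               predicted
#> truth          not_trawling trawling
#>   not_trawling         1217        1
#>   trawling                1     2621
```

Discard accounting and reconciliation of tracks against catch reports:

```r
tc <- build_trip_catch(reported$hauls, reported$species, trips = fleet$trip_summary)
s  <- reported$trip_summary
reconcile(s$trip_id[s$has_track], tc$trip_id)
#> <reconciliation: 26 track+catch, 7 track-only, 2 catch-only (track-only rate 0.212)>

head(monthly_summary(tc), 2)
#>     month reporter n   mean_Dp median_Dp       q25       q75
#> 1 2019-10   fisher 3 0.5406874 0.5625252 0.5047372 0.5875566
#> 2 2019-11   fisher 9 0.5688942 0.5779057 0.5059059 0.6292979
```

Effort maps from two independent reporter subsamples of the same fleet, and
their similarity:

```r
spec <- grid_spec(cfg$study_bbox, 500)
fx   <- fleet$tracks[fleet$labels$trawling, c("trip_id", "lon", "lat")]
set.seed(42); ids <- unique(fx$trip_id); a <- sample(ids, 18)
g_f <- rasterize_effort(fx[fx$trip_id %in% a, ],  spec, reporter = "fisher")
g_o <- rasterize_effort(fx[!fx$trip_id %in% a, ], spec, reporter = "observer")
sim_index(normalize_grid(g_f), normalize_grid(g_o))
#> <sim_index: 0.916 over 963 valid cells (3x3 window, valid=either, fill=zero)>
```

The numbers mean: the two half-fleet effort maps agree closely in local
usage (0.92 on a 0–1 scale); the track-only rate of 0.212 reflects the
configured 25% chance that a tracked trip lacks catch records; and the
classifier separates towing (2–3 kn) from steaming (4–6.4 kn) almost
perfectly at the default 10 m GPS noise.

See `vignettes/trawl-discard-pipeline.Rmd` for the full account of the
models, defaults and numerical choices.

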