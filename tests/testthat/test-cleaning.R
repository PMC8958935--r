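cc <- toy_cleaning_config()
t0 <- as.POSIXct("2019-11-05 01:00:00", tz = "UTC")

test_that("trip assembly keys on vessel and noon-to-noon fishing day", {
  # a night trip spanning local midnight stays one trip
  tr <- track_from_xy(cbind(-(0:80) * 200, 0), (0:80) * 180,
                      t0 = as.POSIXct("2019-11-05 01:00:00", tz = "UTC"))  # 20:00-00:03 local
  trips <- assemble_trips(tr, cc)
  expect_length(trips, 1)
  expect_equal(trips[[1]]$fishing_date, as.Date("2019-11-04"))

  # two vessels on the same date are two trips
  tr2 <- rbind(tr, transform(tr, vessel_id = "VY"))
  expect_length(assemble_trips(tr2, cc), 2)

  # an exact duplicate row is collapsed to one retained copy
  tr3 <- rbind(tr, tr[5, ])
  trips3 <- assemble_trips(tr3, cc)
  expect_equal(sum(trips3[[1]]$records$status == "duplicate"), 1)
  expect_equal(sum(trips3[[1]]$records$status == "retained"), nrow(tr))

  expect_length(assemble_trips(tr[0, ], cc), 0)
})

test_that("spatial filter removes out-of-area and land-buffer fixes", {
  xy <- rbind(c(0, 0), c(595, 10), c(-1000, 0), c(0, -50000))
  # fix 2 is 5 m seaward of the coast; fix 4 is ~0.45 deg south of the bbox
  tr <- track_from_xy(xy, (0:3) * 180)
  traj <- assemble_trips(tr, cc)[[1]]
  traj <- filter_spatial(traj, cc)
  expect_equal(traj$records$status, c("retained", "on_land", "retained", "out_of_area"))
  expect_error(filter_spatial(traj, modifyList(cc, list(coastline = NULL))),
               "coastline")
})

test_that("speed filter enforces the 6.5-knot ceiling against the last retained fix", {
  # 0.02 deg of latitude in 180 s is ~24 kn: removed; a 600 m step is 6.48 kn: kept
  xy <- rbind(c(0, 0), c(0, 2226.4), c(-600, 0), c(-1200, 0))
  tr <- track_from_xy(xy, (0:3) * 180)
  traj <- filter_speed(assemble_trips(tr, cc)[[1]], cc)
  expect_equal(traj$records$status, c("retained", "speed", "retained", "retained"))

  # a single-record trajectory passes through unchanged
  tr1 <- track_from_xy(cbind(0, 0), 0)
  traj1 <- filter_speed(assemble_trips(tr1, cc)[[1]], cc)
  expect_equal(traj1$records$status, "retained")

  # distinct positions sharing a timestamp: later record dropped as duplicate
  tr2 <- track_from_xy(rbind(c(0, 0), c(100, 0), c(-300, 0)), c(0, 0, 180))
  traj2 <- filter_speed(assemble_trips(tr2, cc)[[1]], cc)
  expect_equal(sum(traj2$records$status == "duplicate_time"), 1)
})

test_that("gap filter removes only isolated fixes across >5 km jumps", {
  # B six km from both its neighbours: removed, the dense ends survive
  xy <- rbind(c(0, 0), c(-200, 0), c(-6200, 0), c(-500, 100), c(-700, 100))
  tr <- track_from_xy(xy, c(0, 180, 3780, 7380, 7560))
  traj <- filter_gaps(assemble_trips(tr, cc)[[1]], cc)
  expect_equal(traj$records$status[3], "gap_isolated")
  expect_equal(sum(traj$records$status == "retained"), 4)

  # final fix 7 km from its predecessor: removed (endpoint case)
  xy2 <- rbind(c(0, 0), c(-300, 0), c(-600, 0), c(-7600, 0))
  tr2 <- track_from_xy(xy2, c(0, 180, 360, 4000))
  traj2 <- filter_gaps(assemble_trips(tr2, cc)[[1]], cc)
  expect_equal(traj2$records$status[4], "gap_isolated")

  # a 6 km gap between two dense clusters: nothing is isolated, no removal
  xy3 <- rbind(c(0, 0), c(-200, 0), c(-400, 0),
               c(-6400, 0), c(-6600, 0), c(-6800, 0))
  tr3 <- track_from_xy(xy3, c(0, 180, 360, 4000, 4180, 4360))
  traj3 <- filter_gaps(assemble_trips(tr3, cc)[[1]], cc)
  expect_true(all(traj3$records$status == "retained"))
})

test_that("endpoint buffer flags (not deletes) fixes near trip endpoints", {
  # 20 slow fixes milling within 300 m of the start, then a run offshore
  mill <- cbind(150 * cos(seq(0, 6, length.out = 20)),
                150 * sin(seq(0, 6, length.out = 20)))
  away <- cbind(-(1:20) * 560 - 300, 0)
  tr <- track_from_xy(rbind(c(0, 0), mill, away), (0:40) * 180)
  traj <- filter_endpoint_buffer(assemble_trips(tr, cc)[[1]], cc)
  fl <- traj$records$flagged
  expect_equal(sum(fl[2:21]), 20)        # milling fixes flagged
  expect_false(fl[1])                    # the anchor itself is not
  expect_false(any(fl[30:41]))           # mid-track fixes far from both ends
  expect_equal(sum(traj$records$status == "retained"), 41)  # nothing deleted
})

test_that("trip validation enforces the 3 h and 50-fix floors", {
  mk <- function(n, dt) {
    tr <- track_from_xy(cbind(-(seq_len(n) - 1) * 100, 0), (seq_len(n) - 1) * dt)
    assemble_trips(tr, cc)[[1]]
  }
  expect_equal(validate_trip(mk(80, 130), cc),            # 2.85 h, 80 fixes
               list(accepted = FALSE, reason = "min_duration"))
  expect_equal(validate_trip(mk(49, 380), cc),            # 5 h, 49 fixes
               list(accepted = FALSE, reason = "min_records"))
  expect_true(validate_trip(mk(100, 185), cc)$accepted)   # 5.1 h, 100 fixes
})

test_that("regularization interpolates linearly on the 3-minute lattice", {
  # two fixes 360 s apart: the inserted fix is the spatial midpoint
  tr <- data.frame(vessel_id = "VX", time = t0 + c(0, 360),
                   lon = c(-81.20, -81.20), lat = c(-4.20, -4.18))
  traj <- regularize(assemble_trips(tr, cc)[[1]], cc)
  expect_equal(nrow(traj$records), 3)
  expect_equal(traj$records$lat[2], -4.19)
  expect_equal(traj$records$lon[2], -81.20)

  # fixes at 0, 180, 540 s: output at 0, 180, 360, 540 with the 360 s point
  # the midpoint of the 180 -> 540 segment
  tr2 <- data.frame(vessel_id = "VX", time = t0 + c(0, 180, 540),
                    lon = c(-81.20, -81.21, -81.23), lat = c(-4.20, -4.20, -4.22))
  traj2 <- regularize(assemble_trips(tr2, cc)[[1]], cc)
  expect_equal(as.numeric(traj2$records$time - traj2$records$time[1],
                          units = "secs"), c(0, 180, 360, 540))
  expect_equal(traj2$records$lon[3], -81.22)
  expect_equal(traj2$records$lat[3], -4.21)

  # an already-regular track is unchanged
  tr3 <- track_from_xy(cbind(-(0:10) * 400, (0:10) * 30), (0:10) * 180)
  traj3 <- regularize(assemble_trips(tr3, cc)[[1]], cc)
  expect_equal(traj3$records$lon, tr3$lon)
  expect_equal(traj3$records$lat, tr3$lat)

  # convexity: every regularized position lies between its bracketing fixes
  tr4 <- track_from_xy(cbind(-cumsum(runif(20, 100, 500)), cumsum(runif(20, -200, 200))),
                       cumsum(c(0, sample(c(180, 360, 540), 19, replace = TRUE))))
  raw <- assemble_trips(tr4, cc)[[1]]
  reg <- regularize(raw, cc)
  expect_true(all(reg$records$lon >= min(tr4$lon) & reg$records$lon <= max(tr4$lon)))
  for (i in seq_len(nrow(reg$records))) {
    t_i <- reg$records$time[i]
    j <- findInterval(as.numeric(t_i), as.numeric(tr4$time))
    lo <- pmin(tr4$lon[j], tr4$lon[min(j + 1, nrow(tr4))])
    hi <- pmax(tr4$lon[j], tr4$lon[min(j + 1, nrow(tr4))])
    expect_true(reg$records$lon[i] >= lo - 1e-12 && reg$records$lon[i] <= hi + 1e-12)
  }
})

test_that("the hand-built dirty track yields the hand-derived filter counts", {
  tr <- toy_dirty_track()
  expect_equal(nrow(tr), 60)
  res <- clean_pipeline(tr, cc)
  rpt <- res$report$records
  expect_equal(rpt$n_input, 60)
  expect_equal(rpt$n_duplicate, 1)
  expect_equal(rpt$n_on_land, 1)
  expect_equal(rpt$n_out_of_area, 0)
  expect_equal(rpt$n_speed, 1)
  expect_equal(rpt$n_gap, 1)
  expect_equal(rpt$n_retained, 56)
  expect_equal(rpt$n_flagged, 5)
  expect_true(res$report$trips$accepted)
  # conservation: removals + retained = input
  expect_equal(rpt$n_input,
               rpt$n_duplicate + rpt$n_out_of_area + rpt$n_on_land +
                 rpt$n_speed + rpt$n_gap + rpt$n_retained)
})

test_that("the cleaning pipeline is idempotent and conserves counts", {
  cfg <- tiny_fleet_config(n_vessels = 2, trips_per_vessel_range = c(2, 2),
                           seed = 55L, p_duplicate_fix = 0.5, p_land_fix = 0.5)
  fl <- simulate_fleet(cfg)
  deg <- inject_reporting_errors(fl, cfg)
  ccf <- cleaning_config_from_fleet(cfg)
  res1 <- clean_pipeline(deg$tracks, ccf)
  rpt <- res1$report$records
  expect_true(all(rpt$n_input == rpt$n_duplicate + rpt$n_out_of_area +
                    rpt$n_on_land + rpt$n_speed + rpt$n_gap + rpt$n_retained))
  # feed the cleaned output back through: nothing changes
  out1 <- do.call(rbind, lapply(res1$trajectories, as.data.frame))
  res2 <- clean_pipeline(out1[, c("vessel_id", "time", "lon", "lat")], ccf)
  expect_equal(length(res2$trajectories), length(res1$trajectories))
  out2 <- do.call(rbind, lapply(res2$trajectories, as.data.frame))
  rownames(out1) <- rownames(out2) <- NULL
  expect_equal(out2$lon, out1$lon)
  expect_equal(out2$lat, out1$lat)
  expect_equal(out2$time, out1$time)
  expect_equal(out2$flagged, out1$flagged)
  # post speed-filter bound: all consecutive retained speeds <= 6.5 kn
  for (traj in res1$trajectories) {
    r <- traj$records
    sp <- trawlwatch:::step_distances_m(r$lon, r$lat) /
      diff(as.numeric(r$time)) / 0.5144
    expect_true(all(sp <= 6.5 + 1e-9))
  }
  # empty input
  res0 <- clean_pipeline(trawlwatch:::empty_tracks(), ccf)
  expect_length(res0$trajectories, 0)
})

test_that("a full synthetic fleet with no injected errors is accepted in full", {
  cfg <- tiny_fleet_config(n_vessels = 2, trips_per_vessel_range = c(3, 3),
                           seed = 91L)
  fl <- simulate_fleet(cfg)
  res <- clean_pipeline(fl$tracks, cleaning_config_from_fleet(cfg))
  expect_equal(sum(res$report$trips$accepted), length(fl$trips))
  # truncation below 50 fixes is rejected for that reason
  cfg2 <- tiny_fleet_config(n_vessels = 1, trips_per_vessel_range = c(3, 3),
                            seed = 91L, p_truncated_track = 1)
  deg <- inject_reporting_errors(simulate_fleet(cfg2), cfg2)
  res2 <- clean_pipeline(deg$tracks, cleaning_config_from_fleet(cfg2))
  expect_true(all(!res2$report$trips$accepted))
  expect_true(all(res2$report$trips$reason == "min_records"))
})
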