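# Shared fixtures: a tiny fleet configuration, a hand-built dirty track that
# exercises every cleaning filter with known counts, and an independent
# brute-force oracle for the similarity-in-means index.

tiny_fleet_config <- function(...) {
  args <- list(...)
  defaults <- list(n_vessels = 2, trips_per_vessel_range = c(2, 3), seed = 101L,
                   p_missing_catch = 0, p_missing_track = 0,
                   p_truncated_track = 0, p_duplicate_fix = 0, p_land_fix = 0)
  do.call(fleet_config, utils::modifyList(defaults, args))
}

default_bbox <- function() {
  c(lon_min = -81.35, lon_max = -81.05, lat_min = -4.4, lat_max = -4.0)
}

# Build a trajectory data.frame from projected metre offsets relative to an
# anchor, at given second offsets from t0. Inverse of the package's cleaning
# geometry so expected distances are exact by construction.
track_from_xy <- function(xy, secs, vessel_id = "VX",
                          t0 = as.POSIXct("2019-11-05 01:00:00", tz = "UTC"),
                          anchor = NULL, bbox = default_bbox()) {
  proj <- local_projection(bbox)
  if (is.null(anchor)) {
    coast_x <- proj$project(bbox["lon_max"], mean(bbox[c("lat_min", "lat_max")]))[1]
    anchor <- c(coast_x - 600, 2000)  # 600 m offshore, 2 km north of centre
  }
  ll <- proj$unproject(anchor[1] + xy[, 1], anchor[2] + xy[, 2])
  data.frame(vessel_id = vessel_id, time = t0 + secs,
             lon = ll[, "lon"], lat = ll[, "lat"])
}

# Hand-built 60-row dirty track. Contents (hand-derived expectations):
#   60 input rows, 59 distinct fixes:
#   - 1 exact duplicate row (copy of fix 6)            -> removed "duplicate"
#   - 1 fix 5 m seaward of the coastline (inside the
#     10 m land buffer)                                -> removed "on_land"
#   - 1 fix 2226 m north of its predecessor in 180 s
#     (24 kn arrival speed)                            -> removed "speed"
#   - 1 fix 6 km from both neighbours across 1 h gaps
#     (3.2 kn, passes the speed filter)                -> removed "gap_isolated"
#   - 5 early fixes milling within 300 m of the first  -> flagged, retained
#   retained = 60 - 4 = 56 >= 50; span 17,280 s = 4.8 h >= 3 h -> accepted.
toy_dirty_track <- function() {
  steps <- list()
  add <- function(x, y, dt = 180) steps[[length(steps) + 1L]] <<- c(x, y, dt)
  add(0, 0)            # 1 anchor
  add(150, 50)         # 2 \
  add(250, -30)        # 3  |
  add(80, -140)        # 4  | milling inside the 500 m start buffer
  add(-100, 80)        # 5  |
  add(-200, -50)       # 6 /
  add(595, 0)          # 7 5 m seaward of the coast (600 m east of the anchor)
  add(-760, 0)         # 8 back on the water, 562 m from fix 6 (6.1 kn)
  add(-1320, 40)       # 9  westward at ~560 m/step (6.05 kn)
  add(-1880, 0)        # 10
  add(-2440, -40)      # 11
  add(-2440, -40 + 2226)  # 12 speed violator: 2226 m in 180 s = 24.0 kn
  add(-3000, 0)        # 13 560 m from fix 11 over 360 s = 3.0 kn
  add(-3560, 40)       # 14
  add(-4120, 0)        # 15
  # isolated fix across two one-hour gaps (6 km out and ~5.7 km back)
  add(-10120, 0, 3600) # 16 gap spike: 6000 m in 3600 s = 3.2 kn
  add(-4420, 100, 3600)# 17 5700 m from the spike, 3.2 kn
  # slow trawl-like wander; everything > 500 m from both endpoints until the
  # final legs, which step > 500 m so nothing mills inside the end buffer
  x <- -4420; y <- 100
  for (i in 1:40) { x <- x - 230; y <- y + ifelse(i %% 2 == 0, 60, -60); add(x, y) }
  add(x - 560, y)      # 57th distinct... penultimate
  add(x - 1120, y + 30)
  xy <- do.call(rbind, lapply(steps, function(s) s[1:2]))
  secs <- cumsum(c(0, vapply(steps[-1], function(s) s[3], 0)))
  tr <- track_from_xy(xy, secs)
  rbind(tr[1:6, ], tr[6, ], tr[7:nrow(tr), ])  # insert the duplicate row
}

toy_cleaning_config <- function() cleaning_config(study_bbox = default_bbox())

# Independent brute-force similarity-in-means oracle: plain loops over every
# cell and window, no shared code with the implementation.
brute_sim_index <- function(A, B, window = 3, valid_rule = "either", fill = "zero") {
  h <- (window - 1) / 2
  nr <- nrow(A); nc <- ncol(A)
  lmean <- function(M, r, c) {
    vals <- c(); n_in <- 0
    for (dr in -h:h) for (dc in -h:h) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
        n_in <- n_in + 1
        vals <- c(vals, M[rr, cc])
      }
    }
    if (fill == "zero") sum(vals, na.rm = TRUE) / n_in
    else if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }
  s <- c()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    ok <- if (valid_rule == "either") !is.na(A[r, c]) || !is.na(B[r, c])
          else !is.na(A[r, c]) && !is.na(B[r, c])
    if (!ok) next
    ma <- lmean(A, r, c); mb <- lmean(B, r, c)
    if (is.na(ma) || is.na(mb)) next
    s <- c(s, 1 - abs(ma - mb))
  }
  list(index = if (length(s)) mean(s) else NA_real_, n_valid = length(s))
}

random_01_grid <- function(nr, nc, p_na = 0.2) {
  v <- sample(c(0, 0.5, 1), nr * nc, replace = TRUE)
  v[runif(nr * nc) < p_na] <- NA
  matrix(v, nr, nc)
}

# regularized trajectory following a straight line at constant speed, built
# directly (bypasses the simulator) for classifier edge-case tests
straight_trajectory <- function(n, speed_kn, trip_id = "VX_2019-11-04",
                                heading_east = TRUE,
                                t0 = as.POSIXct("2019-11-05 01:00:00", tz = "UTC")) {
  step <- speed_kn * 0.5144 * 180
  xy <- cbind(-(seq_len(n) - 1) * step * ifelse(heading_east, 1, -1), 0)
  tr <- track_from_xy(xy, (seq_len(n) - 1) * 180)
  traj <- trawlwatch:::new_trajectory(trip_id, "VX", as.Date("2019-11-04"),
                                      data.frame(time = tr$time, lon = tr$lon, lat = tr$lat))
  traj$regularized <- TRUE
  traj
}
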