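# Synthetic fleet simulator: night trawl trips with ground-truth activity
# labels, haul weights and spatially structured discard proportions.

APP_SPECIES <- c("coffee_shrimp", "sand_perch", "flounder", "squid",
                 "white_shrimp", "guitarfish")
SPECIES_ALPHA <- c(4, 2, 1.5, 1, 1, 0.5)  # Dirichlet weights, shrimp-dominated

#' Simulate one night trawl trip
#'
#' Generates a single trip for one vessel on one fishing date: departure from
#' port between 18:00 and 22:00 local, alternating transit legs (correlated
#' random heading toward a fishing ground, steaming speed sampled per leg) and
#' trawl legs (sampled towing speed and duration, low-turning-angle path),
#' return to port. Position fixes are emitted at the configured cadence with
#' isotropic GPS noise; per-fix ground-truth trawling flags and per-haul catch
#' weights are returned alongside. The trip's true discard proportion is set
#' by the configured south and offshore gradients evaluated at the mean haul
#' location, plus trip-level noise, clamped to `discard_range`.
#'
#' The trip is reproducible in isolation: its RNG stream is seeded from a
#' child seed derived from the master seed, the vessel id and the date.
#'
#' @param config a [fleet_config()].
#' @param vessel_id character vessel identifier.
#' @param date fishing date (Date or yyyy-mm-dd); the trip departs that
#'   evening local time.
#' @return an object of class `sim_trip`: a list with `records` (time, lon,
#'   lat), `truth` (per-fix trawling flag and haul id), `hauls` (intervals and
#'   total weights), `species` (per-species commercial weights), `true_Dp`.
#' @export
simulate_trip <- function(config, vessel_id, date) {
  stopifnot(inherits(config, "fleet_config"))
  validate_fleet_config(config)
  date <- as.Date(date)
  if (is.na(date)) stop("invalid date")
  seed <- child_seed(config$seed, vessel_id, as.integer(date))
  with_seed(seed, sim_trip_impl(config, vessel_id, date, seed))
}

sim_trip_impl <- function(config, vessel_id, date, seed) {
  proj <- local_projection(config$study_bbox)
  port <- drop(proj$project(config$port_location["lon"], config$port_location["lat"]))
  dt <- config$fix_interval_s
  bb <- proj$project(config$study_bbox[c("lon_min", "lon_max")],
                     config$study_bbox[c("lat_min", "lat_max")])
  xr <- range(bb[, 1]); yr <- range(bb[, 2])

  fishable <- function(x, y) {
    if (x < xr[1] + 1500 || x > xr[2] || y < yr[1] + 1500 || y > yr[2] - 1500) return(FALSE)
    ll <- proj$unproject(x, y)
    cd <- coast_distance(ll[1], ll[2], config$coastline, proj)
    !cd$on_land && cd$dist_m > 1500
  }
  # grounds lie within a night's steaming of the home port, as in a fishery
  # whose effort concentrates off the home town
  max_ground_m <- config$ground_max_km_from_port * 1000
  sample_ground <- function(near = NULL) {
    for (i in 1:500) {
      if (is.null(near)) {
        x <- port[1] + runif(1, -max_ground_m, max_ground_m)
        y <- port[2] + runif(1, -max_ground_m, max_ground_m)
      } else {
        x <- near[1] + runif(1, -4000, 4000)
        y <- near[2] + runif(1, -4000, 4000)
      }
      if (fishable(x, y) &&
          sqrt((x - port[1])^2 + (y - port[2])^2) <= max_ground_m) return(c(x, y))
    }
    stop("could not place a fishing ground inside the study area")
  }

  n_hauls <- sample(seq(config$hauls_per_trip_range[1], config$hauls_per_trip_range[2]), 1)
  grounds <- vector("list", n_hauls)
  grounds[[1]] <- sample_ground()
  if (n_hauls > 1) for (h in 2:n_hauls) grounds[[h]] <- sample_ground(grounds[[h - 1]])
  dur_h <- runif(n_hauls, config$haul_duration_range_h[1], config$haul_duration_range_h[2])
  v_legs <- runif(n_hauls + 1, config$transit_speed_range_kn[1],
                  config$transit_speed_range_kn[2]) * KNOT_MS

  # keep the trip inside one noon-to-noon fishing day: shrink haul durations
  # proportionally when a long draw would cross next-day noon. The transit
  # estimate uses the sampled leg speeds and the expected path-wander factor
  # of the 30-degree heading noise (1 / E[cos] ~ 1.15).
  start_h <- runif(1, 18, 22)
  wp <- do.call(rbind, c(list(port), grounds, list(port)))
  leg_m <- sqrt(rowSums((wp[-1, , drop = FALSE] - wp[-nrow(wp), , drop = FALSE])^2))
  # 2 km slack per leg: tows wander off their ground, so each transit starts
  # away from the planned waypoint
  est_transit_h <- sum((leg_m + 2000) / (v_legs * 0.87)) / 3600 * 1.1
  max_total_h <- 34.75 - start_h
  if (sum(dur_h) + est_transit_h > max_total_h)
    dur_h <- dur_h * max(0.2, (max_total_h - est_transit_h) / sum(dur_h))

  t0 <- as.POSIXct(as.character(date), tz = "UTC") +
    (start_h - config$local_utc_offset_h) * 3600

  x <- port[1]; y <- port[2]
  X <- x; Y <- y; trawl <- FALSE; haul_id <- NA_integer_

  steer <- function(x, y, target, sd_deg, v_ms) {
    # one correlated step toward a target
    ang <- atan2(target[2] - y, target[1] - x) + rnorm(1, 0, sd_deg * pi / 180)
    c(x + v_ms * dt * cos(ang), y + v_ms * dt * sin(ang))
  }
  transit_to <- function(target, v) {
    guard <- 0
    while (sqrt((x - target[1])^2 + (y - target[2])^2) > v * dt && guard < 2000) {
      p <- steer(x, y, target, 30, v)
      x <<- p[1]; y <<- p[2]
      X <<- c(X, x); Y <<- c(Y, y); trawl <<- c(trawl, FALSE); haul_id <<- c(haul_id, NA_integer_)
      guard <- guard + 1
    }
  }
  centre <- c(mean(xr) - 3000, mean(yr))

  for (h in seq_len(n_hauls)) {
    transit_to(grounds[[h]], v_legs[h])
    v <- runif(1, config$trawl_speed_range_kn[1], config$trawl_speed_range_kn[2]) * KNOT_MS
    n_fix <- max(2L, as.integer(round(dur_h[h] * 3600 / dt)))
    ang <- runif(1, 0, 2 * pi)
    # tow back and forth over the ground: reverse heading every ~20-40 min so
    # the vessel stays on its ground instead of drifting miles down-path
    rev_at <- cumsum(sample(7:14, ceiling(n_fix / 7), replace = TRUE))
    for (k in seq_len(n_fix)) {
      if (k %in% rev_at) ang <- ang + pi + rnorm(1, 0, 20 * pi / 180)
      ang <- ang + rnorm(1, 0, 10 * pi / 180)
      nx <- x + v * dt * cos(ang); ny <- y + v * dt * sin(ang)
      tries <- 0
      while (!fishable(nx, ny) && tries < 5) {  # steer back toward open water
        ang <- atan2(centre[2] - y, centre[1] - x) + rnorm(1, 0, 10 * pi / 180)
        nx <- x + v * dt * cos(ang); ny <- y + v * dt * sin(ang)
        tries <- tries + 1
      }
      x <- nx; y <- ny
      X <- c(X, x); Y <- c(Y, y); trawl <- c(trawl, TRUE); haul_id <- c(haul_id, h)
    }
  }
  transit_to(port, v_legs[n_hauls + 1])
  X <- c(X, port[1]); Y <- c(Y, port[2]); trawl <- c(trawl, FALSE); haul_id <- c(haul_id, NA_integer_)

  n <- length(X)
  times <- t0 + (seq_len(n) - 1) * dt
  noisy <- proj$unproject(X + rnorm(n, 0, config$gps_noise_sd_m),
                          Y + rnorm(n, 0, config$gps_noise_sd_m))

  trip_id <- sprintf("%s_%s", vessel_id, format(date))

  # true discard proportion from the (noiseless) mean haul location
  mx <- mean(X[trawl]); my <- mean(Y[trawl])
  mll <- proj$unproject(mx, my)
  off_km <- coast_distance(mll[1], mll[2], config$coastline, proj)$dist_m / 1000
  south_km <- -my / 1000  # projection is centred on the bbox, +y north
  dp <- mean(config$discard_range) +
    config$discard_south_gradient * south_km +
    config$discard_offshore_gradient * off_km +
    rnorm(1, 0, config$dp_noise_sd)
  dp <- min(config$discard_range[2], max(config$discard_range[1], dp))

  haul_tab <- do.call(rbind, lapply(seq_len(n_hauls), function(h) {
    idx <- which(haul_id == h)
    data.frame(trip_id = trip_id, haul_index = h,
               start = times[min(idx)], end = times[max(idx)],
               total_kg = NA_real_)
  }))
  haul_tab$total_kg <- stats::rlnorm(n_hauls, log(config$weight_median_kg), config$weight_sdlog)
  Tc <- sum(haul_tab$total_kg)
  Cc <- (1 - dp) * Tc
  w <- stats::rgamma(length(APP_SPECIES), SPECIES_ALPHA)
  species <- data.frame(trip_id = trip_id, species = APP_SPECIES,
                        kg = Cc * w / sum(w))

  structure(list(
    trip_id = trip_id, vessel_id = vessel_id, date = date, seed = seed,
    mean_haul = c(lon = unname(mll[1]), lat = unname(mll[2])),
    mean_haul_offshore_km = off_km, mean_haul_south_km = south_km,
    records = data.frame(vessel_id = vessel_id, trip_id = trip_id,
                         time = times, lon = noisy[, "lon"], lat = noisy[, "lat"]),
    truth = data.frame(trip_id = trip_id, time = times, trawling = trawl,
                       haul_id = haul_id),
    hauls = haul_tab,
    species = species,
    true_Dp = dp, Tc = Tc, Cc = Cc
  ), class = "sim_trip")
}

#' @export
print.sim_trip <- function(x, ...) {
  cat(sprintf("<sim_trip %s: %d fixes, %d hauls, %.1f h, true Dp = %.3f>\n",
              x$trip_id, nrow(x$records), nrow(x$hauls),
              as.numeric(difftime(max(x$records$time), min(x$records$time), units = "hours")),
              x$true_Dp))
  invisible(x)
}

#' Simulate a whole fleet with tidy truth tables
#'
#' Draws per-vessel trip counts from `trips_per_vessel_range`, assigns each
#' trip a distinct fishing date within the study period, and simulates every
#' trip with [simulate_trip()]. Alongside the list of trips it returns tidy
#' tables: all position records, haul intervals and weights, per-species
#' commercial weights, per-fix truth labels and a per-trip summary.
#'
#' @param config a [fleet_config()].
#' @return an object of class `sim_fleet` with elements `trips` (list of
#'   `sim_trip`), `tracks`, `hauls`, `species`, `labels`, `trip_summary`.
#' @export
simulate_fleet <- function(config) {
  stopifnot(inherits(config, "fleet_config"))
  validate_fleet_config(config)
  if (config$n_vessels == 0) {
    warning("n_vessels = 0: returning an empty fleet")
    return(structure(list(trips = list(), tracks = empty_tracks(),
                          hauls = NULL, species = NULL, labels = NULL,
                          trip_summary = NULL, config = config),
                     class = "sim_fleet"))
  }
  days <- seq(config$start_date, config$end_date, by = "day")
  plan <- with_seed(child_seed(config$seed, "fleet_plan"), {
    lapply(seq_len(config$n_vessels), function(i) {
      n <- sample(seq(config$trips_per_vessel_range[1],
                      config$trips_per_vessel_range[2]), 1)
      n <- min(n, length(days))
      list(vessel_id = sprintf("V%02d", i),
           dates = sort(sample(days, n)))
    })
  })
  trips <- list()
  for (p in plan)
    for (d in p$dates)
      trips[[length(trips) + 1L]] <- simulate_trip(config, p$vessel_id, as.Date(d, origin = "1970-01-01"))
  structure(list(
    trips = trips,
    tracks = do.call(rbind, lapply(trips, `[[`, "records")),
    hauls = do.call(rbind, lapply(trips, `[[`, "hauls")),
    species = do.call(rbind, lapply(trips, `[[`, "species")),
    labels = do.call(rbind, lapply(trips, `[[`, "truth")),
    trip_summary = do.call(rbind, lapply(trips, function(tr)
      data.frame(trip_id = tr$trip_id, vessel_id = tr$vessel_id, date = tr$date,
                 n_fixes = nrow(tr$records), n_hauls = nrow(tr$hauls),
                 true_Dp = tr$true_Dp, Tc = tr$Tc, Cc = tr$Cc,
                 mean_haul_lon = tr$mean_haul["lon"], mean_haul_lat = tr$mean_haul["lat"],
                 south_km = tr$mean_haul_south_km, offshore_km = tr$mean_haul_offshore_km))),
    config = config
  ), class = "sim_fleet")
}

empty_tracks <- function() {
  data.frame(vessel_id = character(), trip_id = character(),
             time = as.POSIXct(character(), tz = "UTC"),
             lon = numeric(), lat = numeric())
}

#' @export
print.sim_fleet <- function(x, ...) {
  cat(sprintf("<sim_fleet: %d trips, %d vessels, %s fixes>\n",
              length(x$trips),
              length(unique(vapply(x$trips, `[[`, "", "vessel_id"))),
              format(if (is.null(x$tracks)) 0L else nrow(x$tracks), big.mark = ",")))
  invisible(x)
}

#' Degrade a simulated fleet with realistic reporting errors
#'
#' Applies, independently per trip: loss of catch records with probability
#' `p_missing_catch` (track kept), loss of all positional fixes with
#' `p_missing_track` (catch kept), truncation of the track below 50 fixes
#' with `p_truncated_track`, injection of exact-duplicate fixes with
#' `p_duplicate_fix`, and displacement of a few early fixes onto land near
#' the port with `p_land_fix`. Every injected defect is recorded in an error
#' ledger that exactly reconciles input and output record counts.
#'
#' @param fleet a `sim_fleet` (or plain list of `sim_trip`).
#' @param config the [fleet_config()] holding the error probabilities and seed.
#' @return an object of class `reported_fleet`: `tracks`, `hauls`, `species`
#'   (the degraded, "as-reported" tables), `trip_summary` with `has_track` /
#'   `has_catch` flags, and `ledger` (trip_id, defect, n_records).
#' @export
inject_reporting_errors <- function(fleet, config) {
  trips <- if (inherits(fleet, "sim_fleet")) fleet$trips else fleet
  if (length(trips) == 0) stop("no trips to degrade")
  proj <- local_projection(config$study_bbox)
  port <- drop(proj$project(config$port_location["lon"], config$port_location["lat"]))

  tracks <- list(); hauls <- list(); species <- list()
  ledger <- list(); summ <- list()
  for (tr in trips) {
    res <- with_seed(child_seed(config$seed, "errors", tr$trip_id),
                     degrade_trip(tr, config, proj, port))
    tracks[[tr$trip_id]] <- res$records
    hauls[[tr$trip_id]] <- res$hauls
    species[[tr$trip_id]] <- res$species
    ledger[[tr$trip_id]] <- res$ledger
    summ[[tr$trip_id]] <- data.frame(
      trip_id = tr$trip_id, vessel_id = tr$vessel_id, date = tr$date,
      has_track = !is.null(res$records) && nrow(res$records) > 0,
      has_catch = !is.null(res$hauls) && nrow(res$hauls) > 0)
  }
  rb <- function(l) { l <- Filter(Negate(is.null), l); if (length(l)) do.call(rbind, c(l, list(make.row.names = FALSE))) else NULL }
  structure(list(tracks = rb(tracks), hauls = rb(hauls), species = rb(species),
                 trip_summary = rb(summ), ledger = rb(ledger)),
            class = "reported_fleet")
}

degrade_trip <- function(tr, config, proj, port) {
  led <- list()
  note <- function(defect, n) led[[length(led) + 1L]] <<-
    data.frame(trip_id = tr$trip_id, defect = defect, n_records = n)
  rec <- tr$records
  hauls <- tr$hauls; spp <- tr$species

  if (stats::runif(1) < config$p_missing_catch) {
    note("missing_catch", nrow(hauls))
    hauls <- NULL; spp <- NULL
  }
  if (stats::runif(1) < config$p_missing_track) {
    note("missing_track", nrow(rec))
    rec <- NULL
  } else {
    if (stats::runif(1) < config$p_truncated_track) {
      k <- sample(10:49, 1)
      note("truncated_track", nrow(rec) - k)
      rec <- rec[seq_len(k), , drop = FALSE]
    }
    if (stats::runif(1) < config$p_land_fix && nrow(rec) >= 10) {
      m <- sample(1:2, 1)
      idx <- sample(seq_len(min(10, nrow(rec))), m)
      land <- proj$unproject(port[1] + stats::runif(m, 20, 120),
                             port[2] + stats::runif(m, -80, 80))
      rec$lon[idx] <- land[, "lon"]; rec$lat[idx] <- land[, "lat"]
      note("land_fix", m)
    }
    if (stats::runif(1) < config$p_duplicate_fix && nrow(rec) >= 2) {
      m <- sample(1:3, 1)
      idx <- sample(seq_len(nrow(rec)), m, replace = TRUE)
      rec <- rbind(rec, rec[idx, , drop = FALSE])
      rec <- rec[order(rec$time), , drop = FALSE]
      note("duplicate_fix", m)
    }
  }
  list(records = rec, hauls = hauls, species = spp,
       ledger = if (length(led)) do.call(rbind, led) else NULL)
}

#' @export
print.reported_fleet <- function(x, ...) {
  cat(sprintf("<reported_fleet: %d trips (%d with track, %d with catch), %d injected defects>\n",
              nrow(x$trip_summary), sum(x$trip_summary$has_track),
              sum(x$trip_summary$has_catch),
              if (is.null(x$ledger)) 0L else nrow(x$ledger)))
  invisible(x)
}
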