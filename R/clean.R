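# Cleaning cascade for self-reported GPS tracks: trip assembly, study-area and
# land filters, speed and gap filters, endpoint buffering, validity checks and
# 3-minute regularization. Removed fixes are kept with a removal reason so
# every filter's accounting is conserved (input = retained + removed).

#' Configuration for the track-cleaning cascade
#'
#' Thresholds for the positional-data filters. Defaults are the fleet's
#' operational envelope: a 10 m land buffer, a 6.5-knot speed ceiling (no
#' vessel in this fleet operates faster), removal of isolated fixes across
#' >5 km gaps, a 500 m buffer around trip endpoints (anchorage milling is
#' excluded from activity classification), a 3 h minimum trip duration, a
#' 50-fix minimum, and 3-minute regularization.
#'
#' @param study_bbox named `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param coastline a [coastline()]; default north-south line on the bbox's
#'   eastern edge with land to the east.
#' @param land_buffer_m fixes within this distance seaward of the coastline
#'   (or on land) are removed.
#' @param max_speed_kn arrival-speed ceiling, knots.
#' @param gap_km gap threshold for the isolated-fix filter, kilometres.
#' @param endpoint_buffer_m radius of the start/end anchorage buffer.
#' @param min_duration_h,min_records trip validity thresholds.
#' @param resample_interval_s regularization cadence, seconds.
#' @param local_utc_offset_h local clock offset used for trip-day assignment.
#' @return an object of class `cleaning_config`.
#' @export
cleaning_config <- function(study_bbox = c(lon_min = -81.35, lon_max = -81.05,
                                           lat_min = -4.4, lat_max = -4.0),
                            coastline = NULL,
                            land_buffer_m = 10,
                            max_speed_kn = 6.5,
                            gap_km = 5,
                            endpoint_buffer_m = 500,
                            min_duration_h = 3,
                            min_records = 50,
                            resample_interval_s = 180,
                            local_utc_offset_h = -5) {
  study_bbox <- validate_bbox(study_bbox)
  if (is.null(coastline)) coastline <- default_coastline(study_bbox)
  thr <- c(land_buffer_m, max_speed_kn, gap_km, endpoint_buffer_m,
           min_duration_h, min_records, resample_interval_s)
  if (any(thr <= 0)) stop("all cleaning thresholds must be strictly positive")
  structure(list(study_bbox = study_bbox, coastline = coastline,
                 land_buffer_m = land_buffer_m, max_speed_kn = max_speed_kn,
                 gap_km = gap_km, endpoint_buffer_m = endpoint_buffer_m,
                 min_duration_h = min_duration_h, min_records = min_records,
                 resample_interval_s = resample_interval_s,
                 local_utc_offset_h = local_utc_offset_h),
            class = "cleaning_config")
}

#' @rdname cleaning_config
#' @param config a [fleet_config()] whose bbox/coastline/cadence to reuse.
#' @export
cleaning_config_from_fleet <- function(config) {
  stopifnot(inherits(config, "fleet_config"))
  cleaning_config(study_bbox = config$study_bbox, coastline = config$coastline,
                  resample_interval_s = config$fix_interval_s,
                  local_utc_offset_h = config$local_utc_offset_h)
}

new_trajectory <- function(trip_id, vessel_id, fdate, records) {
  records$status <- rep("retained", nrow(records))
  records$flagged <- rep(FALSE, nrow(records))
  structure(list(trip_id = trip_id, vessel_id = vessel_id, fishing_date = fdate,
                 records = records, regularized = FALSE),
            class = "trajectory")
}

retained <- function(traj) traj$records$status == "retained"

#' @export
print.trajectory <- function(x, ...) {
  r <- retained(x)
  cat(sprintf("<trajectory %s: %d/%d fixes retained (%d flagged)%s>\n",
              x$trip_id, sum(r), length(r), sum(x$records$flagged[r]),
              if (x$regularized) ", regularized" else ""))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ..., retained_only = TRUE) {
  df <- x$records
  df$vessel_id <- x$vessel_id
  df$trip_id <- x$trip_id
  if (retained_only) df <- df[df$status == "retained", , drop = FALSE]
  rownames(df) <- NULL
  df[, c("vessel_id", "trip_id", "time", "lon", "lat", "status", "flagged")]
}

#' Assemble raw fixes into per-trip trajectories
#'
#' One trajectory per vessel and fishing day (noon-to-noon local clock, see
#' [fishing_date()]), time-sorted. Exact duplicates (same vessel, timestamp
#' and position) are collapsed to one retained copy; the extras stay in the
#' trajectory with status `"duplicate"` so counts are conserved.
#'
#' @param records data.frame with `vessel_id`, `time` (POSIXct UTC), `lon`,
#'   `lat`.
#' @param config a [cleaning_config()].
#' @return list of `trajectory` objects.
#' @export
assemble_trips <- function(records, config = cleaning_config()) {
  if (is.null(records) || nrow(records) == 0) return(list())
  stopifnot(all(c("vessel_id", "time", "lon", "lat") %in% names(records)))
  if (any(is.na(records$time))) stop("unparseable timestamps in input records")
  if (any(abs(records$lat) > 90) || any(abs(records$lon) > 180))
    stop("coordinates out of WGS84 range")
  fd <- fishing_date(records$time, config$local_utc_offset_h)
  key <- paste(records$vessel_id, format(fd), sep = "_")
  out <- list()
  for (k in sort(unique(key))) {
    sub <- records[key == k, , drop = FALSE]
    sub <- sub[order(sub$time), , drop = FALSE]
    traj <- new_trajectory(k, sub$vessel_id[1], fd[key == k][1],
                           data.frame(time = sub$time, lon = sub$lon, lat = sub$lat))
    dup <- duplicated(paste(as.numeric(sub$time), sub$lon, sub$lat))
    traj$records$status[dup] <- "duplicate"
    out[[k]] <- traj
  }
  out
}

#' Study-area and land filter
#'
#' Removes retained fixes outside the study bbox (`"out_of_area"`) and fixes
#' on land or within `land_buffer_m` seaward of the coastline (`"on_land"`).
#'
#' @param traj a `trajectory`.
#' @param config a [cleaning_config()]; must carry a coastline.
#' @return the trajectory with updated per-record status.
#' @export
filter_spatial <- function(traj, config) {
  if (is.null(config$coastline)) stop("cleaning_config has no coastline")
  r <- which(retained(traj))
  if (!length(r)) return(traj)
  lon <- traj$records$lon[r]; lat <- traj$records$lat[r]
  bb <- config$study_bbox
  out <- lon < bb["lon_min"] | lon > bb["lon_max"] |
         lat < bb["lat_min"] | lat > bb["lat_max"]
  traj$records$status[r[out]] <- "out_of_area"
  r2 <- r[!out]
  if (length(r2)) {
    cd <- coast_distance(traj$records$lon[r2], traj$records$lat[r2],
                         config$coastline, local_projection(config$study_bbox))
    land <- cd$on_land | cd$dist_m <= config$land_buffer_m
    traj$records$status[r2[land]] <- "on_land"
  }
  traj
}

#' Speed filter
#'
#' Sequential forward pass: each fix's arrival speed is the haversine distance
#' from the previous *retained* fix divided by the elapsed time; fixes arriving
#' faster than `max_speed_kn` are removed (`"speed"`), so a single bad fix
#' cannot delete its valid neighbour. Distinct fixes sharing a timestamp are
#' treated as duplicates and the later row removed (`"duplicate_time"`).
#'
#' @inheritParams filter_spatial
#' @export
filter_speed <- function(traj, config) {
  r <- which(retained(traj))
  if (length(r) < 2) return(traj)
  tm <- as.numeric(traj$records$time)
  lon <- traj$records$lon; lat <- traj$records$lat
  last <- r[1]
  for (i in r[-1]) {
    dtm <- tm[i] - tm[last]
    if (dtm <= 0) {
      traj$records$status[i] <- "duplicate_time"
      next
    }
    sp_kn <- haversine_m(lon[last], lat[last], lon[i], lat[i]) / dtm / KNOT_MS
    if (sp_kn > config$max_speed_kn) {
      traj$records$status[i] <- "speed"
    } else {
      last <- i
    }
  }
  traj
}

#' Isolated-fix gap filter
#'
#' A retained fix is removed (`"gap_isolated"`) when it sits alone across a
#' large jump: both its adjacent steps exceed `gap_km`, or it is a trajectory
#' endpoint whose only step exceeds `gap_km`. Applied iteratively until
#' stable, since removing an endpoint can expose another isolated fix.
#'
#' @inheritParams filter_spatial
#' @export
filter_gaps <- function(traj, config) {
  gap_m <- config$gap_km * 1000
  repeat {
    r <- which(retained(traj))
    if (length(r) < 2) return(traj)
    d <- step_distances_m(traj$records$lon[r], traj$records$lat[r])
    n <- length(r)
    big <- d > gap_m
    iso <- logical(n)
    iso[1] <- big[1]
    iso[n] <- big[n - 1]
    if (n > 2) iso[2:(n - 1)] <- big[1:(n - 2)] & big[2:(n - 1)]
    if (!any(iso)) return(traj)
    traj$records$status[r[iso]] <- "gap_isolated"
  }
}

#' Endpoint anchorage buffer
#'
#' Flags (does not delete) retained fixes lying within `endpoint_buffer_m` of
#' the first or last retained fix, the anchors themselves excepted. Flagged
#' fixes are excluded from activity classification downstream; keeping them
#' lets effort summaries optionally include transit.
#'
#' @inheritParams filter_spatial
#' @export
filter_endpoint_buffer <- function(traj, config) {
  r <- which(retained(traj))
  if (length(r) < 2) return(traj)
  lon <- traj$records$lon[r]; lat <- traj$records$lat[r]
  n <- length(r)
  d1 <- haversine_m(lon[1], lat[1], lon, lat)
  d2 <- haversine_m(lon[n], lat[n], lon, lat)
  fl <- (d1 <= config$endpoint_buffer_m | d2 <= config$endpoint_buffer_m)
  fl[c(1, n)] <- FALSE
  traj$records$flagged[r] <- fl
  traj
}

#' Trip validity check
#'
#' @inheritParams filter_spatial
#' @return list with `accepted` (logical) and `reason` (`NA`, `"min_duration"`
#'   or `"min_records"`).
#' @export
validate_trip <- function(traj, config) {
  r <- which(retained(traj))
  if (length(r) < config$min_records)
    return(list(accepted = FALSE, reason = "min_records"))
  dur_h <- as.numeric(difftime(traj$records$time[max(r)],
                               traj$records$time[min(r)], units = "hours"))
  if (dur_h < config$min_duration_h)
    return(list(accepted = FALSE, reason = "min_duration"))
  list(accepted = TRUE, reason = NA_character_)
}

#' Regularize a trajectory to a fixed cadence
#'
#' Resamples the retained fixes to exact `resample_interval_s` spacing from
#' the first retained fix, linearly interpolating lon and lat between
#' bracketing fixes; no extrapolation beyond the last fix. Endpoint-buffer
#' flags are recomputed on the regular track. An already-regular track is
#' returned with identical positions.
#'
#' @inheritParams filter_spatial
#' @export
regularize <- function(traj, config) {
  r <- which(retained(traj))
  if (length(r) < 2) stop("cannot regularize a trajectory with < 2 retained fixes")
  tm <- as.numeric(traj$records$time[r])
  tt <- seq(tm[1], tm[length(tm)], by = config$resample_interval_s)
  lon <- stats::approx(tm, traj$records$lon[r], xout = tt)$y
  lat <- stats::approx(tm, traj$records$lat[r], xout = tt)$y
  out <- traj
  out$records <- data.frame(time = as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
                            lon = lon, lat = lat,
                            status = "retained", flagged = FALSE)
  out$regularized <- TRUE
  filter_endpoint_buffer(out, config)
}

#' Full cleaning pipeline
#'
#' Composes the cascade: assemble into vessel-day trips, spatial filter, speed
#' filter, gap filter, endpoint buffer, validity check, regularization. Trips
#' failing validation are returned unregularized under `rejected`.
#'
#' @param records raw fix data.frame (`vessel_id`, `time`, `lon`, `lat`).
#' @param config a [cleaning_config()].
#' @return list with `trajectories` (accepted, regularized), `rejected`
#'   (trajectories + reasons) and `report` (a `cleaning_report`).
#' @export
clean_pipeline <- function(records, config = cleaning_config()) {
  trajs <- assemble_trips(records, config)
  accepted <- list(); rejected <- list()
  rec_rows <- list(); trip_rows <- list()
  for (traj in trajs) {
    n_in <- nrow(traj$records)
    traj <- filter_spatial(traj, config)
    traj <- filter_speed(traj, config)
    traj <- filter_gaps(traj, config)
    traj <- filter_endpoint_buffer(traj, config)
    tab <- table(traj$records$status)
    cnt <- function(s) if (s %in% names(tab)) as.integer(tab[[s]]) else 0L
    v <- validate_trip(traj, config)
    rec_rows[[traj$trip_id]] <- data.frame(
      trip_id = traj$trip_id, n_input = n_in,
      n_duplicate = cnt("duplicate") + cnt("duplicate_time"),
      n_out_of_area = cnt("out_of_area"), n_on_land = cnt("on_land"),
      n_speed = cnt("speed"), n_gap = cnt("gap_isolated"),
      n_retained = cnt("retained"),
      n_flagged = sum(traj$records$flagged[retained(traj)]))
    trip_rows[[traj$trip_id]] <- data.frame(
      trip_id = traj$trip_id, accepted = v$accepted, reason = v$reason)
    if (v$accepted) {
      accepted[[traj$trip_id]] <- regularize(traj, config)
    } else {
      rejected[[traj$trip_id]] <- traj
    }
  }
  report <- structure(list(
    records = if (length(rec_rows)) do.call(rbind, c(rec_rows, list(make.row.names = FALSE))) else NULL,
    trips = if (length(trip_rows)) do.call(rbind, c(trip_rows, list(make.row.names = FALSE))) else NULL
  ), class = "cleaning_report")
  list(trajectories = accepted, rejected = rejected, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  if (is.null(x$trips)) {
    cat("<cleaning_report: empty input>\n")
    return(invisible(x))
  }
  cat(sprintf("<cleaning_report: %d trips, %d accepted>\n",
              nrow(x$trips), sum(x$trips$accepted)))
  tot <- colSums(x$records[, c("n_input", "n_duplicate", "n_out_of_area",
                               "n_on_land", "n_speed", "n_gap", "n_retained", "n_flagged")])
  cat(sprintf("  fixes: %d in, %d retained (%d flagged); removed: %d dup, %d out-of-area, %d land, %d speed, %d gap\n",
              tot["n_input"], tot["n_retained"], tot["n_flagged"], tot["n_duplicate"],
              tot["n_out_of_area"], tot["n_on_land"], tot["n_speed"], tot["n_gap"]))
  invisible(x)
}
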