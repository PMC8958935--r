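#' Configuration for the synthetic shrimp-trawl fleet
#'
#' Defines the behavioural and reporting regime of a simulated small-scale
#' bottom-trawl fleet operating at night off a schematic coastline. Defaults
#' emulate the northern-Peru shrimp fishery this package was built around:
#' trawling at 2--3 knots for 2--3 h per haul, 3--6 hauls per night trip,
#' transit always below the 6.5-knot fleet ceiling, 3-minute position cadence,
#' per-trip discard proportions between 0.19 and 0.95 that increase southward
#' and decrease away from the coast, and fisher reporting failures (about a
#' quarter of tracked trips lack catch records; a smaller share of catch
#' reports lack usable tracks).
#'
#' @param n_vessels number of vessels in the fleet.
#' @param trips_per_vessel_range integer `[min, max]` trips per vessel over the
#'   study period.
#' @param hauls_per_trip_range integer `[min, max]` hauls per trip.
#' @param trawl_speed_range_kn towing speed range, knots; must lie strictly
#'   below 6.5 kn so true fishing fixes survive the speed filter.
#' @param haul_duration_range_h haul duration range, hours.
#' @param transit_speed_range_kn steaming speed range, knots.
#' @param fix_interval_s position-report cadence, seconds.
#' @param study_bbox named `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param coastline a [coastline()]; default: straight north-south line on the
#'   bbox's eastern edge, land to the east.
#' @param port_location named `c(lon, lat)` of the home anchorage (on the
#'   default coastline).
#' @param ground_max_km_from_port fishing grounds are placed within this
#'   steaming range of the port, concentrating effort off the home town.
#' @param discard_range attainable per-trip discard proportion `[min, max]`.
#' @param discard_south_gradient change in discard proportion per km southward
#'   of the bbox centre (positive = more discards in the south).
#' @param discard_offshore_gradient change per km of distance from the coast
#'   (negative = fewer discards offshore).
#' @param dp_noise_sd trip-level Gaussian scatter added to the discard
#'   proportion before clamping to `discard_range`.
#' @param gps_noise_sd_m isotropic GPS noise, metres (per coordinate).
#' @param weight_median_kg,weight_sdlog log-normal per-haul total catch weight
#'   (median and log-sd).
#' @param p_missing_catch probability a tracked trip loses its catch records.
#' @param p_missing_track probability a trip loses all positional fixes.
#' @param p_truncated_track probability a track is cut below 50 fixes.
#' @param p_duplicate_fix probability a track receives exact-duplicate fixes.
#' @param p_land_fix probability a track receives fixes displaced onto land
#'   near the port.
#' @param start_date,end_date study period (Date or yyyy-mm-dd).
#' @param local_utc_offset_h local clock offset from UTC, hours.
#' @param seed master seed; all draws flow through per-trip child seeds.
#' @return an object of class `fleet_config`.
#' @export
fleet_config <- function(n_vessels = 9,
                         trips_per_vessel_range = c(8, 53),
                         hauls_per_trip_range = c(3, 6),
                         trawl_speed_range_kn = c(2, 3),
                         haul_duration_range_h = c(2, 3),
                         transit_speed_range_kn = c(4, 6.4),
                         fix_interval_s = 180,
                         study_bbox = c(lon_min = -81.35, lon_max = -81.05,
                                        lat_min = -4.4, lat_max = -4.0),
                         coastline = NULL,
                         port_location = c(lon = -81.05, lat = -4.18),
                         ground_max_km_from_port = 15,
                         discard_range = c(0.19, 0.95),
                         discard_south_gradient = 0.008,
                         discard_offshore_gradient = -0.006,
                         dp_noise_sd = 0.05,
                         gps_noise_sd_m = 10,
                         weight_median_kg = 50,
                         weight_sdlog = 0.4,
                         p_missing_catch = 0.25,
                         p_missing_track = 0.05,
                         p_truncated_track = 0.08,
                         p_duplicate_fix = 0.3,
                         p_land_fix = 0.2,
                         start_date = "2019-10-01",
                         end_date = "2020-03-31",
                         local_utc_offset_h = -5,
                         seed = 1L) {
  study_bbox <- validate_bbox(study_bbox)
  if (is.null(coastline)) coastline <- default_coastline(study_bbox)
  cfg <- list(
    n_vessels = as.integer(n_vessels),
    trips_per_vessel_range = as.integer(trips_per_vessel_range),
    hauls_per_trip_range = as.integer(hauls_per_trip_range),
    trawl_speed_range_kn = as.numeric(trawl_speed_range_kn),
    haul_duration_range_h = as.numeric(haul_duration_range_h),
    transit_speed_range_kn = as.numeric(transit_speed_range_kn),
    fix_interval_s = as.numeric(fix_interval_s),
    study_bbox = study_bbox,
    coastline = coastline,
    port_location = c(lon = unname(port_location[1]), lat = unname(port_location[2])),
    ground_max_km_from_port = as.numeric(ground_max_km_from_port),
    discard_range = as.numeric(discard_range),
    discard_south_gradient = as.numeric(discard_south_gradient),
    discard_offshore_gradient = as.numeric(discard_offshore_gradient),
    dp_noise_sd = as.numeric(dp_noise_sd),
    gps_noise_sd_m = as.numeric(gps_noise_sd_m),
    weight_median_kg = as.numeric(weight_median_kg),
    weight_sdlog = as.numeric(weight_sdlog),
    p_missing_catch = as.numeric(p_missing_catch),
    p_missing_track = as.numeric(p_missing_track),
    p_truncated_track = as.numeric(p_truncated_track),
    p_duplicate_fix = as.numeric(p_duplicate_fix),
    p_land_fix = as.numeric(p_land_fix),
    start_date = as.Date(start_date),
    end_date = as.Date(end_date),
    local_utc_offset_h = as.numeric(local_utc_offset_h),
    seed = as.integer(seed)
  )
  class(cfg) <- "fleet_config"
  validate_fleet_config(cfg)
  cfg
}

validate_fleet_config <- function(cfg) {
  rng <- function(x, nm) if (length(x) != 2 || x[1] > x[2])
    stop(sprintf("%s must be an ordered [min, max] pair", nm))
  rng(cfg$trips_per_vessel_range, "trips_per_vessel_range")
  rng(cfg$hauls_per_trip_range, "hauls_per_trip_range")
  rng(cfg$trawl_speed_range_kn, "trawl_speed_range_kn")
  rng(cfg$haul_duration_range_h, "haul_duration_range_h")
  rng(cfg$transit_speed_range_kn, "transit_speed_range_kn")
  rng(cfg$discard_range, "discard_range")
  if (cfg$trawl_speed_range_kn[2] >= 6.5)
    stop("trawl speed range must lie strictly below 6.5 kn")
  probs <- c(cfg$p_missing_catch, cfg$p_missing_track, cfg$p_truncated_track,
             cfg$p_duplicate_fix, cfg$p_land_fix)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (cfg$fix_interval_s <= 0) stop("fix_interval_s must be positive")
  if (cfg$n_vessels < 0) stop("n_vessels must be non-negative")
  if (cfg$start_date > cfg$end_date) stop("start_date must precede end_date")
  invisible(cfg)
}

#' @export
print.fleet_config <- function(x, ...) {
  cat("<fleet_config>\n")
  cat(sprintf("  %d vessels, %d-%d trips each, %d-%d hauls/trip\n",
              x$n_vessels, x$trips_per_vessel_range[1], x$trips_per_vessel_range[2],
              x$hauls_per_trip_range[1], x$hauls_per_trip_range[2]))
  cat(sprintf("  trawl %.1f-%.1f kn for %.1f-%.1f h; transit %.1f-%.1f kn; fix every %g s\n",
              x$trawl_speed_range_kn[1], x$trawl_speed_range_kn[2],
              x$haul_duration_range_h[1], x$haul_duration_range_h[2],
              x$transit_speed_range_kn[1], x$transit_speed_range_kn[2], x$fix_interval_s))
  cat(sprintf("  discards %.2f-%.2f (south %+.3f/km, offshore %+.3f/km)\n",
              x$discard_range[1], x$discard_range[2],
              x$discard_south_gradient, x$discard_offshore_gradient))
  cat(sprintf("  reporting: P(miss catch)=%.2f P(miss track)=%.2f P(truncated)=%.2f\n",
              x$p_missing_catch, x$p_missing_track, x$p_truncated_track))
  cat(sprintf("  period %s to %s, seed %d\n", x$start_date, x$end_date, x$seed))
  invisible(x)
}
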