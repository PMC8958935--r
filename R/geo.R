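# Geometric helpers shared across modules. All geographic coordinates are
# WGS84 lon/lat degrees; distances in metres via haversine (geosphere).

#' @keywords internal
KNOT_MS <- 0.5144  # metres per second in one knot

#' Great-circle distance between consecutive fixes
#'
#' @param lon,lat numeric vectors of equal length.
#' @return numeric vector of length `length(lon) - 1`, metres.
#' @keywords internal
step_distances_m <- function(lon, lat) {
  n <- length(lon)
  if (n < 2) return(numeric(0))
  geosphere::distHaversine(cbind(lon[-n], lat[-n]), cbind(lon[-1], lat[-1]))
}

#' @keywords internal
haversine_m <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2))
}

# wrap an angle in degrees to (-180, 180]
wrap_angle <- function(deg) {
  w <- (deg + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

#' Local equirectangular projection
#'
#' A metric tangent-plane projection centred on a study bounding box:
#' x = R * dlon * cos(lat0), y = R * dlat. At ~4 degrees S over a fraction of
#' a degree the planar error is far below GPS noise; it keeps the package free
#' of heavyweight GIS dependencies while giving grids in true metres.
#'
#' @param bbox named numeric `c(lon_min, lon_max, lat_min, lat_max)`.
#' @return an object of class `local_proj` with `$project(lon, lat)` and
#'   `$unproject(x, y)` closures (both return two-column matrices).
#' @export
local_projection <- function(bbox) {
  bbox <- validate_bbox(bbox)
  lon0 <- mean(bbox[c("lon_min", "lon_max")])
  lat0 <- mean(bbox[c("lat_min", "lat_max")])
  R <- 6378137  # radius used by the haversine backend
  kx <- R * pi / 180 * cos(lat0 * pi / 180)
  ky <- R * pi / 180
  structure(list(
    lon0 = lon0, lat0 = lat0, kx = kx, ky = ky,
    project = function(lon, lat) cbind(x = (lon - lon0) * kx, y = (lat - lat0) * ky),
    unproject = function(x, y) cbind(lon = x / kx + lon0, lat = y / ky + lat0)
  ), class = "local_proj")
}

validate_bbox <- function(bbox) {
  if (is.null(names(bbox))) names(bbox) <- c("lon_min", "lon_max", "lat_min", "lat_max")
  need <- c("lon_min", "lon_max", "lat_min", "lat_max")
  if (!all(need %in% names(bbox))) stop("bbox must have lon_min, lon_max, lat_min, lat_max")
  bbox <- bbox[need]
  if (bbox["lon_min"] >= bbox["lon_max"] || bbox["lat_min"] >= bbox["lat_max"])
    stop("degenerate study bbox: zero or negative area")
  bbox
}

#' Coastline model
#'
#' A coastline is an ordered lon/lat polyline with a declared land side
#' ("right" or "left" when walking along the vertex order). The default used
#' throughout the package is a straight north-south line at a bbox's eastern
#' edge with land to the east, a deliberately schematic stand-in for a real
#' shoreline: every test and simulation in the package is relative to the
#' configured line, so no shapefile is required.
#'
#' @param coords two-column matrix or data.frame of lon, lat vertices.
#' @param land_side "right" (default) or "left".
#' @export
coastline <- function(coords, land_side = c("right", "left")) {
  land_side <- match.arg(land_side)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2 || nrow(coords) < 2) stop("coastline needs >= 2 lon/lat vertices")
  colnames(coords) <- c("lon", "lat")
  structure(list(coords = coords, land_side = land_side), class = "coastline")
}

#' @rdname coastline
#' @param bbox study bounding box; the default line sits at its eastern edge.
#' @export
default_coastline <- function(bbox) {
  bbox <- validate_bbox(bbox)
  coastline(cbind(lon = rep(bbox["lon_max"], 2),
                  lat = c(bbox["lat_min"] - 0.5, bbox["lat_max"] + 0.5)),
            land_side = "right")
}

#' Distance to the coastline and land test
#'
#' Computed in a local metric projection: for each point, the minimum distance
#' to any coastline segment, and whether the point lies on the declared land
#' side of its nearest segment.
#'
#' @param lon,lat point coordinates.
#' @param coast a [coastline()] object.
#' @param proj a [local_projection()]; built from the coastline extent if NULL.
#' @return data.frame with `dist_m` (unsigned) and `on_land` (logical).
#' @export
coast_distance <- function(lon, lat, coast, proj = NULL) {
  stopifnot(inherits(coast, "coastline"))
  if (is.null(proj)) {
    ext <- c(lon_min = min(coast$coords[, 1], lon) - 0.01,
             lon_max = max(coast$coords[, 1], lon) + 0.01,
             lat_min = min(coast$coords[, 2], lat) - 0.01,
             lat_max = max(coast$coords[, 2], lat) + 0.01)
    proj <- local_projection(ext)
  }
  P <- proj$project(lon, lat)
  V <- proj$project(coast$coords[, 1], coast$coords[, 2])
  nseg <- nrow(V) - 1
  npt <- nrow(P)
  dmin <- rep(Inf, npt)
  cross_near <- rep(NA_real_, npt)
  for (s in seq_len(nseg)) {
    A <- V[s, ]; B <- V[s + 1, ]
    AB <- B - A
    len2 <- sum(AB^2)
    t <- if (len2 == 0) rep(0, npt) else
      pmin(1, pmax(0, ((P[, 1] - A[1]) * AB[1] + (P[, 2] - A[2]) * AB[2]) / len2))
    dx <- P[, 1] - (A[1] + t * AB[1])
    dy <- P[, 2] - (A[2] + t * AB[2])
    d <- sqrt(dx^2 + dy^2)
    upd <- d < dmin
    # cross product z-component: >0 means point is left of A->B
    cr <- AB[1] * (P[, 2] - A[2]) - AB[2] * (P[, 1] - A[1])
    cross_near[upd] <- cr[upd]
    dmin[upd] <- d[upd]
  }
  on_land <- if (coast$land_side == "right") cross_near < 0 else cross_near > 0
  on_land[dmin == 0] <- TRUE  # exactly on the line counts as shore
  data.frame(dist_m = dmin, on_land = on_land)
}

# local clock helpers: the fishery's local offset is carried in config objects
local_seconds_of_day <- function(time_utc, utc_offset_h) {
  (as.numeric(time_utc) + utc_offset_h * 3600) %% 86400
}

#' Fishing-day assignment (noon-to-noon rule)
#'
#' Night trips routinely cross local midnight, so trips are keyed to the
#' fishing day running from local noon to the next local noon: a fix belongs
#' to the calendar date of the noon that most recently passed.
#'
#' @param time_utc POSIXct, UTC.
#' @param utc_offset_h local offset from UTC in hours (e.g. -5 for Peru).
#' @return Date vector.
#' @export
fishing_date <- function(time_utc, utc_offset_h = -5) {
  as.Date(floor((as.numeric(time_utc) + utc_offset_h * 3600 - 12 * 3600) / 86400),
          origin = "1970-01-01")
}

# deterministic child seed below 2^31, mixing a master seed with strings/ints
child_seed <- function(master, ...) {
  parts <- list(...)
  h <- master %% 2147483647
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
    h <- (h * 1009 + (v %% 1e7) + 1) %% 2147483647
  }
  as.integer(h)
}

# evaluate expr with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
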