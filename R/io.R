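# Plain-text readers and writers for the pipeline's tables: track CSV (ISO
# 8601 UTC timestamps), GPX 1.1, haul/species catch CSVs and grid CSVs.

TIME_FMT <- "%Y-%m-%dT%H:%M:%SZ"

#' Write / read position tracks as CSV
#'
#' Columns: `vessel_id`, `trip_id`, `timestamp` (ISO 8601 UTC), `lon`, `lat`.
#'
#' @param tracks data.frame with `vessel_id`, `time`, `lon`, `lat` and
#'   optionally `trip_id`.
#' @param path file path.
#' @export
write_tracks_csv <- function(tracks, path) {
  out <- data.frame(
    vessel_id = tracks$vessel_id,
    trip_id = if ("trip_id" %in% names(tracks)) tracks$trip_id else NA_character_,
    timestamp = format(tracks$time, TIME_FMT, tz = "UTC"),
    lon = tracks$lon, lat = tracks$lat)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @return `read_tracks_csv`: data.frame with POSIXct `time`.
#' @export
read_tracks_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vessel_id", "timestamp", "lon", "lat")
  if (!all(need %in% names(d))) stop("track CSV must have columns ", paste(need, collapse = ", "))
  tm <- as.POSIXct(d$timestamp, format = TIME_FMT, tz = "UTC")
  if (any(is.na(tm))) stop("unparseable timestamps in ", path)
  data.frame(vessel_id = d$vessel_id,
             trip_id = if ("trip_id" %in% names(d)) d$trip_id else NA_character_,
             time = tm, lon = d$lon, lat = d$lat)
}

#' Write / read tracks as GPX 1.1
#'
#' One `<trk>` per trip (or per vessel when no trip ids exist), one
#' `<trkseg>` of `<trkpt>` elements with ISO 8601 UTC times.
#'
#' @inheritParams write_tracks_csv
#' @export
write_gpx <- function(tracks, path) {
  doc <- xml2::xml_new_root("gpx", version = "1.1", creator = "trawlwatch",
                            xmlns = "http://www.topografix.com/GPX/1/1")
  grp <- if ("trip_id" %in% names(tracks) && !all(is.na(tracks$trip_id)))
    tracks$trip_id else tracks$vessel_id
  for (g in unique(grp)) {
    sub <- tracks[grp == g, , drop = FALSE]
    trk <- xml2::xml_add_child(doc, "trk")
    xml2::xml_add_child(trk, "name", g)
    seg <- xml2::xml_add_child(trk, "trkseg")
    for (i in seq_len(nrow(sub))) {
      pt <- xml2::xml_add_child(seg, "trkpt",
                                lat = format(sub$lat[i], digits = 10),
                                lon = format(sub$lon[i], digits = 10))
      xml2::xml_add_child(pt, "time", format(sub$time[i], TIME_FMT, tz = "UTC"))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_gpx
#' @param vessel_id vessel id attached to points when reading (GPX carries
#'   track names, used as trip ids).
#' @export
read_gpx <- function(path, vessel_id = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  trks <- xml2::xml_find_all(doc, ".//trk")
  if (length(trks) == 0) stop("no <trk> elements in ", path)
  out <- lapply(trks, function(trk) {
    nm <- xml2::xml_text(xml2::xml_find_first(trk, "./name"))
    pts <- xml2::xml_find_all(trk, ".//trkpt")
    data.frame(
      vessel_id = if (is.null(vessel_id)) nm else vessel_id,
      trip_id = nm,
      time = as.POSIXct(xml2::xml_text(xml2::xml_find_all(trk, ".//trkpt/time")),
                        format = TIME_FMT, tz = "UTC"),
      lon = as.numeric(xml2::xml_attr(pts, "lon")),
      lat = as.numeric(xml2::xml_attr(pts, "lat")))
  })
  do.call(rbind, out)
}

#' Write a usage grid as CSV
#'
#' Columns: `row`, `col`, `easting`, `northing`, `lon`, `lat`, `value`
#' (non-missing cells only by default).
#'
#' @param grid a `usage_grid`.
#' @param path file path.
#' @param drop_missing omit missing cells.
#' @export
write_grid_csv <- function(grid, path, drop_missing = TRUE) {
  utils::write.csv(as.data.frame(grid, drop_missing = drop_missing),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write haul and species catch tables as CSV
#'
#' @param hauls data.frame `trip_id`, `haul_index`, `total_kg` (and times).
#' @param species data.frame `trip_id`, `species`, `kg`.
#' @param hauls_path,species_path file paths.
#' @export
write_catch_csv <- function(hauls, species, hauls_path, species_path) {
  h <- hauls
  for (col in c("start", "end"))
    if (col %in% names(h)) h[[col]] <- format(h[[col]], TIME_FMT, tz = "UTC")
  utils::write.csv(h, hauls_path, row.names = FALSE)
  utils::write.csv(species, species_path, row.names = FALSE)
  invisible(c(hauls_path, species_path))
}

#' @rdname write_catch_csv
#' @export
read_hauls_csv <- function(hauls_path) {
  h <- utils::read.csv(hauls_path, stringsAsFactors = FALSE)
  for (col in c("start", "end"))
    if (col %in% names(h)) h[[col]] <- as.POSIXct(h[[col]], format = TIME_FMT, tz = "UTC")
  h
}
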