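# File formats: CSV (GPS streams, per-signal physiology, trip table,
# POIs, weather, image proportions), GeoJSON (routes, buffers, grid) and
# JSON (config, manifests, ground truth). CSV dialect: UTF-8, comma
# separated, "." decimal, ISO-8601 timestamps.

#' Write / read a GPS stream CSV
#'
#' Columns: trip_id, participant_id, timestamp (ISO-8601, UTC), lat, lon.
#' The in-memory representation uses numeric `time_s` (seconds of day).
#'
#' @param stream,path stream data.frame / file path.
#' @param date calendar day for the timestamps (default the stream's
#'   `date` attribute).
#' @export
write_gps_csv <- function(stream, path, date = attr(stream, "date")) {
  date <- date %||% as.Date("2024-09-01")
  out <- data.frame(
    trip_id = stream$trip_id,
    participant_id = stream$participant_id,
    timestamp = format(as.POSIXct(as.Date(date), tz = "UTC") + stream$time_s,
                       "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    lat = stream$lat, lon = stream$lon)
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_gps_csv
#' @return `read_gps_csv`: a stream data.frame with `time_s` seconds and
#'   a `date` attribute.
#' @export
read_gps_csv <- function(path) {
  x <- as.data.frame(data.table::fread(path))
  need <- c("trip_id", "participant_id", "timestamp", "lat", "lon")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("read_gps_csv: missing column(s): ", paste(miss, collapse = ", "))
  ts <- as.POSIXct(x$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  day <- as.Date(ts[1])
  out <- data.frame(trip_id = as.character(x$trip_id),
                    participant_id = as.character(x$participant_id),
                    time_s = as.numeric(ts - as.POSIXct(day, tz = "UTC"),
                                        units = "secs"),
                    lat = x$lat, lon = x$lon)
  attr(out, "date") <- day
  out
}

#' Write / read the trip-level analysis table
#'
#' Mandatory columns `participant_id` and `trip_id`; all other columns
#' round-trip as-is (unknown columns pass through).
#'
#' @param table,path trip table / file path.
#' @export
write_trip_table <- function(table, path) {
  stopifnot(all(c("participant_id", "trip_id") %in% names(table)))
  data.table::fwrite(table, path)
  invisible(path)
}

#' @rdname write_trip_table
#' @export
read_trip_table <- function(path) {
  x <- as.data.frame(data.table::fread(path))
  miss <- setdiff(c("participant_id", "trip_id"), names(x))
  if (length(miss))
    stop("read_trip_table: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  x$participant_id <- as.character(x$participant_id)
  x$trip_id <- as.character(x$trip_id)
  if ("date" %in% names(x)) x$date <- as.Date(x$date)
  x
}

geojson_feature <- function(geometry, properties) {
  list(type = "Feature", properties = properties, geometry = geometry)
}

lonlat_ring <- function(xy, frame) {
  ll <- local_to_lonlat(xy[, 1], xy[, 2], frame)
  lapply(seq_len(nrow(ll)), function(i) c(ll[i, "lon"], ll[i, "lat"]))
}

#' Write routes, buffers or the grid as GeoJSON (WGS84)
#'
#' @param trips list of `walking_trip`s (for `routes_to_geojson`).
#' @param path output file.
#' @export
routes_to_geojson <- function(trips, path) {
  feats <- lapply(trips, function(tr) {
    geojson_feature(
      list(type = "LineString", coordinates = lonlat_ring(tr$route, tr$frame)),
      list(trip_id = tr$trip_id, participant_id = tr$participant_id,
           length_m = tr$length_m, duration_s = tr$duration_s))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = unname(feats)),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' @rdname routes_to_geojson
#' @param grid a `hex_grid`.
#' @param frame `local_frame` used to georeference the grid.
#' @param attributes optional data.frame of per-cell attributes.
#' @export
grid_to_geojson <- function(grid, frame, path, attributes = NULL) {
  feats <- lapply(seq_along(grid$cell_id), function(k) {
    poly <- hex_cell_polygon(grid, grid$cell_id[k])
    props <- list(cell_id = grid$cell_id[k])
    if (!is.null(attributes)) props <- c(props, as.list(attributes[k, , drop = FALSE]))
    geojson_feature(
      list(type = "Polygon", coordinates = list(lonlat_ring(poly, frame))),
      props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = unname(feats)),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' Serialize / restore a pipeline configuration as JSON
#'
#' Round-trips all thresholds so each run can be reproduced from its
#' serialized config.
#'
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

#' Write a run manifest (seed, filter audit counts) as JSON
#' @param manifest named list from [build_trip_table()].
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  manifest$r_version <- as.character(getRversion())
  manifest$package_version <- as.character(utils::packageVersion("walkscape"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
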