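# Buffered environmental aggregation: per-route summaries of gridded
# layers (NDVI, Lden noise, slope), POI counts, streetscape image class
# proportions, and a date-keyed weather join. Cell inclusion is binary
# intersection with the 25-m buffer, unweighted; dispersion uses the
# population convention.

#' Summary statistics of a gridded layer over intersecting cells
#'
#' @param values layer values of the grid cells intersecting the buffer.
#' @return named vector (mean, min, max, sd); all NA (with a warning) when
#'   no cell intersects.
#' @export
raster_stats <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) {
    warning("raster_stats: no intersecting cells")
    return(c(mean = NA_real_, min = NA_real_, max = NA_real_, sd = NA_real_))
  }
  c(mean = mean(values), min = min(values), max = max(values),
    sd = pop_sd(values))
}

#' POI counts per category within a buffer
#'
#' Points on the buffer boundary count (closed region); categories absent
#' from the buffer are reported as zero (the missing-POI rule). Labels
#' outside `categories` are tallied under "other" with a warning.
#'
#' @param buffer a `route_buffer`.
#' @param poi_points data.frame with `x`, `y` (metres) and `category`.
#' @param categories canonical category labels.
#' @return named integer vector over `categories` (plus "other" if hit).
#' @export
poi_counts <- function(buffer, poi_points,
                       categories = poi_categories()) {
  out <- stats::setNames(integer(length(categories)), categories)
  if (nrow(poi_points) == 0L) return(out)
  inside <- buffer_contains(buffer, cbind(poi_points$x, poi_points$y))
  cats <- as.character(poi_points$category[inside])
  unknown <- !(cats %in% categories)
  if (any(unknown)) {
    warning("poi_counts: unknown categories counted as 'other': ",
            paste(unique(cats[unknown]), collapse = ", "))
    cats[unknown] <- "other"
    out <- c(out, other = 0L)
  }
  tab <- table(cats)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Canonical POI categories
#' @return character vector of the eight functional categories.
#' @export
poi_categories <- function() {
  c("leisure", "tourism", "arts", "greenery", "water",
    "services", "commerce", "public")
}

#' Mean streetscape class proportions over images in a buffer
#'
#' Unweighted mean of per-image semantic class proportions across the
#' geolocated images falling inside the buffer. Per-image proportions must
#' sum to one.
#'
#' @param buffer a `route_buffer`.
#' @param images data.frame with `image_id`, `x`, `y` and one column per
#'   class in `classes`.
#' @param classes class column names.
#' @return named vector of mean proportions; all NA (trip flagged via the
#'   `n_images` attribute = 0) when no image falls inside.
#' @export
image_class_means <- function(buffer, images, classes = image_classes()) {
  stopifnot(all(classes %in% names(images)))
  if (nrow(images)) {
    s <- rowSums(images[, classes, drop = FALSE])
    if (any(abs(s - 1) > 1e-9))
      stop("image_class_means: class proportions must sum to 1 per image")
  }
  inside <- if (nrow(images)) buffer_contains(buffer, cbind(images$x, images$y))
            else logical(0)
  if (!any(inside)) {
    out <- stats::setNames(rep(NA_real_, length(classes)), classes)
    attr(out, "n_images") <- 0L
    return(out)
  }
  out <- colMeans(images[inside, classes, drop = FALSE])
  attr(out, "n_images") <- sum(inside)
  out
}

#' Canonical streetscape classes
#' @return character vector of the eight segmentation classes.
#' @export
image_classes <- function() {
  c("vegetation", "sky", "road", "sidewalk",
    "cars", "poles", "curbs", "pedestrians")
}

#' Join daily weather records to trip dates
#'
#' Exact calendar-day match, no interpolation; trips on missing dates get
#' missing fields with a warning. Day-level resolution: trips sharing a
#' date share weather.
#'
#' @param trip_dates Date vector (one per trip).
#' @param weather data.frame keyed by `date` with `t_max`, `t_mean`,
#'   `t_min` (degrees C) and `precip_mm`.
#' @return data.frame of weather fields aligned with `trip_dates`.
#' @export
weather_join <- function(trip_dates, weather) {
  stopifnot(all(c("date", "t_max", "t_mean", "t_min", "precip_mm")
                %in% names(weather)))
  k <- match(as.Date(trip_dates), as.Date(weather$date))
  if (anyNA(k))
    warning("weather_join: ", sum(is.na(k)), " trip date(s) missing from the weather table")
  data.frame(t_max = weather$t_max[k], t_mean = weather$t_mean[k],
             t_min = weather$t_min[k], precip_mm = weather$precip_mm[k])
}

#' Full exposure block for one trip
#'
#' Aggregates every environmental layer of a scene over the trip's
#' buffered route: NDVI and Lden noise mean/min/max/SD over intersecting
#' grid cells, mean slope, POI counts per category, mean image class
#' proportions, and date-matched weather.
#'
#' @param trip a `walking_trip` (with `date` set for the weather join).
#' @param scene an `env_scene` (see [generate_scene()]); any object with
#'   the same layers works.
#' @param buffer_radius_m buffer radius, default 25.
#' @return one-row data.frame of the exposure block.
#' @export
trip_exposures <- function(trip, scene, buffer_radius_m = 25) {
  buf <- buffer_route(scene_route(trip, scene), radius_m = buffer_radius_m)
  cells <- cells_for_route(scene$grid, buf)
  nd <- raster_stats(scene$ndvi[cells])
  no <- raster_stats(scene$noise[cells])
  slope <- if (length(cells)) mean(scene$slope[cells]) else NA_real_
  poi <- poi_counts(buf, scene$poi, categories = poi_categories())
  img <- image_class_means(buf, scene$images, classes = image_classes())
  wx <- if (!is.null(trip$date))
    weather_join(trip$date, scene$weather)
  else data.frame(t_max = NA_real_, t_mean = NA_real_, t_min = NA_real_,
                  precip_mm = NA_real_)
  out <- data.frame(
    ndvi_mean = nd["mean"], ndvi_min = nd["min"], ndvi_max = nd["max"],
    ndvi_sd = nd["sd"],
    noise_lden_mean = no["mean"], noise_lden_min = no["min"],
    noise_lden_max = no["max"], noise_lden_sd = no["sd"],
    slope = slope, row.names = NULL)
  for (cl in image_classes()) out[[paste0("prop_", cl)]] <- unname(img[cl])
  for (pc in poi_categories()) out[[paste0("poi_", pc)]] <- unname(poi[pc])
  cbind(out, wx, n_cells = length(cells),
        n_images = attr(img, "n_images") %||% 0L)
}

# Express a trip's route in the scene's frame (metres).
scene_route <- function(trip, scene) {
  ll <- local_to_lonlat(trip$route[, 1], trip$route[, 2], trip$frame)
  lonlat_to_local(ll[, 1], ll[, 2], scene$frame)
}
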