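# End-to-end pipeline drivers: from raw synthetic inputs to the
# trip-level analysis table and the three inference stages, with a run
# manifest auditing how many records enter and survive each filter.

#' Processing parameters of the pipeline
#'
#' Houses the study constants: 25-m buffer, 25-m hexagonal cells, 500-m
#' gap exclusion, the 2-min/30-C/0.05-uS QC gates, filter and band
#' settings, the alpha = 0.05 and |beta| > 0.1 retention rule, and the
#' elbow search range.
#'
#' @param buffer_radius_m,hex_diameter_m,gap_exclusion_m geometry.
#' @param stop_speed_mps,stop_dwell_s,min_duration_s,max_speed_mps stop
#'   detection.
#' @param qc_min_duration_s,qc_temp_min_c,qc_eda_min_uS session QC gates.
#' @param hrv_window_s,lf_band,hf_band HRV settings.
#' @param sg_window_s,sg_order,hp_cutoff_hz,scr_amp_threshold_uS EDA
#'   settings.
#' @param alpha,beta_gate inference thresholds.
#' @param k_range elbow search range.
#' @param seed analysis seed (K-means restarts).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(buffer_radius_m = 25, hex_diameter_m = 25,
                            gap_exclusion_m = 500,
                            stop_speed_mps = 0.5, stop_dwell_s = 120,
                            min_duration_s = 120, max_speed_mps = 3,
                            qc_min_duration_s = 120, qc_temp_min_c = 30,
                            qc_eda_min_uS = 0.05,
                            hrv_window_s = 10,
                            lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.40),
                            sg_window_s = 2, sg_order = 3,
                            hp_cutoff_hz = 0.05,
                            scr_amp_threshold_uS = 0.01,
                            alpha = 0.05, beta_gate = 0.1,
                            k_range = 2:8, seed = 1L) {
  cfg <- as.list(environment())
  num <- unlist(cfg[c("buffer_radius_m", "hex_diameter_m", "gap_exclusion_m",
                      "stop_speed_mps", "stop_dwell_s", "min_duration_s",
                      "qc_min_duration_s", "qc_temp_min_c", "qc_eda_min_uS",
                      "alpha", "beta_gate")])
  if (any(num <= 0)) stop("pipeline_config: thresholds must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Simulate the raw inputs of a full synthetic study
#'
#' @param config a `gt_config`.
#' @param extent scene extent in metres.
#' @return list with `scene`, `streams` and the config.
#' @export
simulate_study <- function(config = ground_truth_config(),
                           extent = c(0, 3000, 0, 3000)) {
  scene <- generate_scene(config, extent)
  streams <- generate_trips(scene, config)
  list(scene = scene, streams = streams, config = config)
}

#' Build the trip-level analysis table
#'
#' Runs the processing stages over raw streams: GPS cleaning (500-m gap
#' exclusion), stop-detection segmentation, route buffering, buffered
#' environmental aggregation, synthetic wearable sessions, session QC and
#' the 27-indicator physiological summary, then the ground-truth
#' subjective ratings. One row per validated trip.
#'
#' @param sim result of [simulate_study()] (or a list with `scene`,
#'   `streams`, `config`).
#' @param params a `pipeline_config`.
#' @param ratings append ground-truth subjective ratings (default TRUE).
#' @param progress print stage progress.
#' @return list: `table` (trip-level data.frame), `trips` (the
#'   `walking_trip` objects), `manifest` (filter audit counts).
#' @export
build_trip_table <- function(sim, params = pipeline_config(),
                             ratings = TRUE, progress = FALSE) {
  scene <- sim$scene; config <- sim$config
  manifest <- list(seed = config$seed,
                   n_streams_in = length(sim$streams),
                   n_fixes_in = sum(vapply(sim$streams, nrow, integer(1))))
  dropped_gap <- 0L
  trips <- list()
  for (st in sim$streams) {
    cl <- clean_stream(st, gap_m = params$gap_exclusion_m)
    dropped_gap <- dropped_gap + attr(cl, "n_dropped_gap")
    tr <- segment_trips(cl, stop_speed_mps = params$stop_speed_mps,
                        stop_dwell_s = params$stop_dwell_s,
                        min_duration_s = params$min_duration_s,
                        max_speed_mps = params$max_speed_mps)
    for (x in tr) {
      x$date <- attr(st, "date")
      trips[[x$trip_id]] <- x
    }
  }
  manifest$n_fixes_dropped_gap <- dropped_gap
  manifest$n_trips_segmented <- length(trips)
  if (progress) message(length(trips), " segmented trips")
  rows <- vector("list", length(trips))
  qc_fail <- c(duration = 0L, ibi = 0L, contact = 0L)
  for (i in seq_along(trips)) {
    trip <- trips[[i]]
    expo <- trip_exposures(trip, scene, buffer_radius_m = params$buffer_radius_m)
    sess <- generate_physio(trip, scene, config, exposures = expo,
                            seed = (config$seed + 7919L * i) %% .Machine$integer.max)
    qc <- qc_session(sess, min_duration_s = params$qc_min_duration_s,
                     temp_min_c = params$qc_temp_min_c,
                     eda_min_uS = params$qc_eda_min_uS)
    if (!qc$accepted) {
      qc_fail[qc$reason] <- qc_fail[qc$reason] + 1L
      next
    }
    ind <- summarize_trip(sess, window_s = params$hrv_window_s,
                          amp_threshold_uS = params$scr_amp_threshold_uS,
                          sg_window_s = params$sg_window_s,
                          sg_order = params$sg_order,
                          hp_cutoff_hz = params$hp_cutoff_hz, qc = qc)
    rows[[i]] <- cbind(
      data.frame(trip_id = trip$trip_id,
                 participant_id = trip$participant_id,
                 date = trip$date,
                 length_m = trip$length_m,
                 duration_s = trip$duration_s),
      ind, expo)
    if (progress && i %% 200 == 0) message("  processed ", i, " trips")
  }
  manifest$n_sessions_qc_failed <- as.list(qc_fail)
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(tab) <- NULL
  manifest$n_trips_validated <- nrow(tab)
  if (ratings) tab <- generate_ratings(tab, config, seed = config$seed + 2L)
  list(table = tab, trips = trips, manifest = manifest)
}

#' Run the full synthetic study end to end
#'
#' Simulation, table assembly, and the H1/H2/H3 stages.
#'
#' @param config a `gt_config`.
#' @param params a `pipeline_config`.
#' @param extent scene extent.
#' @param progress print stage progress.
#' @return list: `table`, `manifest`, `h1`, `h2`, `h3`, `correlations`.
#' @export
run_study <- function(config = ground_truth_config(),
                      params = pipeline_config(),
                      extent = c(0, 3000, 0, 3000), progress = FALSE) {
  sim <- simulate_study(config, extent)
  built <- build_trip_table(sim, params, progress = progress)
  tab <- built$table
  h1 <- run_h1(tab, alpha = params$alpha)
  h2 <- run_h2(tab, alpha = params$alpha, beta_gate = params$beta_gate)
  h3 <- run_h3(tab, k_range = params$k_range, seed = params$seed)
  corr <- pearson_matrix(tab, intersect(c(rating_outcomes(), h1_predictors(),
                                          "noise_lden_mean", "t_max",
                                          "scr_amp_mean", "rmssd_mean"),
                                        names(tab)))
  list(table = tab, trips = built$trips, manifest = built$manifest,
       scene = sim$scene, h1 = h1, h2 = h2, h3 = h3, correlations = corr)
}
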