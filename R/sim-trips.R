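# Synthetic GPS point streams: constant-ish-speed noisy walks at 1 fix/s
# with configurable injected defects (a >500-m teleport fix; a stationary
# dwell long enough to split the trip) and stored ground-truth
# segmentation for oracle tests.

#' Generate synthetic GPS streams for every trip of the study
#'
#' One stream per (participant, trip): a heading-random-walk at a
#' per-trip base speed drawn from 0.8-1.8 m/s, 1 fix per second, with
#' smooth correlated GPS error. Each participant walks from a home base
#' inside the scene during a two-week window of the study period. With
#' probability `teleport_rate` a single fix is displaced by more than
#' 500 m; with probability `dwell_rate` a stationary dwell of
#' `dwell_s` seconds is inserted mid-trip. The true segmentation (and the
#' defect positions) is stored per stream in attribute `ground_truth`.
#'
#' @param scene an `env_scene`.
#' @param config a `gt_config`.
#' @return list of stream data.frames (trip_id, participant_id, time_s,
#'   lat, lon) with `date` and `ground_truth` attributes.
#' @export
generate_trips <- function(scene, config) {
  ext <- scene$extent
  margin <- 60
  with_seed(config$seed + 1L, {
    streams <- list()
    for (p in seq_len(config$n_participants)) {
      pid <- sprintf("P%03d", p)
      home <- c(runif(1, ext[1] + margin, ext[2] - margin),
                runif(1, ext[3] + margin, ext[4] - margin))
      window_start <- sample(seq_len(nrow(scene$weather) - 13L), 1L)
      for (tr in seq_len(config$trips_per_participant)) {
        trip_id <- sprintf("%s_T%03d", pid, tr)
        date <- scene$weather$date[window_start + sample(0:13, 1L)]
        dur <- round(runif(1, config$trip_duration_range[1],
                           config$trip_duration_range[2]))
        start <- home + runif(2, -200, 200)
        start <- pmin(pmax(start, c(ext[1], ext[3]) + margin),
                      c(ext[2], ext[4]) - margin)
        base_v <- runif(1, 0.8, 1.8)
        dwell <- NULL
        if (runif(1) < config$dwell_rate) {
          ds <- round(runif(1, 0.25 * dur, 0.65 * dur))
          dwell <- c(start_s = ds, end_s = ds + config$dwell_s)
        }
        n <- dur + (if (is.null(dwell)) 0 else config$dwell_s) + 1L
        heading <- runif(1, 0, 2 * pi)
        pos <- matrix(NA_real_, n, 2)
        pos[1, ] <- start
        moving <- rep(TRUE, n - 1L)
        if (!is.null(dwell))
          moving[(dwell[1] + 1L):(dwell[2])] <- FALSE
        dh <- rnorm(n - 1L, 0, 0.15)
        v <- pmax(0.6, pmin(2.2, base_v + rnorm(n - 1L, 0, 0.08)))
        for (i in seq_len(n - 1L)) {
          if (moving[i]) {
            heading <- heading + dh[i]
            step <- v[i] * c(cos(heading), sin(heading))
            cand <- pos[i, ] + step
            # reflect off the scene margin
            if (cand[1] < ext[1] + margin || cand[1] > ext[2] - margin ||
                cand[2] < ext[3] + margin || cand[2] > ext[4] - margin) {
              heading <- heading + pi + rnorm(1, 0, 0.3)
              cand <- pos[i, ] + v[i] * c(cos(heading), sin(heading))
            }
            pos[i + 1L, ] <- cand
          } else {
            pos[i + 1L, ] <- pos[i, ] + rnorm(2, 0, 0.1)
          }
        }
        # smooth correlated GPS error (frozen while stationary)
        err <- matrix(0, n, 2)
        for (i in 2:n) {
          sdv <- if (moving[i - 1L]) 0.3 else 0.03
          err[i, ] <- 0.95 * err[i - 1L, ] + rnorm(2, 0, sdv)
        }
        obs <- pos + err
        teleport_idx <- NA_integer_
        if (runif(1) < config$teleport_rate) {
          teleport_idx <- sample(2:(n - 1L), 1L)
          ang <- runif(1, 0, 2 * pi)
          obs[teleport_idx, ] <- obs[teleport_idx, ] +
            (600 + runif(1, 0, 400)) * c(cos(ang), sin(ang))
        }
        ll <- local_to_lonlat(obs[, 1], obs[, 2], scene$frame)
        t0 <- round(runif(1, 8, 20) * 3600)
        segments <- if (is.null(dwell))
          data.frame(start_s = 0, end_s = n - 1L)
        else
          data.frame(start_s = c(0, dwell[2]), end_s = c(dwell[1], n - 1L))
        st <- data.frame(trip_id = trip_id, participant_id = pid,
                         time_s = t0 + 0:(n - 1L),
                         lat = ll[, 1], lon = ll[, 2])
        attr(st, "date") <- date
        attr(st, "ground_truth") <- list(
          trip_id = trip_id,
          segments = segments + t0,
          dwell = if (is.null(dwell)) NULL else dwell + t0,
          teleport_idx = teleport_idx,
          base_speed_mps = base_v,
          true_route = pos)
        streams[[trip_id]] <- st
      }
    }
    streams
  })
}
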