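# Shared fixtures: all built in code, tiny scales.

# straight-line GPS stream at constant speed (m/s), 1 fix/s, flat equator
# frame so degrees convert simply
straight_stream <- function(n = 300, speed = 1.2, trip_id = "T1",
                            participant_id = "P1", lat0 = 0, lon0 = 0) {
  deg_m <- pi * 6371000 / 180
  if (n == 0)
    return(data.frame(trip_id = character(0), participant_id = character(0),
                      time_s = numeric(0), lat = numeric(0), lon = numeric(0)))
  data.frame(trip_id = trip_id, participant_id = participant_id,
             time_s = seq_len(n) - 1,
             lat = lat0,
             lon = lon0 + speed * (seq_len(n) - 1) / (deg_m * cos(lat0 * pi / 180)))
}

# walk - dwell - walk stream with known segment boundaries
dwell_stream <- function(walk1_s = 240, dwell_s = 300, walk2_s = 240,
                         speed = 1.2) {
  deg_m <- pi * 6371000 / 180
  n <- walk1_s + dwell_s + walk2_s + 1
  moving <- c(rep(TRUE, walk1_s), rep(FALSE, dwell_s), rep(TRUE, walk2_s))
  x <- c(0, cumsum(ifelse(moving, speed, 0)))
  data.frame(trip_id = "T1", participant_id = "P1",
             time_s = 0:(n - 1), lat = 0, lon = x / deg_m)
}

# constant-interval IBI record
const_ibi <- function(ms = 800, duration_s = 150) {
  t <- seq(ms / 1000, duration_s, by = ms / 1000)
  data.frame(t = t, ibi_ms = ms)
}

# sinusoidally modulated IBI record (for spectral tests)
tone_ibi <- function(f_hz, duration_s = 300, depth_ms = 50, base_ms = 800) {
  t <- seq(0.8, duration_s, by = 0.8)
  data.frame(t = t, ibi_ms = base_ms + depth_ms * sin(2 * pi * f_hz * t))
}

# minimal valid physio session
tiny_session <- function(duration_s = 150, temp_c = 33, eda_uS = 2,
                         n_beats = NULL) {
  ibi <- const_ibi(800, duration_s)
  if (!is.null(n_beats)) ibi <- ibi[seq_len(n_beats), , drop = FALSE]
  t4 <- seq(0, duration_s, by = 0.25)
  physio_session("T1", ibi,
                 eda = data.frame(t = t4, uS = rep(eda_uS, length(t4))),
                 temp = data.frame(t = t4, degC = rep(temp_c, length(t4))),
                 duration_s = duration_s)
}

# evaluate under a local seed without disturbing the test RNG stream
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  code
}

# small scene + config for generator tests (cached per session)
small_config <- function(seed = 11, ...) {
  ground_truth_config(n_participants = 3, trips_per_participant = 2,
                      seed = seed, ...)
}

.scene_cache <- new.env(parent = emptyenv())
small_scene <- function(seed = 11) {
  key <- paste0("s", seed)
  if (is.null(.scene_cache[[key]]))
    .scene_cache[[key]] <- generate_scene(small_config(seed),
                                          extent = c(0, 1200, 0, 1200))
  .scene_cache[[key]]
}
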