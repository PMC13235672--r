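# GPS stream cleaning and trip segmentation. A stream is a data.frame with
# columns trip_id, participant_id, time_s, lat, lon; one raw recording may
# yield zero, one or several validated walking trips.

stream_cols <- c("trip_id", "participant_id", "time_s", "lat", "lon")

check_stream <- function(stream) {
  miss <- setdiff(stream_cols, names(stream))
  if (length(miss))
    stop("stream is missing columns: ", paste(miss, collapse = ", "))
  stream
}

#' Clean a GPS point stream
#'
#' Orders fixes chronologically within trip, drops duplicate timestamps,
#' and excludes any fix lying strictly more than `gap_m` (default 500 m,
#' the signal-error / modal-shift rule) from the last retained fix,
#' applied sequentially in a single pass. Idempotent.
#'
#' @param stream GPS stream data.frame (may contain several trip_ids).
#' @param gap_m exclusion distance in metres; a jump must exceed it
#'   strictly to be dropped.
#' @return cleaned stream; attributes `n_dropped_gap` and
#'   `n_dropped_dup` carry the audit counts.
#' @export
clean_stream <- function(stream, gap_m = 500) {
  if (nrow(stream) == 0L) {
    attr(stream, "n_dropped_gap") <- 0L
    attr(stream, "n_dropped_dup") <- 0L
    return(stream)
  }
  check_stream(stream)
  at <- attributes(stream)
  parts <- split(seq_len(nrow(stream)), stream$trip_id)
  keep_all <- logical(nrow(stream))
  n_gap <- 0L; n_dup <- 0L
  for (idx in parts) {
    idx <- idx[order(stream$time_s[idx])]
    dup <- duplicated(stream$time_s[idx])
    n_dup <- n_dup + sum(dup)
    idx <- idx[!dup]
    n <- length(idx)
    if (n == 0L) next
    lat <- stream$lat[idx]; lon <- stream$lon[idx]
    keep <- logical(n); keep[1] <- TRUE
    last <- 1L
    tol <- gap_m + 1e-6  # guard against float excess at the exact boundary
    d <- haversine_m(cbind(lat[-n], lon[-n]), cbind(lat[-1], lon[-1]))
    if (all(d <= tol)) {
      keep[] <- TRUE
    } else {
      for (k in 2L:n) {
        if (haversine_m(c(lat[last], lon[last]), c(lat[k], lon[k])) <= tol) {
          keep[k] <- TRUE; last <- k
        }
      }
    }
    n_gap <- n_gap + sum(!keep)
    keep_all[idx[keep]] <- TRUE
  }
  ord <- order(stream$trip_id[keep_all], stream$time_s[keep_all])
  out <- stream[which(keep_all)[ord], , drop = FALSE]
  rownames(out) <- NULL
  for (nm in setdiff(names(at), c("names", "row.names", "class")))
    attr(out, nm) <- at[[nm]]
  attr(out, "n_dropped_gap") <- n_gap
  attr(out, "n_dropped_dup") <- n_dup
  out
}

#' Segment a cleaned stream into validated walking trips
#'
#' A simplified stop-detection rule: gaps between consecutive fixes are
#' walking when their speed lies in `[stop_speed_mps, max_speed_mps]`;
#' maximal non-walking runs lasting at least `stop_dwell_s` (stationary
#' dwells, or non-walking modes above the speed ceiling) split the stream,
#' shorter interruptions are absorbed. Candidates are trimmed of leading
#' and trailing non-walking gaps and discarded below `min_duration_s`,
#' aligning trip validity with the 2-minute physiological QC gate.
#'
#' @param stream cleaned GPS stream (strictly increasing timestamps per
#'   trip enforced).
#' @param stop_speed_mps stationary threshold, default 0.5 m/s.
#' @param stop_dwell_s minimum dwell duration that splits, default 120 s.
#' @param min_duration_s minimum validated trip duration, default 120 s.
#' @param max_speed_mps non-walking speed ceiling, default 3 m/s.
#' @return list of `walking_trip` objects.
#' @export
segment_trips <- function(stream, stop_speed_mps = 0.5, stop_dwell_s = 120,
                          min_duration_s = 120, max_speed_mps = 3) {
  if (nrow(stream) == 0L) return(list())
  check_stream(stream)
  trips <- list()
  for (sub in split(stream, stream$trip_id)) {
    tt <- sub$time_s
    if (is.unsorted(tt, strictly = TRUE))
      stop("segment_trips: non-monotone timestamps (stream not cleaned)")
    n <- nrow(sub)
    if (n < 2L) next
    d <- haversine_m(cbind(sub$lat[-n], sub$lon[-n]),
                     cbind(sub$lat[-1], sub$lon[-1]))
    dt <- diff(tt)
    v <- d / dt
    walking <- v >= stop_speed_mps & v <= max_speed_mps
    # splits: maximal non-walking runs with total duration >= stop_dwell_s
    r <- rle(walking)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cut_after <- integer(0)
    for (k in seq_along(r$values)) {
      if (!r$values[k]) {
        dur <- tt[ends[k] + 1L] - tt[starts[k]]
        if (dur >= stop_dwell_s) cut_after <- c(cut_after, k)
      }
    }
    # candidate fix spans between long non-walking runs
    bounds <- c(0L, ends[cut_after], n - 1L)  # gap index boundaries
    seg <- 0L
    for (b in seq_len(length(bounds) - 1L)) {
      lo <- bounds[b] + 1L; hi <- bounds[b + 1L]     # gap index range
      if (lo > hi) next
      w <- which(walking[lo:hi]) + lo - 1L           # walking gaps only
      if (!length(w)) next
      fix_idx <- min(w):(max(w) + 1L)                # trim non-walking edges
      dur <- tt[max(fix_idx)] - tt[min(fix_idx)]
      if (dur < min_duration_s) next
      seg <- seg + 1L
      trips[[length(trips) + 1L]] <-
        new_walking_trip(sub[fix_idx, , drop = FALSE], seg,
                         date = attr(sub, "date") %||% attr(stream, "date"))
    }
  }
  trips
}

new_walking_trip <- function(sub, seg, date = NULL) {
  frame <- local_frame(mean(sub$lat), mean(sub$lon))
  route <- lonlat_to_local(sub$lat, sub$lon, frame)
  n <- nrow(sub)
  len <- if (n >= 2)
    sum(haversine_m(cbind(sub$lat[-n], sub$lon[-n]),
                    cbind(sub$lat[-1], sub$lon[-1]))) else 0
  structure(list(
    trip_id = if (seg > 1L) paste0(sub$trip_id[1], "-", seg) else as.character(sub$trip_id[1]),
    source_trip_id = as.character(sub$trip_id[1]),
    participant_id = as.character(sub$participant_id[1]),
    route = route,
    frame = frame,
    times = sub$time_s,
    length_m = len,
    duration_s = sub$time_s[n] - sub$time_s[1],
    date = date
  ), class = "walking_trip")
}

#' @export
print.walking_trip <- function(x, ...) {
  cat(sprintf("<walking_trip> %s (%s): %.0f m, %.0f s, %d fixes\n",
              x$trip_id, x$participant_id, x$length_m, x$duration_s,
              nrow(x$route)))
  invisible(x)
}
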