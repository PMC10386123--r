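# Reading, validation, clock synchronisation and segmentation.
#
# The label clock (task software) is authoritative: the sensor clock is
# shifted by the hand-shake tap offset, never resampled. Time convention:
# seconds from label start, intervals half-open [start, end).

new_raw_recording <- function(subject_id, session_type, fs, channels,
                              t0_offset = NA_real_, repairs = NULL) {
  structure(list(subject_id = subject_id, session_type = session_type,
                 fs = fs, channels = channels, t0_offset = t0_offset,
                 repairs = repairs),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> subject %s session %s: %d samples @ %.1f Hz (%.1f min)\n",
              x$subject_id, x$session_type, nrow(x$channels), x$fs,
              nrow(x$channels) / x$fs / 60))
  if (!is.na(x$t0_offset))
    cat(sprintf("  synchronised: t0 offset %.3f s\n", x$t0_offset))
  invisible(x)
}

signal_columns <- function() {
  c("time_s", "ppg", "gsr_uS", "accel_x", "accel_y", "accel_z", "temp_C")
}

#' Read a multichannel signals CSV into a validated recording
#'
#' Expects the columns `time_s, ppg, gsr_uS, accel_x, accel_y, accel_z,
#' temp_C` sampled at the configured rate. Non-finite runs shorter than
#' the repair limit (0.5 s by default) are repaired by linear
#' interpolation and logged in the `repairs` field; longer runs are left
#' to window-level artefact rejection. Small negative conductance values
#' are clamped to zero (the channel is physically non-negative).
#'
#' @param path CSV path.
#' @param subject_id,session_type metadata attached to the recording.
#' @param config see [cogload_config()].
#' @return A `raw_recording`.
#' @export
read_signals <- function(path, subject_id = "unknown", session_type = "HL",
                         config = cogload_config()) {
  if (!file.exists(path))
    cogload_error("cogload_format_error", paste("no such file:", path))
  df <- read.csv(path)
  missing <- setdiff(signal_columns(), names(df))
  if (length(missing))
    cogload_error("cogload_format_error",
                  paste("missing required column(s):", paste(missing, collapse = ", ")))
  df <- df[signal_columns()]
  fs <- config$fs
  if (nrow(df) > 2) {
    dt <- median(diff(df$time_s))
    if (abs(dt - 1 / fs) > 0.10 / fs)
      cogload_error("cogload_config_error",
                    sprintf("sampling interval %.5f s does not match configured %.5f s",
                            dt, 1 / fs))
  }
  repairs <- list()
  max_run <- floor(config$nan_repair_max_s * fs)
  for (col in setdiff(signal_columns(), "time_s")) {
    x <- df[[col]]
    bad <- !is.finite(x)
    if (!any(bad)) next
    runs <- rle(bad)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (r in which(runs$values)) {
      if (runs$lengths[r] <= max_run) {
        idx <- starts[r]:ends[r]
        x[idx] <- approx(which(!bad), x[!bad], xout = idx, rule = 2)$y
        repairs[[length(repairs) + 1]] <-
          list(column = col, start = starts[r], length = runs$lengths[r],
               action = "interpolated")
      } else {
        repairs[[length(repairs) + 1]] <-
          list(column = col, start = starts[r], length = runs$lengths[r],
               action = "flagged")
      }
    }
    df[[col]] <- x
  }
  neg <- df$gsr_uS < 0 & is.finite(df$gsr_uS)
  if (any(neg)) {
    df$gsr_uS[neg] <- 0
    repairs[[length(repairs) + 1]] <-
      list(column = "gsr_uS", start = which(neg)[1], length = sum(neg),
           action = "clamped_nonnegative")
  }
  new_raw_recording(subject_id, session_type, fs, df, repairs = repairs)
}

#' Write a recording back to the signals CSV format
#' @param rec a `raw_recording`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_signals <- function(rec, path) {
  write.csv(rec$channels, path, row.names = FALSE)
  invisible(path)
}

#' Read an event-label CSV into a validated event track
#'
#' Columns: `segment`, `start_s`, `end_s` and optionally `load_class`
#' (inferred from the segment name when absent: the three high-load tasks
#' map to HL, the game to LL, everything else to none). Intervals must be
#' sorted and non-overlapping.
#'
#' @param path CSV path (or a data.frame already in that shape).
#' @return data.frame with class `event_track`.
#' @export
read_events <- function(path) {
  ev <- if (is.data.frame(path)) path else read.csv(path)
  missing <- setdiff(c("segment", "start_s", "end_s"), names(ev))
  if (length(missing))
    cogload_error("cogload_format_error",
                  paste("events file missing column(s):", paste(missing, collapse = ", ")))
  if (is.null(ev$load_class)) {
    ev$load_class <- rep("none", nrow(ev))
    ev$load_class[ev$segment %in% paste0("load_task:",
                                         c("reading_span", "stroop", "nback"))] <- "HL"
    ev$load_class[ev$segment == "load_task:game"] <- "LL"
  }
  if (any(ev$start_s >= ev$end_s))
    cogload_error("cogload_format_error", "event intervals must have start < end")
  ord <- order(ev$start_s)
  ev <- ev[ord, , drop = FALSE]
  if (nrow(ev) > 1 && any(ev$start_s[-1] < ev$end_s[-nrow(ev)] - 1e-9))
    cogload_error("cogload_format_error", "event intervals overlap")
  rownames(ev) <- NULL
  class(ev) <- c("event_track", "data.frame")
  ev
}

#' Detect the hand-shake synchronisation taps
#'
#' The accelerometer magnitude is bandpassed (0.5-6 Hz, order 4) and
#' searched for the three largest peaks above
#' `max(2 m/s^2, 5 x median magnitude)` within the search window.
#' Label time zero is aligned to the last (default) or first tap.
#'
#' @param rec a `raw_recording` of at least 15 s.
#' @param config see [cogload_config()]; `sync_align` is "last" or
#'   "first", `sync_window_s` the search window.
#' @return The recording with `t0_offset` set (sensor time of label zero)
#'   and attribute-free field `tap_time`.
#' @export
detect_sync_taps <- function(rec, config = cogload_config()) {
  ch <- rec$channels
  if (nrow(ch) < 15 * rec$fs)
    cogload_error("cogload_sync_error", "recording shorter than 15 s")
  mag <- filtered_magnitude(rec, config)
  win <- seq_len(min(length(mag), floor(config$sync_window_s * rec$fs)))
  thr <- max(config$sync_tap_threshold, 5 * median(mag[win]))
  pk <- find_peaks(mag[win], min_dist = floor(0.2 * rec$fs), min_height = thr)
  if (length(pk) < 3)
    cogload_error("cogload_sync_error",
                  sprintf("found %d tap peak(s) above %.2f m/s^2; need 3",
                          length(pk), thr))
  top3 <- sort(pk[order(-mag[pk])][1:3])
  tap_idx <- if (identical(config$sync_align, "first")) top3[1] else top3[3]
  rec$t0_offset <- (tap_idx - 1) / rec$fs
  rec$tap_time <- rec$t0_offset
  rec
}

filtered_magnitude <- function(rec, config = cogload_config()) {
  ch <- rec$channels
  f <- function(x) bandpass(x, config$accel_band[1], config$accel_band[2],
                            config$filter_order, rec$fs)
  accel_magnitude(f(ch$accel_x), f(ch$accel_y), f(ch$accel_z))
}

#' Cut a synchronised recording into labelled slices
#'
#' Each event interval (label clock, half-open) is mapped through the tap
#' offset onto sample indices; samples outside every interval are
#' dropped. Intervals that extend beyond the recording are truncated with
#' a warning.
#'
#' @param rec a synchronised `raw_recording` (after [detect_sync_taps()]).
#' @param events an `event_track` from [read_events()].
#' @return List of slices; each carries `segment`, `load_class`,
#'   `start_s`, `end_s` (label clock) and `idx`, the sample index range.
#' @export
segment_recording <- function(rec, events) {
  if (is.na(rec$t0_offset))
    cogload_error("cogload_sync_error", "recording is not synchronised")
  n <- nrow(rec$channels)
  fs <- rec$fs
  out <- list()
  for (i in seq_len(nrow(events))) {
    i0 <- floor((events$start_s[i] + rec$t0_offset) * fs) + 1
    i1 <- floor((events$end_s[i] + rec$t0_offset) * fs)
    if (i0 > n) next
    if (i1 > n) {
      warning(sprintf("interval '%s' extends beyond the recording; truncated",
                      events$segment[i]))
      i1 <- n
    }
    if (i1 < i0) next
    out[[length(out) + 1]] <- list(segment = events$segment[i],
                                   load_class = events$load_class[i],
                                   start_s = events$start_s[i],
                                   end_s = events$end_s[i],
                                   idx = c(i0, i1))
  }
  out
}
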