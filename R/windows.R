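# Sliding windows over labelled slices and the three artefact gates.

#' Derive the channels a window needs, per labelled slice
#'
#' Runs the full preprocessing chain on a synchronised recording:
#' bandpassed pulse waveform and accelerometer magnitude, global beat
#' detection, and per-slice electrodermal decomposition for the slices
#' that enter classification (high/low load only, to keep the quadratic
#' program small).
#'
#' @param rec synchronised `raw_recording`.
#' @param events an `event_track`.
#' @param config see [cogload_config()].
#' @param decompose_classes slice classes for which the electrodermal
#'   decomposition is run (default HL and LL).
#' @return List with `rec`, `slices` (each augmented with derived
#'   channels), `beats`, and full-length `ppg_f`, `mag_f`.
#' @export
process_session <- function(rec, events, config = cogload_config(),
                            decompose_classes = c("HL", "LL")) {
  if (is.na(rec$t0_offset)) rec <- detect_sync_taps(rec, config)
  ch <- rec$channels
  ppg_f <- bandpass(ch$ppg, config$ppg_band[1], config$ppg_band[2],
                    config$filter_order, rec$fs)
  mag_f <- filtered_magnitude(rec, config)
  beats <- detect_beats(ppg_f, rec$fs, config)
  slices <- segment_recording(rec, events)
  slices <- lapply(slices, function(sl) {
    rng <- sl$idx[1]:sl$idx[2]
    sl$ppg_f <- ppg_f[rng]
    sl$mag_f <- mag_f[rng]
    sl$gsr <- ch$gsr_uS[rng]
    sl$temp <- ch$temp_C[rng]
    if (sl$load_class %in% decompose_classes &&
        length(rng) >= 5 * rec$fs) {
      dec <- decompose_eda(sl$gsr, rec$fs, config)
      sl$tonic <- dec$tonic
      sl$phasic <- dec$phasic
      sl$smna <- dec$smna
    }
    sl
  })
  list(rec = rec, slices = slices, beats = beats,
       ppg_f = ppg_f, mag_f = mag_f)
}

#' Cut labelled slices into overlapping windows
#'
#' Windows are 120 s with a 30 s stride (75 % overlap) and are always
#' fully contained in one labelled slice, so no window spans a task
#' boundary. A slice of length `L` seconds yields
#' `floor((L - 120) / 30) + 1` windows when `L >= 120`, else none.
#'
#' @param session output of [process_session()].
#' @param config see [cogload_config()].
#' @param classes which load classes enter windowing (default HL, LL).
#' @return List of `cogload_window` objects.
#' @export
make_windows <- function(session, config = cogload_config(),
                         classes = c("HL", "LL")) {
  fs <- session$rec$fs
  wlen <- round(config$window_s * fs)
  step <- round(config$stride_s * fs)
  out <- list()
  for (sl in session$slices) {
    if (!(sl$load_class %in% classes)) next
    nsl <- sl$idx[2] - sl$idx[1] + 1
    if (nsl < wlen) next
    nwin <- floor((nsl - wlen) / step) + 1
    for (k in seq_len(nwin)) {
      off <- (k - 1) * step
      loc <- (off + 1):(off + wlen)
      glob0 <- sl$idx[1] + off            # first sample, recording index
      w <- list(subject_id = session$rec$subject_id,
                session_type = session$rec$session_type,
                load_class = sl$load_class,
                segment = sl$segment,
                start_s = sl$start_s + off / fs,
                fs = fs,
                ppg_f = sl$ppg_f[loc],
                mag_f = sl$mag_f[loc],
                gsr = sl$gsr[loc],
                temp = sl$temp[loc],
                tonic = if (!is.null(sl$tonic)) sl$tonic[loc],
                phasic = if (!is.null(sl$phasic)) sl$phasic[loc],
                smna = if (!is.null(sl$smna)) sl$smna[loc],
                artefact_flags = character(0))
      t0 <- (glob0 - 1) / fs
      t1 <- t0 + config$window_s
      sel <- session$beats$times >= t0 & session$beats$times < t1
      w$beat_times <- session$beats$times[sel]
      # heart rate is attached to the later beat of each gated pair
      hsel <- session$beats$hr_times >= t0 & session$beats$hr_times < t1
      w$hr <- session$beats$hr[hsel]
      w$ibi <- session$beats$ibi[hsel]
      w$hr_times <- session$beats$hr_times[hsel]
      class(w) <- "cogload_window"
      out[[length(out) + 1]] <- w
    }
  }
  out
}

#' Apply the three artefact gates to a window
#'
#' * `motion`: mean bandpassed accelerometer magnitude above 0.5 m/s^2 --
#'   hand movement corrupts every channel of the device, so the whole
#'   time index is discarded;
#' * `hr_unique`: fewer than 3 distinct integer-rounded heart rates in
#'   the window (a pulse signal with no rate variability is a sensor
#'   artefact, not physiology);
#' * `hr_low`: mean window heart rate below 35 beats/min (resting heart
#'   rate ranges roughly 40-109 beats/min; far lower values indicate
#'   missed beats). Windows with no beats raise both heart-rate flags.
#'
#' @param w a `cogload_window`.
#' @param config see [cogload_config()] for the three thresholds.
#' @return The window with `artefact_flags` filled in.
#' @export
flag_artefacts <- function(w, config = cogload_config()) {
  flags <- character(0)
  if (mean(w$mag_f) > config$artefact_accel) flags <- c(flags, "motion")
  if (length(w$hr) == 0) {
    flags <- c(flags, "hr_unique", "hr_low")
  } else {
    if (length(unique(round(w$hr))) < config$artefact_min_unique_hr)
      flags <- c(flags, "hr_unique")
    if (mean(w$hr) < config$artefact_min_hr)
      flags <- c(flags, "hr_low")
  }
  w$artefact_flags <- flags
  w
}

#' @export
print.cogload_window <- function(x, ...) {
  cat(sprintf("<window> %s/%s %s @ %.0f s%s\n", x$subject_id,
              x$session_type, x$load_class, x$start_s,
              if (length(x$artefact_flags))
                paste0(" [", paste(x$artefact_flags, collapse = ","), "]")
              else ""))
  invisible(x)
}
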