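# Pulse-waveform beat detection with sequential inter-beat-interval gating.

#' Detect heartbeats in a filtered pulse waveform
#'
#' Candidate peaks are local maxima with a minimum separation of
#' `60 / hr_max` seconds (greedy by amplitude) and height above half the
#' signal's standard deviation. Candidates are then gated sequentially
#' by the 10 % rule: a candidate is accepted only if its distance to the
#' last accepted peak is within 10 % of the reference interval. The
#' reference is seeded with the median of the first five candidate
#' inter-peak distances (the rule needs a "previous distance" before the
#' first pair) and is updated to the accepted distance on every
#' acceptance; rejected peaks never update it. When the distance exceeds
#' 1.5 times the reference the train is considered interrupted (missed
#' beats, e.g. during motion): the candidate re-anchors the train and no
#' inter-beat interval is emitted for the gap, so the heart-rate series
#' contains only intervals that passed the gate.
#'
#' @param ppg_filtered bandpassed pulse signal.
#' @param fs sampling rate, Hz.
#' @param config see [cogload_config()] (`hr_max`, `ibi_tolerance`).
#' @return A `beat_series`: `peak_indices` (candidates), `accepted`
#'   (logical per candidate), `times` (accepted peak times, s),
#'   `ibi` (s, gated intervals), `hr` (beats/min, `60 / ibi`) and
#'   `hr_times` (time of the later beat of each gated pair).
#' @export
#' @examples
#' t <- seq(0, 30, by = 1 / 51.2)
#' b <- detect_beats(sin(2 * pi * t), 51.2)   # 60 beats/min surrogate
#' mean(b$hr)
detect_beats <- function(ppg_filtered, fs, config = cogload_config()) {
  min_dist <- floor(60 / config$hr_max * fs)
  height <- 0.5 * sd(ppg_filtered)
  if (!is.finite(height) || height == 0) return(empty_beat_series())
  cand <- find_peaks(ppg_filtered, min_dist = min_dist, min_height = height)
  if (length(cand) < 2) return(empty_beat_series())
  # parabolic sub-sample refinement: one-sample quantisation at 51.2 Hz
  # would alone distort heart rate by more than 1 beat/min
  tcand <- refine_peaks(ppg_filtered, cand, fs)
  gate_candidates(cand, fs, config$ibi_tolerance, times = tcand)
}

refine_peaks <- function(x, cand, fs) {
  delta <- numeric(length(cand))
  ok <- cand > 1 & cand < length(x)
  i <- cand[ok]
  denom <- x[i - 1] - 2 * x[i] + x[i + 1]
  d <- ifelse(denom < 0, 0.5 * (x[i - 1] - x[i + 1]) / denom, 0)
  delta[ok] <- pmin(0.5, pmax(-0.5, d))
  (cand - 1 + delta) / fs
}

gate_candidates <- function(cand, fs, tol, times = (cand - 1) / fs) {
  d <- diff(times)
  ref <- median(d[seq_len(min(5, length(d)))])
  accepted <- logical(length(cand))
  gated <- logical(length(cand))      # TRUE: interval to previous passed the gate
  accepted[1] <- TRUE
  last <- times[1]
  for (k in 2:length(cand)) {
    dk <- times[k] - last
    if (abs(dk - ref) <= tol * ref) {
      accepted[k] <- TRUE
      gated[k] <- TRUE
      last <- times[k]
      ref <- dk
    } else if (dk > 1.5 * ref) {
      accepted[k] <- TRUE             # re-anchor after an interrupted train
      last <- times[k]
    }
  }
  tacc <- times[accepted]
  pair <- gated[accepted]             # per accepted beat: gap to predecessor gated?
  ibi <- diff(tacc)[pair[-1]]
  hr_times <- tacc[-1][pair[-1]]
  structure(list(peak_indices = cand, accepted = accepted, times = tacc,
                 ibi = ibi, hr = 60 / ibi, hr_times = hr_times),
            class = "beat_series")
}

empty_beat_series <- function() {
  structure(list(peak_indices = integer(0), accepted = logical(0),
                 times = numeric(0), ibi = numeric(0), hr = numeric(0),
                 hr_times = numeric(0)),
            class = "beat_series")
}

#' Re-apply the 10 % acceptance rule to an accepted beat train
#'
#' Idempotence check: the gate does not alter a train it has already
#' accepted.
#' @param beats a `beat_series`.
#' @param fs sampling rate, Hz.
#' @param config see [cogload_config()].
#' @return A `beat_series`.
#' @export
reaccept_beats <- function(beats, fs, config = cogload_config()) {
  if (length(beats$times) < 2) return(beats)
  gate_candidates(round(beats$times * fs) + 1, fs, config$ibi_tolerance,
                  times = beats$times)
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d candidates, %d accepted, mean hr %.1f\n",
              length(x$peak_indices), sum(x$accepted),
              if (length(x$hr)) mean(x$hr) else NA))
  invisible(x)
}
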