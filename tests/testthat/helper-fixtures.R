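# Shared fixtures, built in code at test time.

# compact session plan: enough load signal for a few 2-minute windows
# without the full ~70-minute session
compact_plan <- function(session_type) {
  if (session_type == "HL") {
    data.frame(segment = c("baseline", "load_task:reading_span",
                           "load_task:stroop", "load_task:nback"),
               duration_s = c(60, 180, 180, 180))
  } else {
    data.frame(segment = c("baseline", "load_task:game"),
               duration_s = c(60, 450))
  }
}

compact_spec <- function(subject_id, session_type, seed, ...) {
  session_spec(subject_id, session_type, segment_plan = compact_plan(session_type),
               seed = seed, ...)
}

# deterministic synthetic feature table with two informative columns
toy_feature_table <- function(n_subj = 8, nw = 20, sep = 2, p_noise = 8,
                              seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_subj), function(s) {
    y <- rep(c("HL", "LL"), each = nw / 2)
    X <- matrix(rnorm(nw * (p_noise + 2)), nw, p_noise + 2)
    X[, 1] <- X[, 1] + sep * (y == "HL")
    X[, 2] <- X[, 2] - sep * (y == "HL")
    colnames(X) <- c("inf1", "inf2", paste0("noise", seq_len(p_noise)))
    cbind(data.frame(subject_id = sprintf("s%02d", s),
                     session_type = rep(c("HL", "LL"), each = nw / 2),
                     load_class = y, segment = "load", start_s = seq_len(nw)),
          as.data.frame(X))
  })
  ft <- do.call(rbind, rows)
  class(ft) <- c("feature_table", "data.frame")
  ft
}

# a ready-made clean window carrying consistent derived channels
synthetic_window <- function(hr = 60, fs = 51.2, seed = 5) {
  set.seed(seed)
  n <- round(120 * fs)
  t <- (seq_len(n) - 1) / fs
  ppg <- sin(2 * pi * hr / 60 * t)
  w <- list(subject_id = "sx", session_type = "HL", load_class = "HL",
            segment = "load_task:stroop", start_s = 0, fs = fs,
            ppg_f = ppg, mag_f = rep(0.1, n),
            gsr = 2 + 0.001 * t + 0.05 * sin(2 * pi * t / 30),
            temp = rep(33, n),
            tonic = 2 + 0.001 * t, phasic = rep(0, n), smna = rep(0, n),
            artefact_flags = character(0))
  b <- detect_beats(ppg, fs)
  w$beat_times <- b$times
  w$hr <- b$hr
  w$ibi <- b$ibi
  w$hr_times <- b$hr_times
  class(w) <- "cogload_window"
  w
}

expect_stat_close <- function(x, y, tol) expect_true(abs(x - y) <= tol)

# one-slice session: 30 s baseline plus a load slice of the given length
make_slice_session <- function(dur_s, load_class = "HL", seed = 21,
                               decompose = TRUE) {
  plan <- data.frame(segment = c("baseline",
                                 if (load_class == "HL") "load_task:nback"
                                 else "load_task:game"),
                     duration_s = c(30, dur_s))
  out <- generate_recording(session_spec("s01",
                                         if (load_class == "HL") "HL" else "LL",
                                         segment_plan = plan,
                                         motion_burst_rate = 0, seed = seed))
  rec <- detect_sync_taps(out$recording)
  ev <- read_events(data.frame(out$truth$segment_intervals))
  process_session(rec, ev,
                  decompose_classes = if (decompose) c("HL", "LL") else character(0))
}
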