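# Synthetic subject-session generator.
#
# Emulates what the downstream pipeline consumes from a wrist-worn
# multichannel recorder: a quasi-periodic pulse waveform whose rate steps
# up during load tasks, skin conductance built as slow tonic drift plus
# sparse skin-conductance responses (a nonnegative driver convolved with
# a bi-exponential kernel), an accelerometer with three hand-shake taps
# for clock synchronisation plus Poisson motion bursts, and a slowly
# drifting temperature channel. All latent event times are returned as
# ground truth so recovery tests have an oracle.

#' Session specification for the synthetic generator
#'
#' @param subject_id identifier (coerced to character).
#' @param session_type "HL" (high cognitive load) or "LL" (low).
#' @param duration_scale multiplies every segment duration of the default
#'   session plan; 1 gives a realistic ~70 min session, 0.1 a desk-scale
#'   one (note that load segments then fall under one 120 s window).
#' @param segment_plan optional data.frame with columns `segment` and
#'   `duration_s` overriding the default plan. Load segments are named
#'   `load_task:<name>`.
#' @param hr_base resting heart rate, beats/min.
#' @param hr_load_delta added heart rate during load segments, beats/min.
#' @param hr_jitter slow heart-rate wander, beats/min (sd).
#' @param scr_rate_base,scr_rate_load skin-conductance-response onset
#'   rates, events/min, outside and inside load segments.
#' @param tonic_drift tonic skin-conductance drift, microsiemens/min.
#' @param motion_burst_rate motion bursts per hour (each burst also
#'   corrupts the pulse and conductance channels, so artefact rejection
#'   is observably beneficial).
#' @param noise_sd named list of channel noise standard deviations
#'   (`ppg`, `gsr`, `accel`, `temp`).
#' @param seed integer; fully determines all generated output.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(subject_id = "s01",
                         session_type = c("HL", "LL"),
                         duration_scale = 1,
                         segment_plan = NULL,
                         hr_base = 70,
                         hr_load_delta = 15,
                         hr_jitter = 2,
                         scr_rate_base = 2,
                         scr_rate_load = 8,
                         tonic_drift = 0.02,
                         motion_burst_rate = 6,
                         noise_sd = list(ppg = 0.03, gsr = 0.005,
                                         accel = 0.05, temp = 0.01),
                         seed = 1L) {
  session_type <- match.arg(session_type)
  if (is.null(segment_plan))
    segment_plan <- default_segment_plan(session_type, duration_scale)
  stopifnot(is.data.frame(segment_plan),
            all(c("segment", "duration_s") %in% names(segment_plan)))
  if (any(segment_plan$duration_s <= 0))
    cogload_error("cogload_spec_error", "all segment durations must be > 0")
  if (scr_rate_base < 0 || scr_rate_load < 0 || motion_burst_rate < 0)
    cogload_error("cogload_spec_error", "rates must be non-negative")
  hr_top <- hr_base + hr_load_delta
  if (hr_base < 35 || hr_top < 35 || hr_base > 180 || hr_top > 180)
    cogload_error("cogload_spec_error",
                  "heart rate (base and base + load delta) must lie in [35, 180]")
  structure(list(subject_id = as.character(subject_id),
                 session_type = session_type,
                 segment_plan = segment_plan,
                 hr_base = hr_base, hr_load_delta = hr_load_delta,
                 hr_jitter = hr_jitter,
                 scr_rate_base = scr_rate_base, scr_rate_load = scr_rate_load,
                 tonic_drift = tonic_drift,
                 motion_burst_rate = motion_burst_rate,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "session_spec")
}

#' Default session plan
#'
#' Baseline video, voice prompts, eyes-closed rest, questionnaires, the
#' load block (three high-load tasks with interleaved workload
#' questionnaires, or one casual game), a second affect questionnaire,
#' an eating break and a closing questionnaire.
#'
#' @param session_type "HL" or "LL".
#' @param duration_scale multiplier on all durations.
#' @return data.frame with columns `segment`, `duration_s`.
#' @export
default_segment_plan <- function(session_type = c("HL", "LL"),
                                 duration_scale = 1) {
  session_type <- match.arg(session_type)
  if (session_type == "HL") {
    seg <- c("baseline", "voice", "eyes_closed", "questionnaire",
             "load_task:reading_span", "questionnaire",
             "load_task:stroop", "questionnaire",
             "load_task:nback", "questionnaire",
             "voice", "eating", "eyes_closed", "questionnaire")
    dur <- c(600, 300, 60, 120, 510, 60, 390, 60, 600, 60, 120, 1200, 60, 120)
  } else {
    seg <- c("baseline", "voice", "eyes_closed", "questionnaire",
             "load_task:game", "questionnaire",
             "voice", "eating", "eyes_closed", "questionnaire")
    dur <- c(600, 300, 60, 120, 1500, 60, 120, 1200, 60, 120)
  }
  data.frame(segment = seg, duration_s = dur * duration_scale)
}

segment_intervals <- function(plan) {
  ends <- cumsum(plan$duration_s)
  starts <- c(0, head(ends, -1))
  load_class <- rep("none", nrow(plan))
  load_class[plan$segment %in% paste0("load_task:",
                                      c("reading_span", "stroop", "nback"))] <- "HL"
  load_class[plan$segment == "load_task:game"] <- "LL"
  data.frame(segment = plan$segment, start_s = starts, end_s = ends,
             load_class = load_class)
}

#' Generate one synthetic subject-session recording
#'
#' @param spec a [session_spec()].
#' @return A list with elements `recording` (a `raw_recording`, see
#'   [read_signals()]) and `truth`, the latent ground truth: beat times,
#'   skin-conductance-response onset times, motion-artefact intervals,
#'   tap times and segment intervals (all in seconds on the sensor
#'   clock; the label clock starts at `truth$tap_times[3]`).
#' @export
#' @examples
#' spec <- session_spec(duration_scale = 0.05, seed = 7)
#' out <- generate_recording(spec)
#' str(out$truth$tap_times)
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  cfg <- cogload_config()
  fs <- cfg$fs
  set.seed(spec$seed)
  segs <- segment_intervals(spec$segment_plan)
  sync_lead <- 8                        # s of sensor data before label zero
  total <- sync_lead + max(segs$end_s) + 2   # small tail pad so the last
                                             # interval survives sync shift
  n <- floor(total * fs)
  t <- (seq_len(n) - 1) / fs            # sensor clock
  tlab <- t - sync_lead                 # label clock (taps precede zero)

  # only the high-load tasks elevate heart rate and response rate; the
  # casual game of a low-load session stays at baseline arousal
  in_load <- rep(FALSE, n)
  for (i in which(segs$load_class == "HL")) {
    in_load <- in_load | (tlab >= segs$start_s[i] & tlab < segs$end_s[i])
  }

  ## --- pulse waveform -----------------------------------------------------
  hr_t <- spec$hr_base + spec$hr_load_delta * smooth_indicator(in_load, fs)
  if (spec$hr_jitter > 0)
    hr_t <- hr_t + slow_wander(n, fs, sd = spec$hr_jitter, period = 60)
  beat_times <- c()
  tb <- 1 / fs
  while (tb < total) {
    beat_times <- c(beat_times, tb)
    hr_here <- hr_t[min(n, max(1, floor(tb * fs) + 1))]
    tb <- tb + 60 / hr_here
  }
  ppg <- numeric(n)
  for (bt in beat_times) {
    ibi <- 60 / hr_t[min(n, max(1, floor(bt * fs) + 1))]
    ppg <- add_gaussian(ppg, fs, center = bt, amp = 1.0, sd = 0.055)
    ppg <- add_gaussian(ppg, fs, center = bt + 0.35 * ibi, amp = 0.35, sd = 0.09)
  }
  ppg <- ppg + rnorm(n, sd = spec$noise_sd$ppg)

  ## --- skin conductance ---------------------------------------------------
  tonic <- 2 + spec$tonic_drift * t / 60 +
    (spec$tonic_drift != 0) * 0.05 * sin(2 * pi * t / max(total, 300))
  rate_t <- ifelse(in_load, spec$scr_rate_load, spec$scr_rate_base) / 60
  scr_onsets <- poisson_events(rate_t, fs)
  gsr <- tonic
  if (length(scr_onsets)) {
    amps <- rlnorm(length(scr_onsets), meanlog = log(0.3), sdlog = 0.4)
    kern <- scr_kernel(fs, cfg$eda_tau_r, cfg$eda_tau_d)
    driver <- numeric(n)
    idx <- pmin(n, floor(scr_onsets * fs) + 1)
    for (j in seq_along(idx)) driver[idx[j]] <- driver[idx[j]] + amps[j]
    phasic <- conv_causal(driver, kern)
    gsr <- gsr + phasic
  }
  if (spec$noise_sd$gsr > 0) gsr <- gsr + rnorm(n, sd = spec$noise_sd$gsr)

  ## --- accelerometer ------------------------------------------------------
  ax <- rnorm(n, sd = spec$noise_sd$accel)
  ay <- rnorm(n, sd = spec$noise_sd$accel)
  az <- 9.81 + rnorm(n, sd = spec$noise_sd$accel)   # gravity on z
  # the task software starts at the last hand-shake tap
  tap_times <- sync_lead - c(1.0, 0.5, 0)
  for (tp in tap_times) {
    ax <- add_gaussian(ax, fs, tp, amp = 18, sd = 0.03)
    ay <- add_gaussian(ay, fs, tp, amp = 12, sd = 0.03)
  }
  n_bursts <- rpois(1, spec$motion_burst_rate * (total - sync_lead) / 3600)
  if (total - 10 <= sync_lead + 5) n_bursts <- 0
  artefact_intervals <- NULL
  if (n_bursts > 0) {
    starts <- sort(runif(n_bursts, sync_lead + 5, total - 10))
    # movement episodes long and strong enough that a 2-minute window
    # they cover substantially exceeds the 0.5 m/s^2 mean-magnitude gate
    durs <- runif(n_bursts, 10, 20)
    artefact_intervals <- cbind(start_s = starts, end_s = pmin(starts + durs, total))
    for (b in seq_len(n_bursts)) {
      i0 <- floor(starts[b] * fs) + 1
      i1 <- min(n, floor((starts[b] + durs[b]) * fs))
      m <- i1 - i0 + 1
      if (m <= 0) next
      burst <- sin(2 * pi * 3 * seq_len(m) / fs) * 6
      ax[i0:i1] <- ax[i0:i1] + burst + rnorm(m, sd = 2.5)
      ay[i0:i1] <- ay[i0:i1] + rnorm(m, sd = 2.5)
      # motion corrupts the optical and conductance channels as well
      ppg[i0:i1] <- ppg[i0:i1] + rnorm(m, sd = 1.2)
      gsr[i0:i1] <- gsr[i0:i1] + abs(rnorm(m, sd = 0.15))
    }
  }

  ## --- temperature --------------------------------------------------------
  temp <- 33 + 0.4 * sin(2 * pi * t / max(total, 1200)) +
    rnorm(n, sd = spec$noise_sd$temp)

  gsr[gsr < 0] <- 0
  channels <- data.frame(time_s = t, ppg = ppg, gsr_uS = gsr,
                         accel_x = ax, accel_y = ay, accel_z = az,
                         temp_C = temp)
  rec <- new_raw_recording(spec$subject_id, spec$session_type, fs, channels)
  truth <- list(beat_times = beat_times,
                scr_onsets = scr_onsets,
                artefact_intervals = artefact_intervals,
                tap_times = tap_times,
                sync_lead_s = sync_lead,
                segment_intervals = segs)
  list(recording = rec, truth = truth)
}

smooth_indicator <- function(ind, fs, ramp_s = 5) {
  k <- floor(ramp_s * fs)
  if (k < 2) return(as.numeric(ind))
  kern <- rep(1 / k, k)
  y <- stats::filter(as.numeric(ind), kern, sides = 2)
  y[is.na(y)] <- as.numeric(ind)[is.na(y)]
  as.numeric(y)
}

slow_wander <- function(n, fs, sd, period = 60) {
  m <- ceiling(n / (period * fs)) + 3
  knots <- rnorm(m, sd = sd)
  approx(seq(0, n - 1, length.out = m), knots, xout = seq_len(n) - 1)$y
}

add_gaussian <- function(x, fs, center, amp, sd) {
  n <- length(x)
  half <- ceiling(4 * sd * fs)
  ic <- floor(center * fs) + 1
  lo <- max(1, ic - half); hi <- min(n, ic + half)
  if (lo > hi || ic > n + half) return(x)
  tt <- ((lo:hi) - 1) / fs
  x[lo:hi] <- x[lo:hi] + amp * exp(-0.5 * ((tt - center) / sd)^2)
  x
}

poisson_events <- function(rate_t, fs) {
  # thinning against the maximum rate
  rmax <- max(rate_t)
  if (rmax <= 0) return(numeric(0))
  n <- length(rate_t)
  total <- n / fs
  m <- rpois(1, rmax * total)
  if (m == 0) return(numeric(0))
  cand <- sort(runif(m, 0, total))
  keep <- runif(m) < rate_t[pmin(n, floor(cand * fs) + 1)] / rmax
  cand[keep]
}

conv_causal <- function(x, kern) {
  n <- length(x)
  y <- convolve(x, rev(kern), type = "open")
  y[seq_len(n)]
}

#' Generate synthetic questionnaire responses for one subject-session
#'
#' Produces 20-item affect-schedule responses (1-5 Likert) at three
#' timepoints (before load, after load, after eating) and six workload
#' subscale ratings (0-100) per load task. In a high-load session the ten
#' negative-affect items are shifted upward after load by `affect_effect`
#' (latent scale units) and the workload subscales by `workload_effect`.
#'
#' @param spec a [session_spec()].
#' @param affect_effect latent upward shift of negative-affect items after
#'   high-load tasks.
#' @param workload_effect added workload rating for high-load tasks.
#' @param seed integer seed (independent of the signal seed).
#' @return list with data.frames `panas` (subject_id, session_type,
#'   timepoint, item_1..item_20) and `nasatlx` (subject_id, session_type,
#'   task and the six subscales).
#' @export
generate_questionnaires <- function(spec, affect_effect = 1.0,
                                    workload_effect = 20, seed = 1L) {
  stopifnot(inherits(spec, "session_spec"),
            is.finite(affect_effect), is.finite(workload_effect))
  set.seed(seed)
  timepoints <- c("before_load", "after_load", "after_eating")
  pos <- panas_positive_items()
  panas <- do.call(rbind, lapply(timepoints, function(tp) {
    shift <- if (spec$session_type == "HL" && tp == "after_load") affect_effect else 0
    items <- vapply(1:20, function(i) {
      base <- if (i %in% pos) 2.8 else 1.4
      mu <- base + if (!(i %in% pos)) shift else -0.3 * (shift > 0)
      pmin(5, pmax(1, round(rnorm(1, mu, 0.8))))
    }, numeric(1))
    out <- data.frame(subject_id = spec$subject_id,
                      session_type = spec$session_type, timepoint = tp)
    out[paste0("item_", 1:20)] <- as.list(items)
    out
  }))
  tasks <- if (spec$session_type == "HL")
    c("reading_span", "stroop", "nback") else "game"
  subscales <- c("mental", "physical", "temporal", "performance",
                 "effort", "frustration")
  nasa <- do.call(rbind, lapply(tasks, function(tk) {
    shift <- if (spec$session_type == "HL") workload_effect else 0
    vals <- pmin(100, pmax(0, round(rnorm(6, 40 + shift, 15))))
    out <- data.frame(subject_id = spec$subject_id,
                      session_type = spec$session_type, task = tk)
    out[subscales] <- as.list(vals)
    out
  }))
  rownames(panas) <- rownames(nasa) <- NULL
  list(panas = panas, nasatlx = nasa)
}

#' Positive-affect item positions of the 20-item affect schedule
#' @return Integer item indices (the remaining ten are negative-affect).
#' @export
panas_positive_items <- function() c(1, 3, 5, 9, 10, 12, 14, 16, 17, 19)

#' Offered snack table for the synthetic eating break
#'
#' Amounts offered per item (grams; millilitres for drinks) and a static
#' energy/sugar density table (per 100 g or 100 mL). The densities are a
#' synthetic stand-in compiled from typical packaged-food label values,
#' shipped so no network lookup is ever needed.
#' @return data.frame with columns item, offered_g, kcal_per_100, sugar_per_100.
#' @export
food_items <- function() {
  data.frame(
    item = c("chocolate", "chips", "pretzels", "nuts", "grapes",
             "carrot", "cucumber", "orange_juice", "water"),
    offered_g = c(54, 60, 80, 60, 85, 85, 85, 500, 500),
    kcal_per_100 = c(450, 530, 380, 600, 70, 35, 15, 45, 0),
    sugar_per_100 = c(60, 0.6, 2, 4, 16, 5, 2, 9, 0))
}

#' Generate a synthetic before/after food-weight table
#'
#' Per subject and session, grams consumed per item are drawn from a
#' truncated normal within the offered amount; high-load session means
#' are multiplied by `item_effects`.
#'
#' @param n_subjects number of subjects.
#' @param item_effects named numeric multipliers (> 0) on the high-load
#'   mean, e.g. `c(chips = 1.3, grapes = 1.5)`; unnamed items default 1.
#' @param seed integer seed.
#' @return data.frame: subject_id, session_type, item, weight_before_g,
#'   weight_after_g, consumed_g.
#' @export
generate_food_table <- function(n_subjects = 12, item_effects = numeric(0),
                                seed = 1L) {
  if (length(item_effects) && any(item_effects <= 0))
    cogload_error("cogload_spec_error", "item_effects must be > 0")
  set.seed(seed)
  items <- food_items()
  base_frac <- c(chocolate = 0.45, chips = 0.5, pretzels = 0.25, nuts = 0.3,
                 grapes = 0.4, carrot = 0.15, cucumber = 0.1,
                 orange_juice = 0.35, water = 0.5)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("s%02d", s)
    subj_appetite <- exp(rnorm(1, 0, 0.25))
    for (sess in c("HL", "LL")) {
      for (k in seq_len(nrow(items))) {
        it <- items$item[k]
        eff <- if (sess == "HL" && it %in% names(item_effects))
          item_effects[[it]] else 1
        mu <- base_frac[[it]] * items$offered_g[k] * eff * subj_appetite
        g <- rnorm(1, mu, 0.35 * mu)
        g <- min(max(g, 0), items$offered_g[k])
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sid, session_type = sess, item = it,
          weight_before_g = items$offered_g[k],
          weight_after_g = items$offered_g[k] - g,
          consumed_g = g)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a synthetic session to disk in the ingest format
#'
#' Emits `signals.csv`, `events.csv`, `truth.json` and, when provided,
#' `panas.csv` / `nasatlx.csv` / `food.csv` under `dir`.
#'
#' @param dir output directory (created if missing).
#' @param session output of [generate_recording()].
#' @param questionnaires optional output of [generate_questionnaires()].
#' @param food optional rows of [generate_food_table()].
#' @return `dir`, invisibly.
#' @export
write_session <- function(dir, session, questionnaires = NULL, food = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- session$recording
  write.csv(rec$channels, file.path(dir, "signals.csv"), row.names = FALSE)
  ev <- session$truth$segment_intervals
  write.csv(data.frame(segment = ev$segment, start_s = ev$start_s,
                       end_s = ev$end_s, load_class = ev$load_class),
            file.path(dir, "events.csv"), row.names = FALSE)
  tr <- session$truth
  tr$segment_intervals <- NULL
  tr$artefact_intervals <- if (is.null(tr$artefact_intervals)) list() else
    as.data.frame(tr$artefact_intervals)
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(questionnaires)) {
    write.csv(questionnaires$panas, file.path(dir, "panas.csv"), row.names = FALSE)
    write.csv(questionnaires$nasatlx, file.path(dir, "nasatlx.csv"), row.names = FALSE)
  }
  if (!is.null(food))
    write.csv(food, file.path(dir, "food.csv"), row.names = FALSE)
  invisible(dir)
}
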