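# The 125-feature catalogue.
#
# The catalogue reconstructs the documented group sizes exactly:
#   ppg_time 46, ppg_freq 4, hr 11, temp 2, gsr_time 43, gsr_decomp 19.
# The group cardinalities are asserted at load time so silent drift is
# impossible. Code names are stable column identifiers; human-readable
# labels (including the eight headline features such as "Sudomotor nerve
# activity count" and "Mean raw amplitude") live in feature_catalogue().

stat_skewness <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s < 1e-12) return(0)
  mean((x - mean(x))^3) / s^3
}

stat_kurtosis <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s < 1e-12) return(0)
  mean((x - mean(x))^4) / s^4 - 3
}

zero_crossing_rate <- function(x) {
  if (length(x) < 2) return(0)
  xc <- x - mean(x)
  mean(abs(diff(sign(xc))) > 0)
}

sd0 <- function(x) if (length(x) < 2) 0 else sd(x)

basic_stats13 <- function(x) {
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  c(mean = mean(x), sd = sd0(x), min = min(x), max = max(x),
    range = max(x) - min(x), median = median(x), iqr = q[2] - q[1],
    p25 = q[1], p75 = q[2], skew = stat_skewness(x),
    kurt = stat_kurtosis(x), rms = sqrt(mean(x^2)),
    zcr = zero_crossing_rate(x))
}

deriv_stats8 <- function(x) {
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  c(mean = mean(x), sd = sd0(x), min = min(x), max = max(x),
    median = median(x), iqr = q[2] - q[1],
    mean_abs = mean(abs(x)), max_abs = max(abs(x)))
}

prefix <- function(v, p) setNames(v, paste0(p, "_", names(v)))

ppg_time_features <- function(x, fs, config) {
  d1 <- diff(x); d2 <- diff(d1)
  out <- c(prefix(basic_stats13(x), "ppgt_sig"),
           prefix(basic_stats13(d1), "ppgt_d1"),
           prefix(basic_stats13(d2), "ppgt_d2"))
  pk <- find_peaks(x, min_dist = floor(60 / config$hr_max * fs),
                   min_height = 0.5 * sd0(x))
  amp <- x[pk]
  p2p <- diff(pk) / fs
  out <- c(out,
           ppgt_peak_count = length(pk),
           ppgt_peak_amp_mean = if (length(amp)) mean(amp) else 0,
           ppgt_peak_amp_sd = sd0(amp),
           ppgt_p2p_mean = if (length(p2p)) mean(p2p) else 0,
           ppgt_p2p_sd = sd0(p2p),
           ppgt_mean_abs = mean(abs(x)),
           ppgt_mean_abs_diff = mean(abs(d1)))
  out
}

# spectral powers of the beat-interval tachogram (classic LF/HF bands)
ppg_freq_features <- function(hr_times, ibi) {
  if (length(ibi) < 4) {
    return(c(ppgf_lf_power = 0, ppgf_hf_power = 0,
             ppgf_total_power = 0, ppgf_lf_hf_ratio = 0))
  }
  fs_i <- 4
  tt <- seq(min(hr_times), max(hr_times), by = 1 / fs_i)
  tach <- approx(hr_times, ibi * 1000, xout = tt, rule = 2)$y
  ps <- welch_psd(tach - mean(tach), fs_i, nperseg = min(length(tach), 256))
  band <- function(lo, hi) {
    sel <- ps$freq >= lo & ps$freq < hi
    if (!any(sel)) return(0)
    sum(ps$power[sel]) * (ps$freq[2] - ps$freq[1])
  }
  lf <- band(0.04, 0.15); hf <- band(0.15, 0.4); tot <- band(0.003, 0.4)
  c(ppgf_lf_power = lf, ppgf_hf_power = hf, ppgf_total_power = tot,
    ppgf_lf_hf_ratio = if (hf > 1e-12) lf / hf else 0)
}

hr_features <- function(hr, ibi, n_beats) {
  if (!length(hr)) hr <- 0
  dibi <- diff(ibi) * 1000   # ms
  q <- quantile(hr, c(0.25, 0.75), names = FALSE, type = 7)
  c(hr_mean = mean(hr), hr_sd = sd0(hr), hr_min = min(hr), hr_max = max(hr),
    hr_range = max(hr) - min(hr),
    hr_rmssd = if (length(dibi)) sqrt(mean(dibi^2)) else 0,
    hr_sdsd = sd0(dibi),
    hr_pnn50 = if (length(dibi)) 100 * mean(abs(dibi) > 50) else 0,
    hr_median = median(hr), hr_iqr = q[2] - q[1], hr_count = n_beats)
}

gsr_time_features <- function(x, fs, config) {
  d1 <- diff(x) * fs; d2 <- diff(d1)
  q <- quantile(x, c(0.1, 0.25, 0.75, 0.9), names = FALSE, type = 7)
  raw <- c(gsrt_raw_mean = mean(x), gsrt_raw_sd = sd0(x),
           gsrt_raw_min = min(x), gsrt_raw_max = max(x),
           gsrt_raw_range = max(x) - min(x), gsrt_raw_median = median(x),
           gsrt_raw_iqr = q[3] - q[2], gsrt_raw_p10 = q[1],
           gsrt_raw_p25 = q[2], gsrt_raw_p75 = q[3], gsrt_raw_p90 = q[4],
           gsrt_raw_skew = stat_skewness(x), gsrt_raw_kurt = stat_kurtosis(x))
  dv <- c(prefix(deriv_stats8(d1), "gsrt_d1"),
          prefix(deriv_stats8(d2), "gsrt_d2"))
  ev <- scr_events(x, fs, config)
  tt <- (seq_along(x) - 1) / fs
  sl <- if (sd0(x) > 0) coef(lm(x ~ tt))[2] else 0
  extra <- c(gsrt_scr_count = ev$count,
             gsrt_scr_amp_mean = ev$amp_mean, gsrt_scr_amp_sd = ev$amp_sd,
             gsrt_scr_amp_max = ev$amp_max, gsrt_scr_amp_sum = ev$amp_sum,
             gsrt_scr_rise_mean = ev$rise_mean,
             gsrt_scr_recovery_mean = ev$recovery_mean,
             gsrt_auc = mean(x) * length(x) / fs,
             gsrt_slope = unname(sl),
             gsrt_rms = sqrt(mean(x^2)),
             gsrt_cv = if (abs(mean(x)) > 1e-12) sd0(x) / mean(x) else 0,
             gsrt_zcr_d1 = zero_crossing_rate(d1),
             gsrt_zcr_d2 = zero_crossing_rate(d2),
             gsrt_log_energy = log1p(sum(x^2)))
  c(raw, dv, extra)
}

# simple trough-to-peak response detector on the raw conductance
scr_events <- function(x, fs, config) {
  d1 <- diff(x) * fs
  k <- max(1, floor(0.5 * fs))
  d1s <- as.numeric(stats::filter(d1, rep(1 / k, k), sides = 2))
  d1s[is.na(d1s)] <- 0
  thr <- 0.01   # microsiemens per second
  up <- which(d1s[-1] > thr & d1s[-length(d1s)] <= thr) + 1
  amps <- rises <- recov <- numeric(0)
  for (o in up) {
    rest <- d1s[o:length(d1s)]
    pk_rel <- which(rest < 0)[1]
    if (is.na(pk_rel)) pk_rel <- length(rest)
    pk <- o + pk_rel - 1
    a <- x[pk] - x[o]
    if (a <= 0) next
    amps <- c(amps, a)
    rises <- c(rises, (pk - o) / fs)
    half <- x[o] + a / 2
    post <- x[pk:length(x)]
    rec_rel <- which(post <= half)[1]
    if (!is.na(rec_rel)) recov <- c(recov, (rec_rel - 1) / fs)
  }
  list(count = length(amps),
       amp_mean = if (length(amps)) mean(amps) else 0,
       amp_sd = sd0(amps),
       amp_max = if (length(amps)) max(amps) else 0,
       amp_sum = sum(amps),
       rise_mean = if (length(rises)) mean(rises) else 0,
       recovery_mean = if (length(recov)) mean(recov) else 0)
}

gsr_decomp_features <- function(tonic, phasic, smna, fs, config) {
  comp4 <- function(x, p) {
    c(setNames(c(mean(x), sd0(x), min(x), max(x)),
               paste0(p, c("_mean", "_sd", "_min", "_max"))))
  }
  maxpow <- function(x) {
    if (sd0(x) < 1e-14) return(0)
    max(welch_psd(x - mean(x), fs, nperseg = min(length(x), 1024))$power)
  }
  tt <- (seq_along(tonic) - 1) / fs
  slope <- if (sd0(tonic) > 0) coef(lm(tonic ~ tt))[2] else 0
  c(comp4(tonic, "gsrd_tonic"), comp4(phasic, "gsrd_phasic"),
    comp4(smna, "gsrd_smna"),
    gsrd_tonic_power_max = maxpow(tonic),
    gsrd_phasic_power_max = maxpow(phasic),
    gsrd_smna_power_max = maxpow(smna),
    gsrd_smna_count = smna_count(smna, fs, config),
    gsrd_smna_auc = sum(smna),
    gsrd_phasic_auc = mean(phasic) * length(phasic) / fs,
    gsrd_tonic_slope = unname(slope))
}

#' Count sudomotor driver excursions
#'
#' Number of driver excursions above the threshold (0.01 a.u. by
#' default) whose onsets are separated by at least one second.
#' @param smna nonnegative driver signal.
#' @param fs sampling rate, Hz.
#' @param config see [cogload_config()].
#' @return Integer count.
#' @export
smna_count <- function(smna, fs, config = cogload_config()) {
  above <- which(smna > config$smna_threshold)
  if (!length(above)) return(0L)
  sum(c(TRUE, diff(above) >= config$smna_min_gap * fs))
}

#' Extract the 125-feature vector from an artefact-free window
#'
#' @param w a `cogload_window` with empty `artefact_flags` and attached
#'   decomposition channels.
#' @param config see [cogload_config()].
#' @return Named numeric vector of length 125, ordered as in
#'   [feature_catalogue()].
#' @export
extract_features <- function(w, config = cogload_config()) {
  stopifnot(inherits(w, "cogload_window"))
  if (is.null(w$tonic))
    cogload_error("cogload_parameter_error",
                  "window lacks decomposition channels; run process_session first")
  v <- c(ppg_time_features(w$ppg_f, w$fs, config),
         ppg_freq_features(w$hr_times, w$ibi),
         hr_features(w$hr, w$ibi, length(w$beat_times)),
         temp_mean = mean(w$temp), temp_sd = sd0(w$temp),
         gsr_time_features(w$gsr, w$fs, config),
         gsr_decomp_features(w$tonic, w$phasic, w$smna, w$fs, config))
  stopifnot(length(v) == 125)
  v
}

#' The feature catalogue: names, groups and labels
#'
#' One row per feature column, in the exact column order of the feature
#' table. Group cardinalities (46 pulse time-domain, 4 pulse frequency-
#' domain, 11 heart-rate, 2 temperature, 43 conductance time-domain,
#' 19 decomposition-derived) are asserted here.
#'
#' @return data.frame with columns `name`, `group`, `label`.
#' @export
feature_catalogue <- function() {
  cfg <- cogload_config()
  w <- dummy_window()
  v <- extract_features(w, cfg)
  nm <- names(v)
  group <- rep(NA_character_, length(nm))
  group[startsWith(nm, "ppgt_")] <- "ppg_time"
  group[startsWith(nm, "ppgf_")] <- "ppg_freq"
  group[startsWith(nm, "hr_")] <- "hr"
  group[startsWith(nm, "temp_")] <- "temp"
  group[startsWith(nm, "gsrt_")] <- "gsr_time"
  group[startsWith(nm, "gsrd_")] <- "gsr_decomp"
  label <- gsub("_", " ", nm)
  special <- c(gsrd_smna_count = "Sudomotor nerve activity count",
               gsrt_raw_mean = "Mean raw amplitude",
               gsrd_tonic_power_max = "Maximum power of tonic component",
               gsrd_phasic_power_max = "Maximum power of phasic component",
               gsrd_phasic_sd = "Standard deviation phasic component",
               hr_mean = "Mean heart rate",
               hr_sd = "Standard deviation of heart rate",
               temp_sd = "Standard deviation",
               temp_mean = "Mean temperature")
  label[match(names(special), nm)] <- unname(special)
  out <- data.frame(name = nm, group = group, label = label)
  counts <- table(factor(out$group, levels = c("ppg_time", "ppg_freq", "hr",
                                               "temp", "gsr_time", "gsr_decomp")))
  stopifnot(identical(as.integer(counts), c(46L, 4L, 11L, 2L, 43L, 19L)),
            nrow(out) == 125)
  out
}

# minimal synthetic window used to derive catalogue structure
dummy_window <- function() {
  fs <- 51.2
  n <- round(120 * fs)
  t <- (seq_len(n) - 1) / fs
  w <- list(subject_id = "dummy", session_type = "HL", load_class = "HL",
            segment = "load_task:stroop", start_s = 0, fs = fs,
            ppg_f = sin(2 * pi * t), mag_f = numeric(n) + 0.1,
            gsr = 2 + 0.01 * t, temp = rep(33, n),
            tonic = 2 + 0.01 * t, phasic = numeric(n), smna = numeric(n),
            beat_times = seq(0.5, 119.5, by = 1),
            hr = 60 + sin(seq_len(118)), ibi = rep(1, 118),
            hr_times = seq(1.5, 118.5, by = 1),
            artefact_flags = character(0))
  class(w) <- "cogload_window"
  w
}

#' Build a feature table from windows
#'
#' Flags artefacts, drops flagged windows, extracts the 125 features per
#' surviving window and drops (with a message) any window producing a
#' non-finite feature.
#'
#' @param windows list of `cogload_window` (from [make_windows()]).
#' @param config see [cogload_config()].
#' @return A `feature_table`: data.frame with metadata columns
#'   (`subject_id`, `session_type`, `load_class`, `segment`, `start_s`)
#'   followed by the 125 feature columns. Attributes: `n_flagged`,
#'   `flag_reasons`.
#' @export
build_feature_table <- function(windows, config = cogload_config()) {
  windows <- lapply(windows, flag_artefacts, config = config)
  flagged <- vapply(windows, function(w) length(w$artefact_flags) > 0, logical(1))
  reasons <- unlist(lapply(windows, function(w) w$artefact_flags))
  kept <- windows[!flagged]
  rows <- list()
  for (w in kept) {
    v <- extract_features(w, config)
    if (any(!is.finite(v))) {
      message("dropping window (non-finite feature: ",
              paste(names(v)[!is.finite(v)], collapse = ", "), ")")
      next
    }
    meta <- data.frame(subject_id = w$subject_id,
                       session_type = w$session_type,
                       load_class = w$load_class, segment = w$segment,
                       start_s = w$start_s)
    rows[[length(rows) + 1]] <- cbind(meta, as.data.frame(as.list(v)))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(subject_id = character(0), session_type = character(0),
                     load_class = character(0), segment = character(0),
                     start_s = numeric(0)))
  rownames(out) <- NULL
  structure(out, class = c("feature_table", "data.frame"),
            n_flagged = sum(flagged), flag_reasons = reasons)
}

#' Names of the metadata (non-feature) columns of a feature table
#' @return Character vector.
#' @export
feature_meta_columns <- function() {
  c("subject_id", "session_type", "load_class", "segment", "start_s")
}
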