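# Synthetic generator: determinism, stated examples, Poisson and sync
# properties.

test_that("identical spec and seed give bit-identical outputs", {
  spec <- compact_spec("s01", "HL", seed = 11)
  a <- generate_recording(spec)
  b <- generate_recording(spec)
  expect_identical(a$recording$channels, b$recording$channels)
  expect_identical(a$truth, b$truth)
  qa <- generate_questionnaires(spec, seed = 3)
  qb <- generate_questionnaires(spec, seed = 3)
  expect_identical(qa, qb)
  expect_identical(generate_food_table(4, seed = 2),
                   generate_food_table(4, seed = 2))
})

test_that("no drivers, no noise, no drift give a constant conductance channel", {
  spec <- session_spec("s01", "HL",
                       segment_plan = data.frame(segment = "baseline",
                                                 duration_s = 30),
                       scr_rate_base = 0, scr_rate_load = 0,
                       tonic_drift = 0, motion_burst_rate = 0,
                       noise_sd = list(ppg = 0.03, gsr = 0, accel = 0.05,
                                       temp = 0.01),
                       seed = 1)
  out <- generate_recording(spec)
  expect_equal(diff(range(out$recording$channels$gsr_uS)), 0)
})

test_that("at 60 beats/min without jitter the waveform carries 120 +/- 1 peaks over 120 s", {
  spec <- session_spec("s01", "HL",
                       segment_plan = data.frame(segment = "baseline",
                                                 duration_s = 130),
                       hr_base = 60, hr_load_delta = 0, hr_jitter = 0,
                       motion_burst_rate = 0,
                       noise_sd = list(ppg = 0.01, gsr = 0.005, accel = 0.05,
                                       temp = 0.01),
                       seed = 2)
  out <- generate_recording(spec)
  fs <- out$recording$fs
  ppg_f <- bandpass(out$recording$channels$ppg, 0.5, 8, fs = fs)
  b <- detect_beats(ppg_f, fs)
  expect_true(abs(sum(b$times >= 10 & b$times < 130) - 120) <= 1)
  # ground truth agrees
  bt <- out$truth$beat_times
  expect_true(abs(sum(bt >= 10 & bt < 130) - 120) <= 1)
})

test_that("skin-conductance-response counts follow the segment rates (3 sigma)", {
  spec <- session_spec("s01", "HL",
                       segment_plan = data.frame(
                         segment = c("baseline", "load_task:nback"),
                         duration_s = c(300, 600)),
                       scr_rate_base = 2, scr_rate_load = 8,
                       motion_burst_rate = 0, seed = 7)
  out <- generate_recording(spec)
  lead <- out$truth$sync_lead_s
  on <- out$truth$scr_onsets - lead       # label clock
  n_load <- sum(on >= 300 & on < 900)
  lambda <- 8 / 60 * 600
  expect_true(abs(n_load - lambda) <= 3 * sqrt(lambda))
  n_base <- sum(on >= 0 & on < 300)
  lambda_b <- 2 / 60 * 300
  expect_true(abs(n_base - lambda_b) <= 3 * sqrt(lambda_b))
})

test_that("the three taps are the three largest filtered-magnitude events early on", {
  spec <- compact_spec("s01", "HL", seed = 3)
  out <- generate_recording(spec)
  rec <- out$recording
  mag <- cogload:::filtered_magnitude(rec)
  fs <- rec$fs
  first10 <- mag[seq_len(round(10 * fs))]
  pk <- cogload:::find_peaks(first10, min_dist = floor(0.2 * fs),
                             min_height = 2)
  top3 <- sort(pk[order(-first10[pk])][1:3]) / fs
  expect_equal(sort(top3), sort(out$truth$tap_times), tolerance = 0.05)
})

test_that("questionnaire scores respect the 10-50 bounds at forced extremes", {
  items_min <- as.data.frame(as.list(setNames(rep(1, 20), paste0("item_", 1:20))))
  s <- score_panas(items_min)
  expect_equal(s$positive, 10)
  expect_equal(s$negative, 10)
  items_max <- as.data.frame(as.list(setNames(rep(5, 20), paste0("item_", 1:20))))
  s <- score_panas(items_max)
  expect_equal(s$positive, 50)
  expect_equal(s$negative, 50)
})

test_that("zero affect effect leaves expected negative-affect sums level", {
  spec <- compact_spec("s07", "HL", seed = 9)
  sums <- replicate(40, {
    q <- generate_questionnaires(spec, affect_effect = 0,
                                 seed = sample.int(1e6, 1))
    s <- score_panas(q$panas)
    s$negative[s$timepoint == "after_load"] -
      s$negative[s$timepoint == "before_load"]
  })
  expect_lt(abs(mean(sums)), 2)   # sampling noise only
})

test_that("food weights are bounded by the offer and effects shift the ratio", {
  tab <- generate_food_table(40, c(chips = 1.3), seed = 4)
  offered <- setNames(food_items()$offered_g, food_items()$item)
  expect_true(all(tab$consumed_g >= 0))
  expect_true(all(tab$consumed_g <= offered[tab$item] + 1e-9))
  chips <- tab[tab$item == "chips", ]
  r <- mean(chips$consumed_g[chips$session_type == "HL"]) /
    mean(chips$consumed_g[chips$session_type == "LL"])
  expect_stat_close(r, 1.3, 0.15)
  # neutral effects: ratios near 1
  tab0 <- generate_food_table(40, seed = 5)
  g <- tab0[tab0$item == "grapes", ]
  r0 <- mean(g$consumed_g[g$session_type == "HL"]) /
    mean(g$consumed_g[g$session_type == "LL"])
  expect_stat_close(r0, 1.0, 0.15)
})

test_that("malformed specs are rejected", {
  expect_error(session_spec(segment_plan = data.frame(segment = "baseline",
                                                      duration_s = -5)),
               class = "cogload_spec_error")
  expect_error(session_spec(hr_base = 20), class = "cogload_spec_error")
  expect_error(session_spec(scr_rate_base = -1), class = "cogload_spec_error")
  expect_error(generate_food_table(3, c(chips = 0)), class = "cogload_spec_error")
})
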