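# Windowing geometry, artefact gates and the feature catalogue.

test_that("window counts follow floor((L - 120) / 30) + 1", {
  expect_length(make_windows(make_slice_session(120, decompose = FALSE)), 1)
  expect_length(make_windows(make_slice_session(210, decompose = FALSE)), 4)
  expect_length(make_windows(make_slice_session(119, decompose = FALSE)), 0)
})

test_that("windows are 6144 samples, stride 30 s, and never span slices", {
  ses <- make_slice_session(210, decompose = FALSE)
  w <- make_windows(ses)
  expect_true(all(vapply(w, function(x) length(x$ppg_f), numeric(1)) == 6144))
  starts <- vapply(w, `[[`, numeric(1), "start_s")
  expect_equal(diff(starts), rep(30, 3))
  expect_true(all(vapply(w, `[[`, character(1), "segment") == "load_task:nback"))
})

test_that("group cardinalities and headline labels are frozen in the catalogue", {
  cat <- feature_catalogue()
  counts <- table(cat$group)
  expect_equal(unname(counts[c("ppg_time", "ppg_freq", "hr", "temp",
                               "gsr_time", "gsr_decomp")]),
               c(46L, 4L, 11L, 2L, 43L, 19L), ignore_attr = TRUE)
  expect_equal(nrow(cat), 125)
  needed <- c("Sudomotor nerve activity count", "Mean raw amplitude",
              "Maximum power of tonic component",
              "Maximum power of phasic component",
              "Standard deviation phasic component", "Mean heart rate",
              "Standard deviation of heart rate", "Standard deviation")
  expect_true(all(needed %in% cat$label))
})

test_that("stated feature examples hold on constructed windows", {
  w <- synthetic_window(hr = 60)
  v <- extract_features(w)
  expect_length(v, 125)
  expect_equal(unname(v["temp_mean"]), 33)
  expect_equal(unname(v["temp_sd"]), 0)
  expect_equal(unname(v["hr_mean"]), 60, tolerance = 0.01)
  expect_lt(unname(v["hr_sd"]), 0.5)
  expect_equal(unname(v["gsrd_smna_count"]), 0)   # zero driver
  expect_equal(unname(v["gsrt_raw_mean"]), mean(w$gsr))
})

test_that("artefact gates flag exactly what they should", {
  # clean window at 70 beats/min: no flags
  w <- synthetic_window(hr = 70)
  w$hr <- w$hr + rep(c(-1, 0, 1), length.out = length(w$hr))  # 3 distinct rates
  expect_length(flag_artefacts(w)$artefact_flags, 0)
  # motion
  wm <- w; wm$mag_f <- rep(0.6, length(wm$mag_f))
  expect_true("motion" %in% flag_artefacts(wm)$artefact_flags)
  # no beats: both heart-rate flags
  wb <- w; wb$hr <- numeric(0)
  expect_setequal(flag_artefacts(wb)$artefact_flags, c("hr_unique", "hr_low"))
  # <= 2 distinct integer rates
  wu <- w; wu$hr <- rep(c(70, 71), length.out = 50)
  expect_true("hr_unique" %in% flag_artefacts(wu)$artefact_flags)
  # low mean heart rate
  wl <- w; wl$hr <- rep(c(30, 31, 32), length.out = 50)
  expect_true("hr_low" %in% flag_artefacts(wl)$artefact_flags)
})

test_that("windows overlapping planted motion bursts are flagged", {
  plan <- data.frame(segment = c("baseline", "load_task:nback"),
                     duration_s = c(30, 400))
  checked_hit <- checked_clean <- 0
  for (seed in c(31, 32, 33, 34)) {
    out <- generate_recording(session_spec("s01", "HL", segment_plan = plan,
                                           motion_burst_rate = 60, seed = seed))
    if (is.null(out$truth$artefact_intervals)) next
    rec <- detect_sync_taps(out$recording)
    ev <- read_events(data.frame(out$truth$segment_intervals))
    ses <- process_session(rec, ev, decompose_classes = character(0))
    w <- lapply(make_windows(ses), flag_artefacts)
    lead <- max(out$truth$tap_times)
    bursts <- out$truth$artefact_intervals
    for (x in w) {
      ov <- sum(pmax(0, pmin(bursts[, "end_s"] - lead, x$start_s + 120) -
                        pmax(bursts[, "start_s"] - lead, x$start_s)))
      if (ov >= 15) {       # substantial coverage: gate must fire
        expect_true("motion" %in% x$artefact_flags)
        checked_hit <- checked_hit + 1
      } else if (ov == 0) { # untouched windows stay clean
        expect_false("motion" %in% x$artefact_flags)
        checked_clean <- checked_clean + 1
      }
    }
  }
  expect_gt(checked_hit, 0)
  expect_gt(checked_clean, 0)
})

test_that("feature tables carry only finite values and the metadata columns", {
  ses <- make_slice_session(180, seed = 22)
  ft <- build_feature_table(make_windows(ses))
  expect_s3_class(ft, "feature_table")
  expect_equal(ncol(ft), 125 + length(feature_meta_columns()))
  fm <- cogload:::feature_matrix(ft)
  expect_true(all(is.finite(fm)))
})
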