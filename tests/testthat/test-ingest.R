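# Ingest, synchronisation and segmentation.

test_that("write/read round-trips a valid recording", {
  spec <- session_spec("s01", "HL",
                       segment_plan = data.frame(segment = "baseline",
                                                 duration_s = 20),
                       seed = 1)
  out <- generate_recording(spec)
  f <- tempfile(fileext = ".csv")
  write_signals(out$recording, f)
  rec <- read_signals(f, "s01", "HL")
  expect_equal(rec$channels, out$recording$channels, tolerance = 1e-12)
  expect_equal(nrow(rec$channels), nrow(out$recording$channels))
})

test_that("a well-formed 10 s file yields 512 samples and fs is validated", {
  fs <- 51.2
  n <- 512
  df <- data.frame(time_s = (seq_len(n) - 1) / fs, ppg = rnorm(n),
                   gsr_uS = abs(rnorm(n)) + 1, accel_x = rnorm(n),
                   accel_y = rnorm(n), accel_z = rnorm(n) + 9.81,
                   temp_C = rnorm(n) + 33)
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  rec <- read_signals(f)
  expect_equal(nrow(rec$channels), 512)
  # wrong rate
  df2 <- df; df2$time_s <- (seq_len(n) - 1) / 32
  write.csv(df2, f, row.names = FALSE)
  expect_error(read_signals(f), class = "cogload_config_error")
})

test_that("a missing column raises a format error naming the column", {
  df <- data.frame(time_s = 1:10 / 51.2, ppg = rnorm(10))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  expect_error(read_signals(f), regexp = "gsr_uS",
               class = "cogload_format_error")
})

test_that("short non-finite runs are repaired by interpolation and logged", {
  fs <- 51.2; n <- 1024
  df <- data.frame(time_s = (seq_len(n) - 1) / fs, ppg = sin(seq_len(n) / 10),
                   gsr_uS = rep(2, n), accel_x = 0, accel_y = 0,
                   accel_z = 9.81, temp_C = 33)
  df$ppg[500] <- NA
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  rec <- read_signals(f)
  by_hand <- (sin(499 / 10) + sin(501 / 10)) / 2
  expect_equal(rec$channels$ppg[500], by_hand, tolerance = 1e-9)
  expect_true(any(vapply(rec$repairs, function(r)
    r$column == "ppg" && r$action == "interpolated", logical(1))))
})

test_that("tap detection returns the last of the three largest peaks", {
  fs <- 51.2
  n <- round(30 * fs)
  t <- (seq_len(n) - 1) / fs
  ax <- rnorm(n, sd = 0.02)
  for (tp in c(2.0, 2.5, 3.0))
    ax <- ax + 15 * exp(-0.5 * ((t - tp) / 0.03)^2)
  # a later, lower-magnitude motion burst must not move the tap
  ax <- ax + 3 * exp(-0.5 * ((t - 20) / 0.03)^2)
  ch <- data.frame(time_s = t, ppg = rnorm(n), gsr_uS = rep(2, n),
                   accel_x = ax, accel_y = rnorm(n, sd = 0.02),
                   accel_z = 9.81 + rnorm(n, sd = 0.02), temp_C = 33)
  rec <- cogload:::new_raw_recording("s", "HL", fs, ch)
  rec <- detect_sync_taps(rec)
  expect_equal(rec$tap_time, 3.0, tolerance = 0.1)
  cfgf <- cogload_config(sync_align = "first")
  expect_equal(detect_sync_taps(rec, cfgf)$tap_time, 2.0, tolerance = 0.1)
})

test_that("a recording without taps is unsynchronisable", {
  fs <- 51.2; n <- round(20 * fs)
  ch <- data.frame(time_s = (seq_len(n) - 1) / fs, ppg = rnorm(n),
                   gsr_uS = rep(2, n), accel_x = 0, accel_y = 0,
                   accel_z = 9.81, temp_C = 33)
  rec <- cogload:::new_raw_recording("s", "HL", fs, ch)
  expect_error(detect_sync_taps(rec), class = "cogload_sync_error")
})

test_that("sync recovery on synthetic data is within 0.1 s of truth", {
  for (seed in 1:3) {
    out <- generate_recording(compact_spec("s01", "HL", seed = seed))
    rec <- detect_sync_taps(out$recording)
    expect_lt(abs(rec$tap_time - max(out$truth$tap_times)), 0.1)
  }
})

test_that("segmentation maps label intervals to the expected sample counts", {
  out <- generate_recording(session_spec(
    "s01", "HL", segment_plan = data.frame(segment = "baseline",
                                           duration_s = 150), seed = 2))
  rec <- detect_sync_taps(out$recording)
  ev <- read_events(data.frame(segment = "baseline", start_s = 0, end_s = 120))
  sl <- segment_recording(rec, ev)
  expect_length(sl, 1)
  expect_equal(sl[[1]]$idx[2] - sl[[1]]$idx[1] + 1, 6144)
  # empty track -> empty list; samples conserved under a tiling
  expect_length(segment_recording(rec, read_events(
    data.frame(segment = character(0), start_s = numeric(0),
               end_s = numeric(0)))), 0)
  ev2 <- read_events(data.frame(segment = c("a", "b", "c"),
                                start_s = c(0, 50, 100),
                                end_s = c(50, 100, 150)))
  sl2 <- segment_recording(rec, ev2)
  expect_equal(sum(vapply(sl2, function(s) s$idx[2] - s$idx[1] + 1,
                          numeric(1))),
               150 * rec$fs)
})

test_that("overlapping event intervals are rejected and long ones truncated", {
  expect_error(read_events(data.frame(segment = c("a", "b"),
                                      start_s = c(0, 50), end_s = c(60, 100))),
               class = "cogload_format_error")
  out <- generate_recording(session_spec(
    "s01", "HL", segment_plan = data.frame(segment = "baseline",
                                           duration_s = 30), seed = 2))
  rec <- detect_sync_taps(out$recording)
  expect_warning(segment_recording(rec, read_events(
    data.frame(segment = "baseline", start_s = 0, end_s = 500))),
    regexp = "truncated")
})

test_that("load classes are inferred from task names", {
  ev <- read_events(data.frame(
    segment = c("baseline", "load_task:stroop", "load_task:game"),
    start_s = c(0, 10, 20), end_s = c(10, 20, 30)))
  expect_equal(ev$load_class, c("none", "HL", "LL"))
})
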