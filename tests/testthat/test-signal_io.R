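test_that("recording constructor enforces its invariants", {
  rec <- recording(matrix(0, 2560, 2), 2560, c("ecg", "pcg"))
  expect_equal(rec$duration, 1.0)
  expect_error(recording(matrix(0, 10, 2), 0, c("ecg", "pcg")),
               "sample_rate")
  expect_error(recording(matrix(0, 10, 2), 100, "pcg"), "channel_roles")
  expect_error(recording(matrix(0, 10, 1), 100, "audio"), "roles")
})

test_that("csv records round-trip and require an explicit sampling rate", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  m <- matrix(round(rnorm(2560 * 2), 8), ncol = 2)
  rec <- recording(m, 2560, c("pcg", "pcg"), c("P1", "P2"))
  write_recording(rec, tmp, "csv")
  back <- read_recording(tmp, "csv", sample_rate_override = 2560,
                         channel_roles = c("pcg", "pcg"))
  expect_equal(back$duration, 1.0)
  expect_equal(back$samples, rec$samples, ignore_attr = TRUE)
  expect_equal(back$channel_names, c("P1", "P2"))
  expect_error(read_recording(tmp, "csv"), "pcgbeat_missing_sample_rate")
})

test_that("wav supports the 8-channel ECG+7xPCG layout and both encodings", {
  tmp <- withr::local_tempfile(fileext = ".wav")
  m <- matrix(runif(2560 * 8, -0.9, 0.9), ncol = 8)
  roles <- c("ecg", rep("pcg", 7))
  write_recording(recording(m, 2560, roles), tmp, "wav")
  back <- read_recording(tmp, "wav", channel_roles = roles)
  expect_equal(ncol(back$samples), 8L)
  expect_equal(back$sample_rate, 2560)
  expect_equal(back$channel_roles, roles)
  expect_equal(back$samples, m, tolerance = 1e-7, ignore_attr = TRUE)

  write_recording(recording(m, 2560, roles), tmp, "wav", bit_depth = "pcm16")
  pcm <- read_recording(tmp, "wav", channel_roles = roles)
  expect_equal(pcm$samples, m, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("wfdb records round-trip with channel roles", {
  dir <- withr::local_tempdir()
  base <- file.path(dir, "rec01")
  m <- cbind(sin(seq(0, 20, length.out = 5000)),
             cos(seq(0, 40, length.out = 5000)))
  rec <- recording(m, 500, c("ecg", "pcg"), c("ECG", "P3"))
  write_recording(rec, base, "wfdb")
  back <- read_recording(paste0(base, ".hea"), "wfdb")
  expect_equal(back$sample_rate, 500)
  expect_equal(back$channel_roles, c("ecg", "pcg"))
  expect_equal(back$samples, m, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("annotation tracks validate labels and ordering", {
  expect_error(annotation_track(c(1, 1), c("S1", "S2")), "increasing")
  expect_error(annotation_track(1, "Q"), "unknown label")
  expect_silent(annotation_track(numeric(), character()))
})

test_that("annotation round-trip preserves events to within one sample", {
  fs <- 2560
  tmp <- withr::local_tempfile(fileext = ".csv")
  # empty track -> header-only file
  write_annotations(annotation_track(numeric(), character()), tmp)
  expect_equal(length(readLines(tmp)), 1L)

  set.seed(11)
  times <- sort(runif(100, 0, 600))
  times <- times[c(TRUE, diff(times) > 1e-3)]
  labs <- sample(c("S1", "S2", "U", "R", "T"), length(times), replace = TRUE)
  tr <- annotation_track(times, labs, runif(length(times)))
  write_annotations(tr, tmp)
  back <- read_annotations(tmp)
  expect_equal(back$labels, tr$labels)
  expect_lt(max(abs(back$times - tr$times)), 1 / fs)

  # wfdb_ann flavour carries sample numbers
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_annotations(tr, tmp2, format = "wfdb_ann", sample_rate = fs)
  df <- read.csv(tmp2)
  expect_true(all(c("sample", "time_s", "label") %in% names(df)))
  expect_equal(df$sample, round(tr$times * fs))
})

test_that("config files round-trip and reject unknown keys", {
  tmp <- withr::local_tempfile(fileext = ".toml")
  writeLines(c("# detector settings", 'wavelet = "db6"',
               "pcg_band_hz = 2, 90", "ecg_invert = true"), tmp)
  cfg <- read_config(tmp)
  expect_equal(cfg$wavelet, "db6")
  expect_equal(cfg$pcg_band_hz, c(2, 90))
  expect_true(cfg$ecg_invert)
  expect_equal(cfg$min_peak_gap_s, 0.15)  # untouched keys keep defaults
  writeLines("bogus_key = 1", tmp)
  expect_error(read_config(tmp), "unknown config key")
})

test_that("default configuration matches the detector's design constants", {
  cfg <- pipeline_config()
  expect_equal(cfg$pcg_band_hz, c(2, 100))
  expect_equal(cfg$pcg_filter_order, 2L)
  expect_equal(cfg$wavelet, "db12")
  expect_equal(cfg$wavelet_level, 5L)
  expect_equal(cfg$norm_window_s, 1)
  expect_equal(cfg$envelope_cutoff_hz, 10)
  expect_equal(cfg$min_peak_gap_s, 0.15)
  expect_equal(cfg$centroid_fractions, c(0.35, 0.65, 1.0))
  expect_equal(cfg$confirm_low, 0.8)
  expect_equal(cfg$confirm_high, 1.3)
  expect_equal(cfg$recovery_window_s, 0.3)
  expect_equal(c(cfg$s1_window_frac, cfg$s2_window_start_frac,
                 cfg$s2_window_end_frac), c(0.2, 1.2, 0.6))
  expect_equal(cfg$hr_window_s, 2)
})
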