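mk_ecg_ann <- function(r, rr, rt) {
  structure(list(r_times = r, t_times = r + rt, median_rr = rr,
                 median_rt = rt, sample_rate = 2560),
            class = "pcg_ecg_annotations")
}

test_that("scoring windows follow the heart-rate-scaled formulas", {
  ann <- mk_ecg_ann(c(0, 0.84), 0.84, 0.30)
  w <- build_windows(ann)
  expect_equal(w$s1$end - w$s1$start, rep(0.2 * 0.84, 2))  # 0.168 s
  expect_equal(w$s2$start, c(0, 0.84) + 1.2 * 0.30)
  expect_equal(w$s2$end, c(0, 0.84) + 0.6 * 0.84)

  ann2 <- mk_ecg_ann(c(0, 0.80), 0.80, 0.30)
  w2 <- build_windows(ann2)
  expect_equal(w2$s2$start[1], 0.36)
  expect_equal(w2$s2$end[1], 0.48)

  # degenerate: S2 start formula beyond its end -> empty, flagged
  ann3 <- mk_ecg_ann(c(0, 0.8), 0.80, 0.45)
  w3 <- build_windows(ann3)
  expect_true(all(w3$s2$empty))

  # missing RT -> no S2 windows, S1 still produced
  ann4 <- mk_ecg_ann(c(0, 0.8), 0.80, NA_real_)
  w4 <- build_windows(ann4)
  expect_null(w4$s2)
  expect_equal(nrow(w4$s1), 2L)
})

test_that("detection scoring matches brute-force interval membership", {
  w <- data.frame(start = (0:9), end = (0:9) + 0.2)
  d <- w$start[1:9] + 0.1                      # 9 hits, 1 empty window
  m <- score_detection(d, w)
  expect_equal(c(m$tp, m$fn, m$fp), c(9, 1, 0))
  expect_equal(m$se, 90)
  expect_equal(m$ppv, 100)

  empty <- score_detection(numeric(), w)
  expect_equal(empty$se, 0)
  expect_true(is.na(empty$ppv))                # undefined, never zero

  # double hit in one window: one credit, one FP
  dbl <- score_detection(c(0.05, 0.1), w)
  expect_equal(c(dbl$tp, dbl$fp), c(1, 1))

  expect_error(
    score_detection(1, data.frame(start = c(0, 0.1), end = c(0.3, 0.4))),
    "pcgbeat_invalid_windows")

  set.seed(41)
  for (rep in 1:40) {
    nw <- sample(3:15, 1)
    starts <- sort(runif(nw, 0, 20))
    ends <- starts + pmin(diff(c(starts, 21)), runif(nw, 0.05, 0.5))
    d <- runif(sample(0:25, 1), 0, 21)
    got <- score_detection(d, data.frame(start = starts, end = ends))
    want <- oracle_score(d, starts, ends)
    expect_equal(c(got$tp, got$fp, got$fn), c(want$tp, want$fp, want$fn))
    expect_equal(got$tp + got$fn, nw)          # conservation
    if (!is.na(got$se)) expect_true(got$se >= 0 && got$se <= 100)
    if (!is.na(got$ppv)) expect_true(got$ppv >= 0 && got$ppv <= 100)
  }
})

test_that("metric summaries use interpolated quartiles and IQR = Q3 - Q1", {
  s <- summarize_metrics(c(95.8, 96.2, 98.5, 99.1, 99.5))
  expect_equal(s$iqr, s$q3 - s$q1)

  one <- summarize_metrics(42)
  expect_equal(c(one$min, one$median, one$max, one$iqr), c(42, 42, 42, 0))

  v <- c(1, 2, 3, 4)
  s4 <- summarize_metrics(v)
  expect_equal(s4$q1, oracle_quantile7(v, 0.25))
  expect_equal(s4$q3, oracle_quantile7(v, 0.75))
  expect_error(summarize_metrics(numeric()), "pcgbeat_empty_input")

  set.seed(42)
  for (rep in 1:30) {
    v <- runif(sample(2:40, 1), 0, 100)
    s <- summarize_metrics(v)
    expect_equal(s$q1, oracle_quantile7(v, 0.25))
    expect_equal(s$median, oracle_quantile7(v, 0.5))
    expect_equal(s$q3, oracle_quantile7(v, 0.75))
  }
})

test_that("heart-rate series uses the median gap per 2 s window", {
  hr <- heart_rate_series(seq(0, 30, by = 0.75), 30)
  expect_true(all(abs(hr$hr_bpm - 80) < 1e-9, na.rm = TRUE))
  expect_false(anyNA(hr$hr_bpm[2:14]))

  # gaps 0.70, 0.80, 0.90 within one window -> 60 / 0.80
  hr2 <- heart_rate_series(c(0.1, 0.8, 1.6, 2.5), 4, window_s = 4)
  expect_equal(hr2$hr_bpm[1], 75)

  hr3 <- heart_rate_series(numeric(), 10)
  expect_true(all(is.na(hr3$hr_bpm)))
})

test_that("paired Wilcoxon comparison behaves at both extremes", {
  grid <- data.frame(window_start = seq(0, 58, 2))
  a <- grid; a$hr_bpm <- 70 + sin(seq_len(30))
  same <- compare_hr_paired(a, a)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  b <- a; b$hr_bpm <- a$hr_bpm + 5
  shifted <- compare_hr_paired(a, b)
  expect_lt(shifted$p_value, 0.05)
  # symmetry: swapping the series leaves p unchanged
  expect_equal(compare_hr_paired(b, a)$p_value, shifted$p_value)

  few <- data.frame(window_start = 0:4 * 2, hr_bpm = rep(70, 5))
  expect_error(compare_hr_paired(few, few), "pcgbeat_insufficient_pairs")
})

test_that("whole-record evaluation has the right shape and is reproducible", {
  g <- generate_recording(simulation_spec(duration = 30, hr_bpm = 72,
                                          seed = 51, n_pcg_channels = 3))
  ev1 <- evaluate_record(g$recording)
  expect_equal(nrow(ev1$metrics), 6L)          # 3 channels x S1/S2
  expect_setequal(unique(ev1$metrics$label), c("S1", "S2"))
  ev2 <- evaluate_record(g$recording)
  expect_identical(ev1$metrics, ev2$metrics)
  expect_identical(ev1$hr_tests, ev2$hr_tests)
})
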