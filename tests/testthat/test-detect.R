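fs <- 2560

test_that("thresholds follow the envelope statistics", {
  th <- compute_thresholds(0.2, 0.5)
  expect_equal(th$th1, -0.36)
  expect_equal(th$th2, 0)     # Th2 = global mean on the standardized scale
  expect_equal(compute_thresholds(0, 1)$th1, 0)
  expect_error(compute_thresholds(0.2, 0), "pcgbeat_constant_signal")
})

test_that("candidate peaks equal a brute-force local-maximum scan", {
  expect_equal(nrow(detect_candidate_peaks(seq(0, 1, 0.01), 100, -0.36)), 0L)

  tri <- c(seq(0, 2, length.out = 50), seq(2, 0, length.out = 50)[-1])
  pk <- detect_candidate_peaks(tri, 100, -0.36)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$amplitude, 2)

  set.seed(21)
  for (rep in 1:20) {
    x <- bump_envelope(sort(runif(10, 0.5, 9.5)), 200, 10) + rnorm(2000, 0, 0.05)
    th <- runif(1, -0.5, 0.5)
    got <- detect_candidate_peaks(x, 200, th)
    want <- oracle_local_maxima(x, th)
    expect_equal(round(got$time * 200) + 1, want)
    expect_equal(got$amplitude, x[want])
  }
})

test_that("minimum-spacing rule matches exhaustive removal and its examples", {
  pk <- function(t, a) data.frame(time = t, amplitude = a, above_th2 = NA)
  expect_equal(enforce_min_spacing(pk(c(0, 0.10), c(1.0, 0.8)))$time, 0)
  expect_equal(enforce_min_spacing(pk(c(0, 0.40), c(1.0, 0.8)))$time,
               c(0, 0.40))
  # chain resolves closest pair first, to a fixed point
  chain <- enforce_min_spacing(pk(c(0, 0.10, 0.20), c(0.5, 0.9, 0.6)))
  expect_equal(chain$time, 0.10)

  set.seed(22)
  for (rep in 1:50) {
    n <- sample(3:25, 1)
    t <- sort(runif(n, 0, 3))
    a <- runif(n)
    got <- enforce_min_spacing(pk(t, a), 0.15)
    want <- oracle_min_spacing(t, a, 0.15)
    expect_equal(got$time, want$times)
    if (nrow(got) > 1) expect_true(all(diff(got$time) >= 0.15))
  }
})

test_that("presumed heart period is the mode of lag-2 intervals", {
  # alternating S1/S2: systole 0.3, diastole 0.5 -> every lag-2 gap 0.8
  t <- cumsum(c(0, rep(c(0.3, 0.5), 10)))
  expect_equal(presumed_heart_period(t), 0.8)
  # counting with a tie-free mode
  t2 <- c(0, 0.80, 1.60, 2.39, 4.01)
  got <- presumed_heart_period(t2)
  expect_equal(got, oracle_period_mode(t2, 0.01))
  expect_error(presumed_heart_period(c(0, 1)), "pcgbeat_insufficient_peaks")

  set.seed(23)
  for (rep in 1:30) {
    t <- sort(runif(sample(5:40, 1), 0, 30))
    expect_equal(presumed_heart_period(t), oracle_period_mode(t, 0.01))
  }
})

test_that("interval K-means converges to a nearest-centroid fixed point", {
  cls <- classify_intervals_kmeans(c(0.28, 0.30, 0.50, 0.52, 0.80), 0.80)
  expect_equal(cls$labels,
               c("systole", "systole", "diastole", "diastole", "longer"))
  expect_equal(cls$centroids, c(0.29, 0.51, 0.80))

  one <- classify_intervals_kmeans(0.30, 0.80)
  expect_equal(one$labels, "systole")

  alld <- classify_intervals_kmeans(rep(0.65 * 0.8, 4), 0.8)
  expect_equal(unique(alld$labels), "diastole")

  expect_error(classify_intervals_kmeans(numeric(), 0.8),
               "pcgbeat_insufficient_peaks")
  expect_error(classify_intervals_kmeans(0.3, 0), "pcgbeat_invalid_period")

  set.seed(24)
  for (rep in 1:50) {
    iv <- runif(sample(1:40, 1), 0.1, 1.6)
    Tp <- runif(1, 0.5, 1.2)
    cls <- classify_intervals_kmeans(iv, Tp)
    # fixed point: every interval sits with its nearest final centroid
    d <- abs(outer(cls$intervals, cls$centroids, "-"))
    expect_equal(cls$assignments, max.col(-d, ties.method = "first"))
    expect_true(all(diff(cls$centroids) >= 0))
  }
})

test_that("peaks are labelled by the interval they open", {
  pk <- function(t, a = rep(1, length(t))) data.frame(time = t, amplitude = a)
  # alternating short/long starting with short -> S1,S2,...; last peak U
  t <- cumsum(c(0.5, rep(c(0.3, 0.5), 4)))
  cls <- classify_intervals_kmeans(diff(t), 0.8)
  ann <- assign_labels(pk(t), cls, pk(t))
  expect_equal(ann$s1$time, t[seq(1, 7, 2)])
  expect_equal(ann$s2$time, t[seq(2, 8, 2)])
  expect_equal(ann$unclassified$time, t[9])

  # all gaps "longer" -> everything unclassified
  tl <- cumsum(c(0.5, rep(0.8, 4)))
  cls_l <- classify_intervals_kmeans(diff(tl), 0.8)
  ann_l <- assign_labels(pk(tl), cls_l, pk(tl))
  expect_equal(nrow(ann_l$s1), 0L)
  expect_equal(nrow(ann_l$s2), 0L)
  expect_equal(ann_l$unclassified$time, tl)

  # a below-Th2 peak between classified peaks stays unclassified here
  all_peaks <- pk(sort(c(t, 0.65)))
  ann_b <- assign_labels(pk(t), cls, all_peaks)
  expect_true(0.65 %in% ann_b$unclassified$time)
  expect_false(0.65 %in% c(ann_b$s1$time, ann_b$s2$time))
})

test_that("confirmation demotes early peaks and recovers missed ones", {
  mk <- function(s1, uncl) {
    structure(list(
      s1 = data.frame(time = s1, amplitude = rep(1, length(s1))),
      s2 = data.frame(time = numeric(), amplitude = numeric()),
      unclassified = data.frame(time = uncl,
                                amplitude = rep(0.5, length(uncl))),
      presumed_period = 0.8, removed = 0L, recovered = 0L),
      class = "pcg_heart_sounds")
  }
  # recovery: gap 1.6 > 1.04, window [1.45, 1.75] centred at 1.6
  got <- confirm_peaks(mk(c(0, 0.8, 2.4), 1.58))
  expect_equal(got$s1$time, c(0, 0.8, 1.58, 2.4))
  expect_equal(got$recovered, 1L)

  # demotion: gap 0.5 < 0.64
  got2 <- confirm_peaks(mk(c(0, 0.5, 0.8), numeric()))
  expect_equal(got2$s1$time, c(0, 0.8))
  expect_equal(got2$removed, 1L)

  # two candidates in the window: closer to the centre wins
  got3 <- confirm_peaks(mk(c(0, 0.8, 2.4), c(1.55, 1.65)))
  expect_true(1.65 %in% got3$s1$time)
  expect_false(1.55 %in% got3$s1$time)
  # exact distance tie -> earlier peak
  got4 <- confirm_peaks(mk(c(0, 0.8, 2.4), c(1.55, 1.65 + 1e-9)))
  expect_true(1.55 %in% got4$s1$time)

  # never creates a same-label gap below 0.8 * period
  set.seed(25)
  for (rep in 1:30) {
    s1 <- sort(runif(sample(3:10, 1), 0, 8))
    uncl <- sort(runif(8, 0, 8))
    uncl <- uncl[!uncl %in% s1]
    out <- confirm_peaks(mk(s1, uncl))
    if (nrow(out$s1) > 1) {
      expect_true(all(diff(out$s1$time) >= 0.8 * 0.8 - 1e-12))
    }
  }
})

test_that("end-to-end detection is deterministic and tracks the beat count", {
  g <- generate_recording(simulation_spec(duration = 60, hr_bpm = 60,
                                          seed = 31))
  hs1 <- detect_heart_sounds(g$recording)
  hs2 <- detect_heart_sounds(g$recording)
  expect_identical(hs1$s1, hs2$s1)
  expect_identical(hs1$s2, hs2$s2)

  n_truth <- length(g$truth$s1_times)
  expect_lte(abs(nrow(hs1$s1) - n_truth), 1)
  expect_lte(abs(nrow(hs1$s2) - n_truth), 1)

  # all-noise input must not crash: sparse or diagnosably absent output
  set.seed(32)
  noise <- recording(matrix(rnorm(fs * 10), ncol = 1), fs, "pcg")
  res <- tryCatch(detect_heart_sounds(noise), error = identity)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "pcgbeat_insufficient_peaks")
  } else {
    expect_s3_class(res, "pcg_heart_sounds")
    expect_gt(nrow(res$unclassified), 0)
    # noise peaks cannot be denser than the 150 ms spacing rule allows
    total <- nrow(res$s1) + nrow(res$s2) + nrow(res$unclassified)
    expect_lte(total, 10 / 0.15 + 1)
  }

  expect_error(
    detect_heart_sounds(recording(matrix(0, fs, 1), fs, "pcg")),
    "pcgbeat_insufficient_data")
  rec2 <- recording(matrix(rnorm(fs * 8), ncol = 2), fs, c("ecg", "pcg"))
  expect_error(detect_heart_sounds(rec2, channel = 1), "not a PCG channel")
})

test_that("annotations shift with the signal (1 s integer-window shift)", {
  g <- generate_recording(simulation_spec(duration = 20, hr_bpm = 75,
                                          seed = 33))
  x <- g$recording$samples[, 2]
  h1 <- detect_heart_sounds(recording(x, fs, "pcg"))
  h2 <- detect_heart_sounds(recording(c(numeric(fs), x), fs, "pcg"))
  # away from the record edges every S1 must reappear 1 s later
  core <- h1$s1$time[h1$s1$time > 2 & h1$s1$time < 18]
  for (tt in core) {
    expect_lt(min(abs(h2$s1$time - (tt + 1))), 2 / fs)
  }
})
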