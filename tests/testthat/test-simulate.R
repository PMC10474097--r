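test_that("systole fraction follows the rate-dependence anchors", {
  expect_equal(systole_fraction(60), 0.35)
  expect_equal(systole_fraction(130), 0.50)
  expect_equal(systole_fraction(40), 0.35)     # clipped below
  hr <- seq(60, 130, by = 5)
  expect_true(all(diff(systole_fraction(hr)) >= 0))
})

test_that("generated beats respect the timing physiology", {
  g <- generate_recording(simulation_spec(duration = 60, hr_bpm = 75,
                                          seed = 61))
  tr <- g$truth
  n <- length(tr$r_times)
  expect_lte(abs(n - 75), 1)                    # ~75 beats in 60 s
  # R < S1 < S2 < next R within every beat
  expect_true(all(tr$r_times < tr$s1_times))
  expect_true(all(tr$s1_times < tr$s2_times))
  expect_true(all(tr$s2_times[-n] < tr$r_times[-1]))
  # T maxima sit strictly between their R and the next R
  expect_true(all(tr$t_times[-n] < tr$r_times[-1]))

  # resting systole/diastole ratio ~ 35/65 of the beat period
  g70 <- generate_recording(simulation_spec(duration = 30, hr_bpm = 70,
                                            jitter_s = 0, seed = 62))
  frac <- g70$truth$systole_s / (60 / 70)
  expect_equal(unname(frac[1]), systole_fraction(70), tolerance = 1e-9)
  ratio <- g70$truth$systole_s / (g70$truth$systole_s + g70$truth$diastole_s)
  expect_equal(median(ratio, na.rm = TRUE), systole_fraction(70),
               tolerance = 0.02)
})

test_that("generation is bit-reproducible from the seed", {
  s <- simulation_spec(duration = 10, seed = 63)
  a <- generate_recording(s)
  b <- generate_recording(s)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth, b$truth)
})

test_that("white noise hits the requested SNR and spikes obey their rate", {
  g <- generate_recording(simulation_spec(duration = 30, hr_bpm = 70,
                                          snr_db = Inf, wander_amp = 0,
                                          seed = 64))
  clean <- g$recording$samples[, 2]
  noisy <- add_noise(g$recording, snr_db = 20, wander_amp = 0,
                     spike_rate = 0, seed = 65)
  noise <- noisy$samples[, 2] - clean
  snr <- 10 * log10(mean(clean^2) / mean(noise^2))
  expect_lt(abs(snr - 20), 0.5)

  none <- add_noise(g$recording, snr_db = Inf, wander_amp = 0,
                    spike_rate = 0, seed = 66)
  expect_identical(none$samples, g$recording$samples)

  spiky <- add_noise(g$recording, snr_db = Inf, wander_amp = 0,
                     spike_rate = 0.5, seed = 67)
  expect_gt(max(abs(spiky$samples[, 2])), 1.5 * max(abs(clean)))
  # ECG channel is never touched
  expect_identical(spiky$samples[, 1], g$recording$samples[, 1])
})

test_that("baseline wander is almost entirely removed by the band-pass", {
  fs <- 2560
  silent <- recording(matrix(0, fs * 20, 1), fs, "pcg")
  wandered <- add_noise(silent, snr_db = Inf, wander_amp = 0.5,
                        spike_rate = 0, seed = 68)
  w <- wandered$samples[, 1]
  resid <- bandpass_pcg(w, fs)$samples
  core <- seq(2 * fs, 18 * fs)
  expect_lt(mean(resid[core]^2), 0.05 * mean(w[core]^2))
})

test_that("heart-sound bursts keep >= 95% of their energy below 100 Hz", {
  g <- generate_recording(simulation_spec(duration = 20, hr_bpm = 70,
                                          snr_db = Inf, wander_amp = 0,
                                          seed = 69))
  x <- g$recording$samples[, 2]
  sp <- stats::spec.pgram(ts(x, frequency = 2560), plot = FALSE, taper = 0)
  below <- sum(sp$spec[sp$freq < 100])
  expect_gte(below / sum(sp$spec), 0.95)
})

test_that("cohorts are deterministic and carry the pathology flag", {
  c1 <- make_cohort(5, duration = 10, master_seed = 7)
  c2 <- make_cohort(5, duration = 10, master_seed = 7)
  expect_length(c1, 5L)
  expect_identical(c1[[3]]$recording$samples, c2[[3]]$recording$samples)
  # distinct records within a cohort
  expect_false(identical(c1[[1]]$recording$samples,
                         c1[[2]]$recording$samples))
  att <- make_cohort(3, duration = 10, master_seed = 7,
                     s2_attenuation = c(1, 0.1, 1))
  expect_false(att[[1]]$truth$pathological)
  expect_true(att[[2]]$truth$pathological)
})

test_that("invalid specifications are rejected", {
  expect_error(simulation_spec(hr_bpm = 150), "40-140")
  expect_error(simulation_spec(s1_freq_hz = 120), "s1_freq_hz")
  expect_error(generate_recording(simulation_spec(duration = 1)),
               "3 beats")
})
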