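#' Systole fraction of the beat period as a function of heart rate
#'
#' At rest (around 60 bpm) systole occupies roughly 35% of the beat and
#' diastole 65%; as heart rate rises the diastole shortens faster, and near
#' 130 bpm the two are almost equal.  Modelled as a linear ramp from 0.35 at
#' 60 bpm to 0.50 at 130 bpm, clipped outside that range.
#'
#' @param hr_bpm Heart rate in beats per minute.
#' @return Fraction of the beat period occupied by systole, in (0, 0.5\].
#' @examples
#' systole_fraction(c(60, 95, 130))
#' @export
systole_fraction <- function(hr_bpm) {
  pmin(pmax(0.35 + 0.15 * (hr_bpm - 60) / 70, 0.35), 0.5)
}

#' Specification of a synthetic PCG+ECG recording
#'
#' Collects the physiological and noise parameters of the simulator.  The
#' defaults describe a resting adult recorded by a chest sensor whose
#' pass-band ends at 100 Hz: S1 and S2 are Hann-windowed sinusoidal bursts
#' below 100 Hz, the ECG carries an R spike and a T bump per beat, and the
#' PCG is contaminated by white noise at a requested SNR plus baseline
#' wander and optional motion spikes.
#'
#' @param duration Record length in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param hr_bpm Heart rate: a constant (bpm) or a function of time
#'   returning bpm, kept within 40--140.
#' @param jitter_s Per-beat Gaussian jitter of the beat period (s).
#' @param s1_freq_hz,s1_dur_s,s1_amp S1 burst centre frequency, duration and
#'   amplitude.
#' @param s2_freq_hz,s2_dur_s,s2_amp S2 burst parameters.
#' @param s2_attenuation Multiplier on the S2 amplitude (0.1 emulates the
#'   attenuated-S2 pathology).
#' @param r_s1_delay_s Electromechanical delay from the R peak to S1 (s).
#' @param snr_db White-noise SNR of the PCG channels (dB, measured against
#'   the clean PCG); `Inf` for noise-free.
#' @param wander_amp Baseline-wander amplitude (signal units).
#' @param spike_rate Motion-spike rate (events per second).
#' @param ecg_r_amp,ecg_r_width_s R spike amplitude and Gaussian width.
#' @param ecg_t_amp,ecg_t_width_s T bump amplitude and width; the T maximum
#'   sits `0.25 * sqrt(RR)` after each R (Bazett-like rate scaling).
#' @param ecg_noise_sd ECG additive noise standard deviation.
#' @param n_pcg_channels Number of identical-physiology PCG channels (each
#'   gets independent noise).
#' @param seed Integer seed; every stochastic draw passes through one stream
#'   seeded with it.
#' @return Object of class `pcg_sim_spec`.
#' @export
simulation_spec <- function(duration = 60, sample_rate = 2560,
                            hr_bpm = 70, jitter_s = 0.003,
                            s1_freq_hz = 35, s1_dur_s = 0.12, s1_amp = 1.0,
                            s2_freq_hz = 50, s2_dur_s = 0.10, s2_amp = 0.8,
                            s2_attenuation = 1.0,
                            r_s1_delay_s = 0.04,
                            snr_db = 20, wander_amp = 0.1, spike_rate = 0,
                            ecg_r_amp = 1.0, ecg_r_width_s = 0.012,
                            ecg_t_amp = 0.3, ecg_t_width_s = 0.04,
                            ecg_noise_sd = 0.01,
                            n_pcg_channels = 1L, seed = 1L) {
  spec <- list(duration = duration, sample_rate = sample_rate,
               hr_bpm = hr_bpm, jitter_s = jitter_s,
               s1_freq_hz = s1_freq_hz, s1_dur_s = s1_dur_s, s1_amp = s1_amp,
               s2_freq_hz = s2_freq_hz, s2_dur_s = s2_dur_s, s2_amp = s2_amp,
               s2_attenuation = s2_attenuation,
               r_s1_delay_s = r_s1_delay_s,
               snr_db = snr_db, wander_amp = wander_amp,
               spike_rate = spike_rate,
               ecg_r_amp = ecg_r_amp, ecg_r_width_s = ecg_r_width_s,
               ecg_t_amp = ecg_t_amp, ecg_t_width_s = ecg_t_width_s,
               ecg_noise_sd = ecg_noise_sd,
               n_pcg_channels = as.integer(n_pcg_channels),
               seed = as.integer(seed))
  validate_sim_spec(spec)
  structure(spec, class = "pcg_sim_spec")
}

validate_sim_spec <- function(spec) {
  hr_probe <- if (is.function(spec$hr_bpm)) {
    spec$hr_bpm(seq(0, spec$duration, length.out = 64))
  } else spec$hr_bpm
  if (any(hr_probe < 40 | hr_probe > 140)) {
    stop("pcgbeat_invalid_spec: heart-rate trajectory must stay in 40-140 bpm",
         call. = FALSE)
  }
  stopifnot(
    spec$duration > 0, spec$sample_rate > 0,
    spec$s1_freq_hz < 100, spec$s2_freq_hz < 100,
    spec$s1_dur_s > 0, spec$s2_dur_s > 0,
    spec$s1_amp > 0, spec$s2_amp > 0, spec$s2_attenuation >= 0,
    spec$r_s1_delay_s >= 0, spec$jitter_s >= 0,
    spec$spike_rate >= 0, spec$n_pcg_channels >= 1L
  )
  invisible(spec)
}

# Run code with a private RNG stream; NULL seed continues the current stream.
with_rng <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  force(code)
}

hann_burst <- function(n_total, fs, center_s, freq_hz, dur_s, amp) {
  half <- dur_s / 2
  i0 <- max(1L, time_to_index(center_s - half, fs) + 1L)
  i1 <- min(n_total, time_to_index(center_s + half, fs) + 1L)
  if (i0 > i1) return(NULL)
  t <- (seq.int(i0, i1) - 1L) / fs
  phase <- (t - center_s + half) / dur_s          # 0..1 across the burst
  w <- 0.5 - 0.5 * cos(2 * pi * phase)            # Hann window
  list(idx = i0:i1, vals = amp * w * sin(2 * pi * freq_hz * (t - center_s)))
}

gauss_bump <- function(n_total, fs, center_s, width_s, amp) {
  i0 <- max(1L, time_to_index(center_s - 4 * width_s, fs) + 1L)
  i1 <- min(n_total, time_to_index(center_s + 4 * width_s, fs) + 1L)
  if (i0 > i1) return(NULL)
  t <- (seq.int(i0, i1) - 1L) / fs
  list(idx = i0:i1, vals = amp * exp(-0.5 * ((t - center_s) / width_s)^2))
}

#' Generate a synthetic PCG+ECG recording with ground truth
#'
#' Beats are placed at `60 / HR` spacing (plus optional jitter); in each
#' beat S1 follows the R peak by a fixed electromechanical delay and S2
#' follows S1 by the heart-rate-dependent systole duration
#' ([systole_fraction()] times the beat period).  Heart sounds are
#' Hann-windowed sinusoids; the ECG channel carries Gaussian R spikes and T
#' bumps.  Noise (white at the requested SNR, baseline wander, motion
#' spikes) is added last.  Fully reproducible from `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @return List with `recording` (a [recording()]: ECG channel first, then
#'   the PCG channels) and `truth` (class `pcg_ground_truth`: `r_times`,
#'   `s1_times`, `s2_times`, `t_times`, `systole_s`, `diastole_s`,
#'   `hr_bpm`, `pathological`).
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "pcg_sim_spec"))
  validate_sim_spec(spec)
  fs <- spec$sample_rate
  n <- as.integer(round(spec$duration * fs))
  hr_at <- if (is.function(spec$hr_bpm)) spec$hr_bpm else function(t) spec$hr_bpm

  with_rng(spec$seed, {
    # ---- beat timing ----
    r_times <- numeric()
    periods <- numeric()
    r <- 0.5
    repeat {
      p <- 60 / hr_at(r)
      if (spec$jitter_s > 0) p <- p + stats::rnorm(1, 0, spec$jitter_s)
      # cardiac activity is continuous: beats span the whole record, and a
      # beat is kept whenever its full cycle fits before the record ends
      if (r + p > spec$duration) break
      r_times <- c(r_times, r)
      periods <- c(periods, p)
      r <- r + p
    }
    nb <- length(r_times)
    if (nb < 3L) {
      stop("pcgbeat_invalid_spec: record too short for 3 beats", call. = FALSE)
    }
    hr_beat <- 60 / periods
    sys_s <- systole_fraction(hr_beat) * periods
    s1_times <- r_times + spec$r_s1_delay_s
    s2_times <- s1_times + sys_s
    t_times <- r_times + 0.25 * sqrt(periods)
    dia_s <- c(s1_times[-1L], NA) - s2_times

    # ---- clean PCG ----
    pcg_clean <- numeric(n)
    s2a <- spec$s2_amp * spec$s2_attenuation
    for (k in seq_len(nb)) {
      b1 <- hann_burst(n, fs, s1_times[k], spec$s1_freq_hz, spec$s1_dur_s,
                       spec$s1_amp)
      if (!is.null(b1)) pcg_clean[b1$idx] <- pcg_clean[b1$idx] + b1$vals
      b2 <- hann_burst(n, fs, s2_times[k], spec$s2_freq_hz, spec$s2_dur_s,
                       s2a)
      if (!is.null(b2)) pcg_clean[b2$idx] <- pcg_clean[b2$idx] + b2$vals
    }

    # ---- ECG ----
    ecg <- numeric(n)
    for (k in seq_len(nb)) {
      rb <- gauss_bump(n, fs, r_times[k], spec$ecg_r_width_s, spec$ecg_r_amp)
      if (!is.null(rb)) ecg[rb$idx] <- ecg[rb$idx] + rb$vals
      tb <- gauss_bump(n, fs, t_times[k], spec$ecg_t_width_s, spec$ecg_t_amp)
      if (!is.null(tb)) ecg[tb$idx] <- ecg[tb$idx] + tb$vals
    }
    if (spec$ecg_noise_sd > 0) ecg <- ecg + stats::rnorm(n, 0, spec$ecg_noise_sd)

    # ---- PCG channels with independent noise ----
    samples <- matrix(0, nrow = n, ncol = 1L + spec$n_pcg_channels)
    samples[, 1L] <- ecg
    clean_rec <- recording(matrix(rep(pcg_clean, spec$n_pcg_channels),
                                  ncol = spec$n_pcg_channels),
                           fs, rep("pcg", spec$n_pcg_channels))
    noisy <- add_noise(clean_rec, snr_db = spec$snr_db,
                       wander_amp = spec$wander_amp,
                       spike_rate = spec$spike_rate, seed = NULL)
    samples[, -1L] <- noisy$samples

    rec <- recording(samples, fs,
                     channel_roles = c("ecg", rep("pcg", spec$n_pcg_channels)),
                     channel_names = c("ECG",
                                       paste0("PCG",
                                              seq_len(spec$n_pcg_channels))))
    truth <- structure(
      list(r_times = r_times, s1_times = s1_times, s2_times = s2_times,
           t_times = t_times, systole_s = sys_s, diastole_s = dia_s,
           hr_bpm = hr_beat, pathological = spec$s2_attenuation < 1),
      class = "pcg_ground_truth")
    list(recording = rec, truth = truth)
  })
}

#' @export
print.pcg_ground_truth <- function(x, ...) {
  cat(sprintf("<pcg_ground_truth> %d beats, HR %.1f-%.1f bpm%s\n",
              length(x$r_times), min(x$hr_bpm), max(x$hr_bpm),
              if (isTRUE(x$pathological)) " (attenuated S2)" else ""))
  invisible(x)
}

#' Add noise to the PCG channels of a recording
#'
#' White Gaussian noise scaled so the clean-signal-to-noise power ratio
#' equals `snr_db`; baseline wander as a sub-2 Hz sinusoid pair plus a
#' smoothed random walk scaled to `wander_amp`; sparse motion spikes
#' (exponentially decaying pulses) at `spike_rate` per second.  ECG channels
#' are left untouched.
#'
#' @param rec A [recording()] whose PCG channels carry the clean signal.
#' @param snr_db Target white-noise SNR in dB (`Inf` disables).
#' @param wander_amp Baseline-wander amplitude (signal units; 0 disables).
#' @param spike_rate Expected motion spikes per second (0 disables).
#' @param seed Integer seed, or `NULL` to continue the current RNG stream.
#' @return A [recording()] with contaminated PCG channels.
#' @export
add_noise <- function(rec, snr_db = 20, wander_amp = 0, spike_rate = 0,
                      seed = NULL) {
  stopifnot(inherits(rec, "pcg_recording"), is.finite(snr_db) || snr_db == Inf)
  fs <- rec$sample_rate
  n <- nrow(rec$samples)
  t <- (seq_len(n) - 1L) / fs
  with_rng(seed, {
    out <- rec$samples
    for (ch in which(rec$channel_roles == "pcg")) {
      x <- rec$samples[, ch]
      y <- x
      if (is.finite(snr_db)) {
        p_sig <- mean(x^2)
        if (p_sig > 0) {
          noise_sd <- sqrt(p_sig / 10^(snr_db / 10))
          y <- y + stats::rnorm(n, 0, noise_sd)
        }
      }
      if (wander_amp > 0) {
        ph <- stats::runif(2, 0, 2 * pi)
        wander <- 0.7 * sin(2 * pi * 0.3 * t + ph[1]) +
          0.3 * sin(2 * pi * 1.1 * t + ph[2])
        rw <- cumsum(stats::rnorm(n))
        rw <- rw - mean(rw)
        m <- max(abs(rw))
        if (m > 0) wander <- wander + 0.5 * rw / m
        y <- y + wander_amp * wander
      }
      if (spike_rate > 0) {
        n_spikes <- stats::rpois(1, spike_rate * n / fs)
        if (n_spikes > 0) {
          at <- sort(stats::runif(n_spikes, 0, n / fs))
          amp <- stats::runif(n_spikes, 2, 5) *
            sample(c(-1, 1), n_spikes, replace = TRUE)
          for (j in seq_len(n_spikes)) {
            i0 <- time_to_index(at[j], fs) + 1L
            len <- as.integer(0.03 * fs)
            i1 <- min(n, i0 + len)
            if (i0 <= n) {
              k <- seq.int(i0, i1)
              y[k] <- y[k] + amp[j] * exp(-(k - i0) / (0.008 * fs))
            }
          }
        }
      }
      out[, ch] <- y
    }
    recording(out, fs, rec$channel_roles, rec$channel_names)
  })
}

#' Generate a seeded cohort of synthetic recordings
#'
#' Per-record seeds are drawn deterministically from `master_seed`; record
#' parameters are sampled uniformly from the given ranges.
#'
#' @param n_records Number of records (at least 1).
#' @param hr_range Heart-rate range (bpm) sampled per record.
#' @param duration Record length in seconds.
#' @param s2_attenuation S2 amplitude multiplier applied to every record
#'   (scalar) or per record (vector of length `n_records`).
#' @param master_seed Integer master seed.
#' @param ... Further arguments passed to [simulation_spec()].
#' @return List of `list(recording, truth, spec)` entries.
#' @export
make_cohort <- function(n_records, hr_range = c(60, 90), duration = 60,
                        s2_attenuation = 1, master_seed = 1L, ...) {
  stopifnot(n_records >= 1L)
  s2_att <- rep_len(s2_attenuation, n_records)
  with_rng(master_seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n_records)
    hrs <- stats::runif(n_records, hr_range[1], hr_range[2])
    lapply(seq_len(n_records), function(i) {
      spec <- simulation_spec(duration = duration, hr_bpm = hrs[i],
                              s2_attenuation = s2_att[i],
                              seed = seeds[i], ...)
      out <- generate_recording(spec)
      out$spec <- spec
      out
    })
  })
}

#' Ground-truth annotation track
#'
#' @param truth A `pcg_ground_truth` object.
#' @return An [annotation_track()] with `R`, `S1`, `S2`, `T` events.
#' @export
truth_track <- function(truth) {
  df <- rbind(data.frame(time = truth$r_times, label = "R"),
              data.frame(time = truth$s1_times, label = "S1"),
              data.frame(time = truth$s2_times, label = "S2"),
              data.frame(time = truth$t_times, label = "T"))
  df <- df[order(df$time), , drop = FALSE]
  annotation_track(df$time, df$label)
}
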