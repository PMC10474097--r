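# Independent brute-force oracles used to cross-check the pipeline's
# vectorized implementations.  These stay deliberately naive (explicit
# loops, closed forms) so they cannot share a bug with the code under test.

# Analytic magnitude of a bilinear-transform Butterworth filter at f Hz.
# Prototype order n; edges prewarped individually (w = tan(pi f / fs)).
# Zero-phase (forward-backward) application squares the magnitude.
butter_mag_bandpass <- function(f, f1, f2, fs, n = 2) {
  w <- tan(pi * f / fs); w1 <- tan(pi * f1 / fs); w2 <- tan(pi * f2 / fs)
  om <- (w^2 - w1 * w2) / (w * (w2 - w1))
  1 / sqrt(1 + om^(2 * n))
}
butter_mag_lowpass <- function(f, fc, fs, n = 2) {
  1 / sqrt(1 + (tan(pi * f / fs) / tan(pi * fc / fs))^(2 * n))
}
butter_mag_bandstop <- function(f, f1, f2, fs, n = 2) {
  w <- tan(pi * f / fs); w1 <- tan(pi * f1 / fs); w2 <- tan(pi * f2 / fs)
  om <- (w * (w2 - w1)) / (w^2 - w1 * w2)
  1 / sqrt(1 + om^(2 * n))
}

# Steady-state amplitude of a filtered sinusoid (middle half of the trace).
steady_amp <- function(y, fs) {
  n <- length(y)
  max(abs(y[seq.int(floor(n / 4), floor(3 * n / 4))]))
}

# Three-point local-maximum scan, explicit loop.
oracle_local_maxima <- function(x, th) {
  out <- integer()
  for (i in 2:(length(x) - 1L)) {
    if (x[i] > x[i - 1L] && x[i] > x[i + 1L] && x[i] > th) out <- c(out, i)
  }
  out
}

# Exhaustive closest-pair-first removal of peaks closer than min_gap;
# ties on gap -> earliest pair, ties on amplitude -> drop the later peak.
oracle_min_spacing <- function(times, amps, min_gap) {
  repeat {
    if (length(times) < 2L) break
    best <- NULL; best_gap <- Inf
    for (i in seq_len(length(times) - 1L)) {
      g <- times[i + 1L] - times[i]
      if (g < min_gap && g < best_gap) { best <- i; best_gap <- g }
    }
    if (is.null(best)) break
    drop <- if (amps[best] < amps[best + 1L]) best else best + 1L
    times <- times[-drop]; amps <- amps[-drop]
  }
  list(times = times, amps = amps)
}

# Histogram mode of quantized lag-2 gaps, smallest bin on ties.
oracle_period_mode <- function(times, quantum) {
  gaps <- c()
  for (i in seq_len(length(times) - 2L)) gaps <- c(gaps, times[i + 2L] - times[i])
  bins <- round(gaps / quantum)
  counts <- table(bins)
  cand <- as.numeric(names(counts)[counts == max(counts)])
  min(cand) * quantum
}

# Brute-force interval-membership scoring: one TP credit per window,
# extras and strays are FP, empty windows FN.
oracle_score <- function(detections, starts, ends) {
  used <- rep(FALSE, length(starts))
  tp <- 0L; fp <- 0L
  for (d in sort(detections)) {
    inside <- which(starts <= d & d < ends)
    if (length(inside) == 0L) fp <- fp + 1L
    else if (!used[inside[1]]) { used[inside[1]] <- TRUE; tp <- tp + 1L }
    else fp <- fp + 1L
  }
  list(tp = tp, fp = fp, fn = sum(!used))
}

# Type-7 quantile by direct sorted interpolation.
oracle_quantile7 <- function(x, p) {
  s <- sort(x); n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) s[n] else s[lo] + (h - lo) * (s[lo + 1L] - s[lo])
}

# Small synthetic envelope: bumps at given times on a quiet baseline.
bump_envelope <- function(times, fs, duration, width = 0.04, amps = NULL) {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  if (is.null(amps)) amps <- rep(1, length(times))
  x <- numeric(n)
  for (i in seq_along(times)) {
    x <- x + amps[i] * exp(-0.5 * ((t - times[i]) / width)^2)
  }
  x
}
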