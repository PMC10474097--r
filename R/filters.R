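## Zero-phase Butterworth filtering.  All filters in the pipeline run
## forward-backward so that detected event times are not delayed; the signal
## is extended by odd reflection before filtering to suppress edge
## transients (critical for the 2 Hz and 1 Hz high-pass edges, whose impulse
## responses are long).

zero_phase_filter <- function(filt, x, fs, lowest_edge_hz) {
  n <- length(x)
  pad <- min(n - 1L, max(32L, ceiling(3 * fs / lowest_edge_hz)))
  if (pad > 0L && n > 2L) {
    left <- 2 * x[1] - x[(pad + 1):2]
    right <- 2 * x[n] - x[(n - 1):(n - pad)]
    xp <- c(left, x, right)
  } else {
    xp <- x
  }
  y <- signal::filter(filt, xp)
  y <- rev(signal::filter(filt, rev(y)))
  y <- as.numeric(y)
  if (pad > 0L && n > 2L) y <- y[(pad + 1):(pad + n)]
  y
}

as_samples <- function(x) {
  if (inherits(x, "pcg_filtered")) x$samples else as.numeric(x)
}

filtered_signal <- function(samples, sample_rate, stage, parent = NULL) {
  prov <- if (inherits(parent, "pcg_filtered")) parent$provenance else character()
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 provenance = c(prov, stage)),
            class = "pcg_filtered")
}

#' @export
print.pcg_filtered <- function(x, ...) {
  cat(sprintf("<pcg_filtered> %d samples @ %g Hz | %s\n",
              length(x$samples), x$sample_rate,
              paste(x$provenance, collapse = " -> ")))
  invisible(x)
}

#' @export
as.numeric.pcg_filtered <- function(x, ...) x$samples

check_band <- function(low_hz, high_hz, sample_rate) {
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop("pcgbeat_invalid_filter: need 0 < low_hz < high_hz", call. = FALSE)
  }
  if (high_hz >= sample_rate / 2) {
    stop("pcgbeat_invalid_filter: band edge ", high_hz,
         " Hz reaches the Nyquist frequency (fs = ", sample_rate, " Hz)",
         call. = FALSE)
  }
}

#' Band-pass filter a PCG channel
#'
#' Zero-phase Butterworth band-pass.  The default 2--100 Hz band removes
#' baseline wander and motion artifacts below 2 Hz and broadband noise above
#' 100 Hz while keeping the S1/S2 energy, which lies below 100 Hz.
#'
#' @param signal Numeric vector (or a previous stage's output).
#' @param sample_rate Sampling rate in Hz.
#' @param low_hz,high_hz Band edges in Hz.
#' @param order Butterworth prototype order.
#' @return A `pcg_filtered` object (same length as the input).
#' @export
bandpass_pcg <- function(signal, sample_rate, low_hz = 2, high_hz = 100,
                         order = 2L) {
  x <- as_samples(signal)
  check_band(low_hz, high_hz, sample_rate)
  bf <- signal::butter(order, c(low_hz, high_hz) / (sample_rate / 2),
                       type = "pass")
  y <- zero_phase_filter(bf, x, sample_rate, low_hz)
  filtered_signal(y, sample_rate,
                  sprintf("bandpass %g-%g Hz (order %d)", low_hz, high_hz,
                          order),
                  parent = signal)
}

#' Low-pass the Shannon energy into a smooth envelope
#'
#' Zero-phase Butterworth low-pass (default 10 Hz, order 2).  Zero-phase
#' operation matters here: the envelope maxima are the detected heart-sound
#' times, so any phase delay would bias every annotation.
#'
#' @param energy Numeric Shannon-energy sequence.
#' @param sample_rate Sampling rate in Hz.
#' @param cutoff_hz Cut-off frequency in Hz.
#' @param order Filter order.
#' @return Numeric vector, same length as `energy`.
#' @export
envelope_lowpass <- function(energy, sample_rate, cutoff_hz = 10, order = 2L) {
  x <- as_samples(energy)
  if (!(cutoff_hz > 0 && cutoff_hz < sample_rate / 2)) {
    stop("pcgbeat_invalid_filter: cutoff must lie in (0, fs/2)", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (sample_rate / 2), type = "low")
  zero_phase_filter(bf, x, sample_rate, cutoff_hz)
}

#' Filter the reference ECG
#'
#' Zero-phase 2nd-order Butterworth band-pass (1--150 Hz, suppressing motion
#' and respiration drift and high-frequency noise) followed by a zero-phase
#' band-stop (48--52 Hz) removing mains interference.
#'
#' @param ecg Numeric ECG sequence.
#' @param sample_rate Sampling rate in Hz; must exceed 300 Hz so the 150 Hz
#'   edge is below Nyquist.
#' @param band_hz,stop_hz Pass-band and stop-band edges in Hz.
#' @param order Filter order for both stages.
#' @return Numeric vector, same length as `ecg`.
#' @export
filter_ecg <- function(ecg, sample_rate, band_hz = c(1, 150),
                       stop_hz = c(48, 52), order = 2L) {
  x <- as_samples(ecg)
  if (sample_rate <= 2 * band_hz[2]) {
    stop("pcgbeat_invalid_filter: sample rate ", sample_rate,
         " Hz too low for a ", band_hz[2], " Hz band edge", call. = FALSE)
  }
  bp <- signal::butter(order, band_hz / (sample_rate / 2), type = "pass")
  bs <- signal::butter(order, stop_hz / (sample_rate / 2), type = "stop")
  y <- zero_phase_filter(bp, x, sample_rate, band_hz[1])
  zero_phase_filter(bs, y, sample_rate, stop_hz[1])
}
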