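#' Window-wise amplitude normalization
#'
#' Rescales the signal to \[-1, 1\] inside consecutive non-overlapping
#' windows (default 1 s): each window is divided by its own maximum absolute
#' value.  Normalizing per window rather than globally stops a single large
#' artifact (e.g. a movement spike) from crushing the amplitude of the rest
#' of the recording.  A trailing partial window is normalized by its own
#' maximum; all-zero (or sub-`1e-12`) windows are passed through as zeros so
#' no division by zero occurs.
#'
#' @param signal Numeric vector (or a previous stage's output).
#' @param sample_rate Sampling rate in Hz.
#' @param window_s Window length in seconds.
#' @return A `pcg_filtered` object with every window's peak magnitude equal
#'   to 1 (except all-zero windows).
#' @export
normalize_windowed <- function(signal, sample_rate, window_s = 1) {
  x <- as_samples(signal)
  if (window_s <= 0) {
    stop("pcgbeat_invalid_filter: window_s must be positive", call. = FALSE)
  }
  n <- length(x)
  w <- max(1L, as.integer(round(window_s * sample_rate)))
  starts <- seq.int(1L, n, by = w)
  y <- x
  for (s in starts) {
    e <- min(s + w - 1L, n)
    m <- max(abs(x[s:e]))
    if (m > 1e-12) y[s:e] <- x[s:e] / m
    else y[s:e] <- 0
  }
  filtered_signal(y, sample_rate, sprintf("normalize %gs windows", window_s),
                  parent = signal)
}

#' Run the full PCG preprocessing chain
#'
#' Band-pass, wavelet denoise, and window-normalize one PCG channel, in that
#' order.
#'
#' @param x Numeric PCG signal.
#' @param sample_rate Sampling rate in Hz.
#' @param config A [pipeline_config()].
#' @return A `pcg_filtered` object in \[-1, 1\].
#' @export
preprocess_pcg <- function(x, sample_rate, config = pipeline_config()) {
  y <- bandpass_pcg(x, sample_rate,
                    low_hz = config$pcg_band_hz[1],
                    high_hz = config$pcg_band_hz[2],
                    order = config$pcg_filter_order)
  y <- wavelet_denoise(y, wavelet = config$wavelet,
                       level = config$wavelet_level)
  normalize_windowed(y, sample_rate, window_s = config$norm_window_s)
}
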