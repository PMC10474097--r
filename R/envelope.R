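#' Third-order Shannon energy
#'
#' Pointwise transform `E(i) = -|x(i)^3| * log(|x(i)^3|)` of a normalized
#' signal.  Cubing before the Shannon transform emphasizes medium-amplitude
#' oscillations (heart-sound bursts) while suppressing both the low-level
#' noise floor and samples near full scale; the energy is zero at `x = 0`
#' (limit convention) and at `|x| = 1`, and non-negative in between.
#'
#' @param normalized_signal Numeric vector with values in \[-1, 1\]
#'   (tolerance `1e-9`), typically from [normalize_windowed()].
#' @param log_base Base of the logarithm.  Changing the base rescales the
#'   energy by a positive constant, which cancels in the detector's
#'   thresholds; the default is the natural log.
#' @return Numeric vector of non-negative energies, same length as input.
#' @examples
#' shannon_energy(c(0, 0.5, 1))    # 0, 0.125*log(8), 0
#' @export
shannon_energy <- function(normalized_signal, log_base = exp(1)) {
  x <- as_samples(normalized_signal)
  if (any(abs(x) > 1 + 1e-9)) {
    stop("pcgbeat_not_normalized: input exceeds [-1, 1] (max |x| = ",
         format(max(abs(x))), ")", call. = FALSE)
  }
  a <- pmin(abs(x)^3, 1)
  e <- ifelse(a > 0, -a * log(a, base = log_base), 0)
  pmax(e, 0)
}

#' Standardize an envelope to zero mean and unit variance
#'
#' `E_N = (E - mu) / sigma` with `mu` and `sigma` the global mean and
#' standard deviation of the smoothed energy.  The returned `mu`/`sigma`
#' feed the detector's thresholds.
#'
#' @param envelope Numeric smoothed-energy sequence (non-constant).
#' @return List with `normalized`, `mu`, `sigma`.
#' @export
normalize_energy <- function(envelope) {
  x <- as_samples(envelope)
  mu <- mean(x)
  sigma <- stats::sd(x)
  if (!is.finite(sigma) || sigma <= 0) {
    stop("pcgbeat_constant_signal: envelope has zero variance; ",
         "cannot standardize", call. = FALSE)
  }
  list(normalized = (x - mu) / sigma, mu = mu, sigma = sigma)
}

#' Compute the normalized Shannon-energy envelope of a preprocessed PCG
#'
#' Chains [shannon_energy()], [envelope_lowpass()] and [normalize_energy()].
#' The mean and standard deviation are taken over the smoothed envelope of
#' the whole recording — the same signal whose peaks are picked — so the
#' derived thresholds are constants across the trace.
#'
#' @param normalized_signal Output of [normalize_windowed()] (values in
#'   \[-1, 1\]).
#' @param sample_rate Sampling rate in Hz.
#' @param config A [pipeline_config()].
#' @return An object of class `pcg_envelope` with fields `shannon_energy`,
#'   `envelope` (low-pass-smoothed energy), `normalized` (standardized
#'   envelope), `mu`, `sigma`, `sample_rate`.
#' @export
pcg_envelope <- function(normalized_signal, sample_rate,
                         config = pipeline_config()) {
  es <- shannon_energy(normalized_signal, log_base = config$shannon_log_base)
  env <- envelope_lowpass(es, sample_rate,
                          cutoff_hz = config$envelope_cutoff_hz,
                          order = config$envelope_filter_order)
  nz <- normalize_energy(env)
  structure(list(shannon_energy = es,
                 envelope = env,
                 normalized = nz$normalized,
                 mu = nz$mu, sigma = nz$sigma,
                 sample_rate = sample_rate),
            class = "pcg_envelope")
}

#' @export
print.pcg_envelope <- function(x, ...) {
  cat(sprintf("<pcg_envelope> %d samples @ %g Hz (mu = %.4g, sigma = %.4g)\n",
              length(x$normalized), x$sample_rate, x$mu, x$sigma))
  invisible(x)
}
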