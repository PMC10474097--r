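#' Pipeline configuration
#'
#' Collects every tunable constant of the detection and evaluation pipeline.
#' The defaults are the operating point the detector was designed for; see
#' the package vignette for the meaning and provenance of each value.
#'
#' @param pcg_band_hz Band-pass edges for the PCG channel (Hz).
#' @param pcg_filter_order Butterworth prototype order of the PCG band-pass.
#' @param wavelet Mother wavelet used for denoising (Daubechies family,
#'   `"db2"` ... `"db14"`).
#' @param wavelet_level Decomposition depth of the discrete wavelet transform.
#' @param norm_window_s Length of the non-overlapping amplitude-normalization
#'   windows (seconds).
#' @param envelope_cutoff_hz Cut-off of the zero-phase low-pass that smooths
#'   the Shannon energy into an envelope (Hz).
#' @param envelope_filter_order Order of that low-pass.
#' @param min_peak_gap_s Minimum spacing between retained envelope peaks
#'   (seconds); two candidate heart sounds closer than this are merged by
#'   dropping the smaller one.
#' @param period_quantum_s Bin width used when taking the mode of lag-2
#'   inter-peak intervals for the presumed heart period (seconds).
#' @param centroid_fractions Initial K-means centroids for interval
#'   classification, as fractions of the presumed heart period
#'   (systole, diastole, longer).
#' @param confirm_low,confirm_high Interval-ratio factors of the confirmation
#'   rules: same-label gaps shorter than `confirm_low` times the presumed
#'   period demote a peak; gaps longer than `confirm_high` times the period
#'   trigger a recovery search.
#' @param recovery_window_s Length of the recovery search window (seconds),
#'   centred one presumed period after the last confirmed peak.
#' @param shannon_log_base Base of the logarithm in the Shannon energy
#'   (`exp(1)` for natural log); only rescales the energy, so thresholds are
#'   unaffected.
#' @param ecg_band_hz Band-pass edges for the reference ECG (Hz).
#' @param ecg_stop_hz Band-stop edges for mains interference removal (Hz).
#' @param ecg_filter_order Order of both ECG filters.
#' @param r_window_s Length of the adaptive-threshold windows for R-peak
#'   detection (seconds).
#' @param r_threshold_frac Fraction of the per-window maximum that an R
#'   candidate must exceed.
#' @param r_refractory_s Refractory spacing between R peaks (seconds).
#' @param t_search_start_s,t_search_end_frac T-wave search window after each
#'   R peak: from `R + t_search_start_s` to `R + t_search_end_frac *
#'   median(RR)`.
#' @param ecg_invert Flip ECG polarity before detection (for inverted leads).
#' @param s1_window_frac S1 scoring window is `[R, R + s1_window_frac *
#'   median(RR))`.
#' @param s2_window_start_frac,s2_window_end_frac S2 scoring window is
#'   `[R + s2_window_start_frac * median(RT), R + s2_window_end_frac *
#'   median(RR))`.
#' @param hr_window_s Width of the tumbling windows used for heart-rate
#'   series (seconds).
#' @param seed Random seed recorded with the run (the detector itself is
#'   deterministic; the seed feeds the simulator).
#'
#' @return An object of class `pcg_config`: a validated named list.
#' @examples
#' cfg <- pipeline_config()
#' cfg$pcg_band_hz
#' @export
pipeline_config <- function(pcg_band_hz = c(2, 100),
                            pcg_filter_order = 2L,
                            wavelet = "db12",
                            wavelet_level = 5L,
                            norm_window_s = 1,
                            envelope_cutoff_hz = 10,
                            envelope_filter_order = 2L,
                            min_peak_gap_s = 0.15,
                            period_quantum_s = 0.01,
                            centroid_fractions = c(0.35, 0.65, 1.0),
                            confirm_low = 0.8,
                            confirm_high = 1.3,
                            recovery_window_s = 0.3,
                            shannon_log_base = exp(1),
                            ecg_band_hz = c(1, 150),
                            ecg_stop_hz = c(48, 52),
                            ecg_filter_order = 2L,
                            r_window_s = 5,
                            r_threshold_frac = 0.7,
                            r_refractory_s = 0.25,
                            t_search_start_s = 0.12,
                            t_search_end_frac = 0.4,
                            ecg_invert = FALSE,
                            s1_window_frac = 0.2,
                            s2_window_start_frac = 1.2,
                            s2_window_end_frac = 0.6,
                            hr_window_s = 2,
                            seed = 1L) {
  cfg <- list(
    pcg_band_hz = as.numeric(pcg_band_hz),
    pcg_filter_order = as.integer(pcg_filter_order),
    wavelet = as.character(wavelet),
    wavelet_level = as.integer(wavelet_level),
    norm_window_s = as.numeric(norm_window_s),
    envelope_cutoff_hz = as.numeric(envelope_cutoff_hz),
    envelope_filter_order = as.integer(envelope_filter_order),
    min_peak_gap_s = as.numeric(min_peak_gap_s),
    period_quantum_s = as.numeric(period_quantum_s),
    centroid_fractions = as.numeric(centroid_fractions),
    confirm_low = as.numeric(confirm_low),
    confirm_high = as.numeric(confirm_high),
    recovery_window_s = as.numeric(recovery_window_s),
    shannon_log_base = as.numeric(shannon_log_base),
    ecg_band_hz = as.numeric(ecg_band_hz),
    ecg_stop_hz = as.numeric(ecg_stop_hz),
    ecg_filter_order = as.integer(ecg_filter_order),
    r_window_s = as.numeric(r_window_s),
    r_threshold_frac = as.numeric(r_threshold_frac),
    r_refractory_s = as.numeric(r_refractory_s),
    t_search_start_s = as.numeric(t_search_start_s),
    t_search_end_frac = as.numeric(t_search_end_frac),
    ecg_invert = isTRUE(ecg_invert),
    s1_window_frac = as.numeric(s1_window_frac),
    s2_window_start_frac = as.numeric(s2_window_start_frac),
    s2_window_end_frac = as.numeric(s2_window_end_frac),
    hr_window_s = as.numeric(hr_window_s),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "pcg_config")
}

validate_config <- function(cfg) {
  stopifnot(
    length(cfg$pcg_band_hz) == 2L, cfg$pcg_band_hz[1] > 0,
    cfg$pcg_band_hz[1] < cfg$pcg_band_hz[2],
    cfg$pcg_filter_order >= 1L,
    cfg$wavelet %in% names(.daubechies_filters),
    cfg$wavelet_level >= 1L,
    cfg$norm_window_s > 0,
    cfg$envelope_cutoff_hz > 0,
    cfg$min_peak_gap_s > 0,
    cfg$period_quantum_s > 0,
    length(cfg$centroid_fractions) == 3L,
    all(diff(cfg$centroid_fractions) > 0),
    cfg$confirm_low > 0, cfg$confirm_high > cfg$confirm_low,
    cfg$recovery_window_s > 0,
    cfg$shannon_log_base > 1,
    length(cfg$ecg_band_hz) == 2L, length(cfg$ecg_stop_hz) == 2L,
    cfg$r_window_s > 0, cfg$r_threshold_frac > 0, cfg$r_threshold_frac < 1,
    cfg$r_refractory_s > 0,
    cfg$s1_window_frac > 0, cfg$s2_window_end_frac > cfg$s1_window_frac,
    cfg$hr_window_s > 0
  )
  invisible(cfg)
}

#' Read a pipeline configuration from a flat key-value file
#'
#' The file format is TOML-like: one `key = value` pair per line, `#`
#' comments, vectors as comma-separated values.  Every key is optional and
#' defaults to the value in [pipeline_config()].  Logical values are
#' `true`/`false`; strings may be quoted.
#'
#' @param path Path to the configuration file.
#' @return A `pcg_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("pcgbeat_io_error: config file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  defaults <- formals(pipeline_config)
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("pcgbeat_io_error: malformed config line: ", ln, call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(defaults)) {
      stop("pcgbeat_io_error: unknown config key: ", key, call. = FALSE)
    }
    args[[key]] <- parse_config_value(val)
  }
  do.call(pipeline_config, args)
}

parse_config_value <- function(val) {
  val <- gsub('^"|"$', "", val)
  if (tolower(val) %in% c("true", "false")) {
    return(tolower(val) == "true")
  }
  parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
  nums <- suppressWarnings(as.numeric(parts))
  if (!anyNA(nums)) nums else val
}

#' @export
print.pcg_config <- function(x, ...) {
  cat("<pcg_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-22s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  }
  invisible(x)
}
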