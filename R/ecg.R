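#' Detect R peaks with an adaptive per-window threshold
#'
#' The filtered ECG is cut into consecutive windows (default 5 s); within
#' each window, local maxima exceeding a fixed fraction (default 70%) of the
#' window maximum are R candidates.  Candidate sets from all windows are
#' merged and a refractory rule keeps only the largest candidate within any
#' `refractory_s` span, so one QRS complex is never counted twice.
#'
#' @param filtered_ecg Output of [filter_ecg()].
#' @param sample_rate Sampling rate in Hz.
#' @param window_s Adaptive-threshold window length in seconds.
#' @param frac Fraction of the per-window maximum a candidate must exceed.
#' @param refractory_s Minimum spacing between retained R peaks (seconds).
#' @return Numeric vector of R-peak times in seconds.
#' @export
detect_r_peaks <- function(filtered_ecg, sample_rate, window_s = 5,
                           frac = 0.7, refractory_s = 0.25) {
  x <- as_samples(filtered_ecg)
  n <- length(x)
  if (n < 3L || max(x) == min(x)) return(numeric())
  core <- x[2:(n - 1L)]
  locmax <- which(core > x[1:(n - 2L)] & core > x[3:n]) + 1L
  if (length(locmax) == 0L) return(numeric())
  w <- max(1L, as.integer(round(window_s * sample_rate)))
  win_id <- (locmax - 1L) %/% w
  keep <- logical(length(locmax))
  for (wi in unique(win_id)) {
    s <- wi * w + 1L
    e <- min(s + w - 1L, n)
    thr <- frac * max(x[s:e])
    sel <- win_id == wi
    keep[sel] <- x[locmax[sel]] > thr & thr > 0
  }
  cand <- locmax[keep]
  if (length(cand) == 0L) return(numeric())
  df <- data.frame(time = index_to_time(cand - 1L, sample_rate),
                   amplitude = x[cand])
  df <- enforce_min_spacing(df, refractory_s)
  df$time
}

#' Correct an R-peak train with interval-ratio rules
#'
#' Reuses the heart-sound confirmation machinery with the presumed period
#' replaced by the median R-R interval: an R-R gap shorter than
#' `low_factor` times the median drops the later (falsely detected) peak; a
#' gap longer than `high_factor` times the median opens a recovery window
#' (default 300 ms) centred one median interval after the earlier peak, and
#' the largest local ECG maximum inside it is added as the missed R peak.
#' Scans repeat until stable.
#'
#' @param r_times Detected R-peak times in seconds (at least 3).
#' @param filtered_ecg The filtered ECG the times refer to.
#' @param sample_rate Sampling rate in Hz.
#' @param low_factor,high_factor Gap ratio bounds.
#' @param recovery_window_s Recovery window length in seconds.
#' @return Corrected, strictly increasing R-peak times in seconds.
#' @export
correct_r_peaks <- function(r_times, filtered_ecg, sample_rate,
                            low_factor = 0.8, high_factor = 1.3,
                            recovery_window_s = 0.3) {
  t <- sort(as.numeric(r_times))
  if (length(t) < 3L) {
    stop("pcgbeat_insufficient_peaks: need at least 3 R peaks to correct ",
         "(got ", length(t), ")", call. = FALSE)
  }
  x <- as_samples(filtered_ecg)
  n <- length(x)
  med_rr <- stats::median(diff(t))
  # removal: drop the later peak of any too-close pair, to a fixed point
  repeat {
    gaps <- diff(t)
    v <- which(gaps < low_factor * med_rr)
    if (length(v) == 0L) break
    t <- t[-(v[1] + 1L)]
    if (length(t) < 2L) break
  }
  # recovery: fill long gaps with the local maximum inside the window
  repeat {
    changed <- FALSE
    i <- 1L
    while (i < length(t)) {
      gap <- t[i + 1L] - t[i]
      if (gap > high_factor * med_rr) {
        center <- t[i] + med_rr
        lo <- max(1L, time_to_index(center - recovery_window_s / 2,
                                    sample_rate) + 1L)
        hi <- min(n, time_to_index(center + recovery_window_s / 2,
                                   sample_rate) + 1L)
        if (hi - lo >= 2L) {
          seg <- x[lo:hi]
          rel <- which(seg[2:(length(seg) - 1L)] > seg[1:(length(seg) - 2L)] &
                         seg[2:(length(seg) - 1L)] > seg[3:length(seg)]) + 1L
          if (length(rel)) {
            pick <- rel[which.max(seg[rel])]
            cand <- index_to_time(lo + pick - 2L, sample_rate)
            if (cand - t[i] >= low_factor * med_rr &&
                t[i + 1L] - cand >= low_factor * med_rr) {
              t <- sort(c(t, cand))
              changed <- TRUE
              next
            }
          }
        }
      }
      i <- i + 1L
    }
    if (!changed) break
  }
  t
}

#' Locate T-wave maxima after each R peak
#'
#' For each R peak the T time is the maximum of the filtered ECG inside the
#' search window `(R + start_s, R + end_frac * median(RR)]`, clipped to end
#' before the next R peak.  Beats whose window is empty or truncated off the
#' record yield no T time.
#'
#' @param filtered_ecg Filtered ECG samples.
#' @param r_times R-peak times in seconds (at least 1).
#' @param sample_rate Sampling rate in Hz.
#' @param start_s Search-window start offset after R (seconds).
#' @param end_frac Search-window end as a fraction of the median R-R.
#' @return List with `t_times` (one per R where found, `NA` otherwise) and
#'   `median_rt` (median R-to-T interval in seconds).
#' @export
detect_t_wave_max <- function(filtered_ecg, r_times, sample_rate,
                              start_s = 0.12, end_frac = 0.4) {
  t <- sort(as.numeric(r_times))
  if (length(t) < 1L) {
    stop("pcgbeat_insufficient_peaks: no R peaks", call. = FALSE)
  }
  x <- as_samples(filtered_ecg)
  n <- length(x)
  med_rr <- if (length(t) >= 2L) stats::median(diff(t)) else NA_real_
  end_off <- if (is.finite(med_rr)) end_frac * med_rr else 0.4
  t_times <- rep(NA_real_, length(t))
  for (i in seq_along(t)) {
    lo_t <- t[i] + start_s
    hi_t <- t[i] + end_off
    if (i < length(t)) hi_t <- min(hi_t, t[i + 1L] - 1 / sample_rate)
    lo <- time_to_index(lo_t, sample_rate) + 1L
    hi <- time_to_index(hi_t, sample_rate) + 1L
    if (lo >= hi || hi > n || lo < 1L) next
    seg <- x[lo:hi]
    t_times[i] <- index_to_time(lo + which.max(seg) - 2L, sample_rate)
  }
  ok <- !is.na(t_times)
  list(t_times = t_times,
       median_rt = if (any(ok)) stats::median(t_times[ok] - t[ok]) else NA_real_)
}

#' Annotate the reference ECG channel of a recording
#'
#' Filters the ECG, detects and corrects R peaks, and locates T-wave maxima.
#'
#' @param rec A [recording()] with an ECG channel.
#' @param config A [pipeline_config()].
#' @return Object of class `pcg_ecg_annotations` with `r_times`, `t_times`,
#'   `median_rr`, `median_rt`, `sample_rate`.
#' @export
annotate_ecg <- function(rec, config = pipeline_config()) {
  stopifnot(inherits(rec, "pcg_recording"))
  ch <- ecg_channel(rec)
  fs <- rec$sample_rate
  x <- rec$samples[, ch]
  if (config$ecg_invert) x <- -x
  f <- filter_ecg(x, fs, band_hz = config$ecg_band_hz,
                  stop_hz = config$ecg_stop_hz,
                  order = config$ecg_filter_order)
  r <- detect_r_peaks(f, fs, window_s = config$r_window_s,
                      frac = config$r_threshold_frac,
                      refractory_s = config$r_refractory_s)
  r <- correct_r_peaks(r, f, fs,
                       low_factor = config$confirm_low,
                       high_factor = config$confirm_high,
                       recovery_window_s = config$recovery_window_s)
  tw <- detect_t_wave_max(f, r, fs,
                          start_s = config$t_search_start_s,
                          end_frac = config$t_search_end_frac)
  structure(list(r_times = r, t_times = tw$t_times,
                 median_rr = stats::median(diff(r)),
                 median_rt = tw$median_rt,
                 sample_rate = fs),
            class = "pcg_ecg_annotations")
}

#' @export
print.pcg_ecg_annotations <- function(x, ...) {
  cat(sprintf(paste0("<pcg_ecg_annotations> %d R peaks, median RR %.3f s, ",
                     "median RT %.3f s\n"),
              length(x$r_times), x$median_rr, x$median_rt))
  invisible(x)
}

#' Convert ECG annotations to an annotation track
#'
#' @param ecg_ann A `pcg_ecg_annotations` object.
#' @return An [annotation_track()] with `R` and `T` events.
#' @export
ecg_track <- function(ecg_ann) {
  tt <- ecg_ann$t_times[!is.na(ecg_ann$t_times)]
  df <- rbind(data.frame(time = ecg_ann$r_times, label = "R"),
              if (length(tt)) data.frame(time = tt, label = "T"))
  df <- df[order(df$time), , drop = FALSE]
  annotation_track(df$time, df$label)
}
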