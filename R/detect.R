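#' Detection thresholds from envelope statistics
#'
#' The candidate threshold is `Th1 = -0.9 * mu / sigma`: on the standardized
#' envelope scale this sits 90% of the way from the envelope mean down
#' toward the shifted origin, low enough to admit weak heart sounds (and
#' noise — later rules sort those out).  The classification threshold `Th2`
#' is the envelope mean, expressed on the same standardized scale as the
#' peak amplitudes, i.e. `(mean_energy - mu) / sigma`; when `mean_energy` is
#' the same global mean used for standardization, `Th2 = 0`.
#'
#' @param mu,sigma Mean and standard deviation of the smoothed envelope
#'   (from [normalize_energy()]); `sigma` must be positive.
#' @param mean_energy Mean energy defining `Th2`; defaults to `mu`.
#' @return List with `th1` and `th2` (standardized-envelope units).
#' @examples
#' compute_thresholds(0.2, 0.5)  # th1 = -0.36, th2 = 0
#' @export
compute_thresholds <- function(mu, sigma, mean_energy = mu) {
  if (!is.finite(sigma) || sigma <= 0) {
    stop("pcgbeat_constant_signal: sigma must be positive", call. = FALSE)
  }
  list(th1 = -0.9 * mu / sigma,
       th2 = (mean_energy - mu) / sigma)
}

#' Candidate envelope peaks above the detection threshold
#'
#' Finds every strict local maximum of the standardized envelope whose
#' amplitude exceeds `th1`, in time order.
#'
#' @param normalized_envelope Standardized envelope (from
#'   [normalize_energy()] / [pcg_envelope()]).
#' @param sample_rate Sampling rate in Hz.
#' @param th1 Detection threshold on the standardized scale.
#' @return Data frame with columns `time` (s), `amplitude`, `above_th2`
#'   (logical, filled by the caller; `NA` here).
#' @export
detect_candidate_peaks <- function(normalized_envelope, sample_rate, th1) {
  x <- as_samples(normalized_envelope)
  n <- length(x)
  if (n < 3L) {
    return(data.frame(time = numeric(), amplitude = numeric(),
                      above_th2 = logical()))
  }
  core <- x[2:(n - 1L)]
  is_peak <- core > x[1:(n - 2L)] & core > x[3:n] & core > th1
  idx <- which(is_peak) + 1L
  data.frame(time = index_to_time(idx - 1L, sample_rate),
             amplitude = x[idx],
             above_th2 = rep(NA, length(idx)))
}

#' Enforce a minimum spacing between candidate peaks
#'
#' Heart sounds last on the order of 150 ms, so two candidate peaks closer
#' than `min_gap_s` cannot both be true sounds; the lower-amplitude member
#' of the closest violating pair is removed, repeatedly, until no violation
#' remains.  Resolving the closest pair first makes the outcome
#' deterministic; an amplitude tie removes the later peak.
#'
#' @param peaks Data frame from [detect_candidate_peaks()] (time-ordered).
#' @param min_gap_s Minimum allowed spacing in seconds.
#' @return The surviving subset of `peaks`, still time-ordered.
#' @export
enforce_min_spacing <- function(peaks, min_gap_s = 0.15) {
  if (nrow(peaks) < 2L) return(peaks)
  keep <- rep(TRUE, nrow(peaks))
  t <- peaks$time
  a <- peaks$amplitude
  repeat {
    idx <- which(keep)
    if (length(idx) < 2L) break
    gaps <- diff(t[idx])
    bad <- which(gaps < min_gap_s)
    if (length(bad) == 0L) break
    j <- bad[which.min(gaps[bad])]          # closest violating pair, earliest on ties
    p1 <- idx[j]; p2 <- idx[j + 1L]
    drop <- if (a[p1] < a[p2]) p1 else p2   # amplitude tie -> drop the later
    keep[drop] <- FALSE
  }
  peaks[keep, , drop = FALSE]
}

#' Presumed heart period from lag-2 inter-peak intervals
#'
#' When S1 and S2 alternate, the interval between every other peak equals
#' the beat period.  Intervals among the odd-indexed peaks and among the
#' even-indexed peaks are pooled, quantized to `quantum_s`, and their mode
#' is returned (ties resolve to the smallest value).  The mode is robust to
#' the occasional extra or missed peak, which contributes off-mode
#' intervals.
#'
#' @param above_th2_times Times (s) of the peaks above `Th2`, sorted.
#' @param quantum_s Quantization bin width in seconds.
#' @return The presumed heart period in seconds.
#' @export
presumed_heart_period <- function(above_th2_times, quantum_s = 0.01) {
  t <- as.numeric(above_th2_times)
  if (length(t) < 3L) {
    stop("pcgbeat_insufficient_peaks: need at least 3 peaks above Th2 to ",
         "estimate the heart period (got ", length(t), ")", call. = FALSE)
  }
  gaps <- diff(t, lag = 2L)   # odd-odd and even-even intervals, interleaved
  bins <- round(gaps / quantum_s)
  tab <- table(bins)
  best <- as.numeric(names(tab)[tab == max(tab)])
  min(best) * quantum_s
}

#' Classify inter-peak intervals by 1-D K-means
#'
#' Lloyd's algorithm on the interval durations with `k = 3` clusters seeded
#' at fixed fractions of the presumed heart period (defaults 0.35, 0.65 and
#' 1.0 — the approximate systole/diastole split of a resting beat and the
#' full period).  Iterates assignment/update to a fixed point; distance ties
#' go to the lower-indexed centroid and a cluster that empties keeps its
#' centroid for that iteration.
#'
#' @param intervals Consecutive inter-peak gaps in seconds (non-empty).
#' @param presumed_period Presumed heart period in seconds (positive).
#' @param centroid_fractions Initial centroids as fractions of
#'   `presumed_period`.
#' @return List of class `pcg_intervals` with `intervals`, `labels`
#'   (`"systole"`, `"diastole"`, `"longer"`), `centroids` (final, ordered
#'   systole < diastole < longer), `assignments` (1--3), and
#'   `presumed_period`.
#' @export
classify_intervals_kmeans <- function(intervals, presumed_period,
                                      centroid_fractions = c(0.35, 0.65, 1.0)) {
  x <- as.numeric(intervals)
  if (length(x) == 0L) {
    stop("pcgbeat_insufficient_peaks: no intervals to classify", call. = FALSE)
  }
  if (!is.finite(presumed_period) || presumed_period <= 0) {
    stop("pcgbeat_invalid_period: presumed_period must be positive",
         call. = FALSE)
  }
  centers <- centroid_fractions * presumed_period
  assign_nearest <- function(x, centers) {
    d <- abs(outer(x, centers, "-"))
    max.col(-d, ties.method = "first")
  }
  cl <- assign_nearest(x, centers)
  for (iter in seq_len(100L)) {
    new_centers <- centers
    for (k in 1:3) {
      if (any(cl == k)) new_centers[k] <- mean(x[cl == k])
    }
    new_cl <- assign_nearest(x, new_centers)
    centers <- new_centers
    if (identical(new_cl, cl)) { cl <- new_cl; break }
    cl <- new_cl
  }
  ord <- order(centers)
  remap <- match(seq_len(3L), ord)   # old cluster id -> rank
  cl <- remap[cl]
  centers <- centers[ord]
  lab <- c("systole", "diastole", "longer")[cl]
  structure(list(intervals = x, labels = lab, centroids = centers,
                 assignments = cl, presumed_period = presumed_period),
            class = "pcg_intervals")
}

#' Provisional S1/S2 labels from classified intervals
#'
#' The peak opening a systole interval is S1 (the sound at the start of
#' systole); the peak opening a diastole interval is S2.  Peaks before
#' "longer" intervals, the final above-`Th2` peak, and every peak below
#' `Th2` stay unclassified — they remain available to the confirmation
#' rules.
#'
#' @param above_th2_peaks Data frame (`time`, `amplitude`) of peaks above
#'   `Th2`, whose consecutive gaps are `classification$intervals`.
#' @param classification A [classify_intervals_kmeans()] result.
#' @param all_peaks Data frame of all retained candidate peaks (superset of
#'   `above_th2_peaks`).
#' @return A provisional `pcg_heart_sounds` object: `s1`, `s2`,
#'   `unclassified` (each a data frame `time`/`amplitude`),
#'   `presumed_period`, and zeroed `removed`/`recovered` counters.
#' @export
assign_labels <- function(above_th2_peaks, classification, all_peaks) {
  m <- nrow(above_th2_peaks)
  stopifnot(length(classification$labels) == max(m - 1L, 0L))
  lab <- rep("U", m)
  if (m >= 2L) {
    lab[seq_len(m - 1L)] <- c(systole = "S1", diastole = "S2",
                              longer = "U")[classification$labels]
  }
  below <- all_peaks[!all_peaks$time %in% above_th2_peaks$time, , drop = FALSE]
  sel <- function(which_lab) {
    df <- above_th2_peaks[lab == which_lab, c("time", "amplitude"),
                          drop = FALSE]
    rownames(df) <- NULL
    df
  }
  uncl <- rbind(sel("U"), below[, c("time", "amplitude"), drop = FALSE])
  uncl <- uncl[order(uncl$time), , drop = FALSE]
  rownames(uncl) <- NULL
  structure(list(s1 = sel("S1"), s2 = sel("S2"), unclassified = uncl,
                 presumed_period = classification$presumed_period,
                 removed = 0L, recovered = 0L),
            class = "pcg_heart_sounds")
}

#' @export
print.pcg_heart_sounds <- function(x, ...) {
  cat(sprintf(paste0("<pcg_heart_sounds> %d S1, %d S2, %d unclassified ",
                     "(presumed period %.3f s; %d removed, %d recovered)\n"),
              nrow(x$s1), nrow(x$s2), nrow(x$unclassified),
              x$presumed_period, x$removed, x$recovered))
  invisible(x)
}

#' Confirmation rules: demote implausible peaks, recover missed ones
#'
#' Within each label sequence (S1 and S2 independently): (a) a same-label
#' gap shorter than `low_factor` times the presumed period means the second
#' peak cannot be a true beat — it is demoted to unclassified; (b) a gap
#' longer than `high_factor` times the period suggests a missed beat — a
#' window of `recovery_window_s` is centred one period after the earlier
#' peak and, if unclassified peaks fall inside, the one closest to the
#' window centre is promoted to the label (an exact distance tie promotes
#' the earlier peak).  Demotion runs to a fixed point first, then recovery
#' passes repeat until stable.  A promotion is skipped if it would itself
#' create a same-label gap shorter than `low_factor` times the period, so
#' the demotion invariant is never violated.
#'
#' @param annotations Provisional [assign_labels()] output.
#' @param presumed_period Presumed heart period in seconds (defaults to the
#'   one stored in `annotations`).
#' @param low_factor,high_factor Gap ratio bounds.
#' @param recovery_window_s Recovery window length in seconds.
#' @return A confirmed `pcg_heart_sounds` object with updated
#'   `removed`/`recovered` counters.
#' @export
confirm_peaks <- function(annotations,
                          presumed_period = annotations$presumed_period,
                          low_factor = 0.8, high_factor = 1.3,
                          recovery_window_s = 0.3) {
  Tp <- presumed_period
  ann <- annotations
  demote_pass <- function(lab_df, uncl) {
    removed <- 0L
    repeat {
      if (nrow(lab_df) < 2L) break
      gaps <- diff(lab_df$time)
      v <- which(gaps < low_factor * Tp)
      if (length(v) == 0L) break
      v <- v[1]
      uncl <- rbind(uncl, lab_df[v + 1L, , drop = FALSE])
      lab_df <- lab_df[-(v + 1L), , drop = FALSE]
      removed <- removed + 1L
    }
    uncl <- uncl[order(uncl$time), , drop = FALSE]
    rownames(uncl) <- rownames(lab_df) <- NULL
    list(lab = lab_df, uncl = uncl, removed = removed)
  }
  recover_pass <- function(lab_df, uncl) {
    recovered <- 0L
    repeat {
      changed <- FALSE
      i <- 1L
      while (i < nrow(lab_df)) {
        gap <- lab_df$time[i + 1L] - lab_df$time[i]
        if (gap > high_factor * Tp && nrow(uncl) > 0L) {
          center <- lab_df$time[i] + Tp
          lo <- center - recovery_window_s / 2
          hi <- center + recovery_window_s / 2
          inside <- which(uncl$time >= lo & uncl$time <= hi)
          if (length(inside)) {
            d <- abs(uncl$time[inside] - center)
            pick <- inside[order(d, uncl$time[inside])][1]
            cand <- uncl$time[pick]
            # promotion must not create a too-short same-label gap
            if (cand - lab_df$time[i] >= low_factor * Tp &&
                lab_df$time[i + 1L] - cand >= low_factor * Tp) {
              lab_df <- rbind(lab_df, uncl[pick, , drop = FALSE])
              lab_df <- lab_df[order(lab_df$time), , drop = FALSE]
              uncl <- uncl[-pick, , drop = FALSE]
              recovered <- recovered + 1L
              changed <- TRUE
              next  # re-examine the split gap from the same i
            }
          }
        }
        i <- i + 1L
      }
      if (!changed) break
    }
    rownames(uncl) <- rownames(lab_df) <- NULL
    list(lab = lab_df, uncl = uncl, recovered = recovered)
  }
  for (lab in c("s1", "s2")) {
    st <- demote_pass(ann[[lab]], ann$unclassified)
    ann[[lab]] <- st$lab
    ann$unclassified <- st$uncl
    ann$removed <- ann$removed + st$removed
  }
  for (lab in c("s1", "s2")) {
    st <- recover_pass(ann[[lab]], ann$unclassified)
    ann[[lab]] <- st$lab
    ann$unclassified <- st$uncl
    ann$recovered <- ann$recovered + st$recovered
  }
  ann$presumed_period <- Tp
  ann
}

#' Detect heart sounds in one PCG channel
#'
#' Runs the full direct-segmentation chain: band-pass, wavelet denoise,
#' window normalization, Shannon-energy envelope, dual-threshold peak
#' picking, minimum-spacing pruning, presumed-period estimation, K-means
#' interval classification, provisional labelling and confirmation.  The
#' result is deterministic for a fixed input and configuration.
#'
#' @param rec A [recording()].
#' @param channel Channel index (must be a PCG channel); defaults to the
#'   first PCG channel.
#' @param config A [pipeline_config()].
#' @param keep_stages If `TRUE`, attach the intermediate signals (band-pass,
#'   denoised, normalized, energy, envelope, standardized envelope) for
#'   inspection.
#' @return A `pcg_heart_sounds` object; also carries `thresholds`,
#'   `sample_rate`, `channel`, and (optionally) `stages`.
#' @export
detect_heart_sounds <- function(rec, channel = NULL,
                                config = pipeline_config(),
                                keep_stages = FALSE) {
  stopifnot(inherits(rec, "pcg_recording"))
  if (is.null(channel)) {
    ch <- pcg_channels(rec)
    if (length(ch) == 0L) {
      stop("pcgbeat_invalid_recording: no PCG channel", call. = FALSE)
    }
    channel <- ch[1]
  }
  if (rec$channel_roles[channel] != "pcg") {
    stop("pcgbeat_invalid_recording: channel ", channel,
         " is not a PCG channel", call. = FALSE)
  }
  if (rec$duration < 3) {
    stop("pcgbeat_insufficient_data: recording shorter than 3 s (",
         format(rec$duration), " s)", call. = FALSE)
  }
  fs <- rec$sample_rate
  x <- rec$samples[, channel]
  pre <- preprocess_pcg(x, fs, config)
  env <- pcg_envelope(pre, fs, config)
  th <- compute_thresholds(env$mu, env$sigma)
  peaks <- detect_candidate_peaks(env$normalized, fs, th$th1)
  peaks <- enforce_min_spacing(peaks, config$min_peak_gap_s)
  peaks$above_th2 <- peaks$amplitude > th$th2
  above <- peaks[peaks$above_th2, , drop = FALSE]
  if (nrow(above) < 3L) {
    stop("pcgbeat_insufficient_peaks: only ", nrow(above),
         " peaks above Th2; cannot estimate the heart period", call. = FALSE)
  }
  Tp <- presumed_heart_period(above$time, config$period_quantum_s)
  cls <- classify_intervals_kmeans(diff(above$time), Tp,
                                   config$centroid_fractions)
  ann <- assign_labels(above, cls, peaks)
  ann <- confirm_peaks(ann, Tp,
                       low_factor = config$confirm_low,
                       high_factor = config$confirm_high,
                       recovery_window_s = config$recovery_window_s)
  ann$thresholds <- th
  ann$sample_rate <- fs
  ann$channel <- channel
  ann$classification <- cls
  if (keep_stages) {
    ann$stages <- list(
      bandpassed = NULL,  # re-run cheaply when requested
      normalized = pre$samples,
      shannon_energy = env$shannon_energy,
      envelope = env$envelope,
      normalized_envelope = env$normalized
    )
    bp <- bandpass_pcg(x, fs, config$pcg_band_hz[1], config$pcg_band_hz[2],
                       config$pcg_filter_order)
    ann$stages$bandpassed <- bp$samples
    ann$stages$denoised <- wavelet_denoise(bp, config$wavelet,
                                           config$wavelet_level)$samples
  }
  ann
}

#' Convert detected heart sounds to an annotation track
#'
#' @param hs A `pcg_heart_sounds` object.
#' @param include_unclassified Include unclassified peaks as `U` events.
#' @return An [annotation_track()].
#' @export
heart_sounds_track <- function(hs, include_unclassified = TRUE) {
  df <- rbind(
    data.frame(time = hs$s1$time, label = "S1", amp = hs$s1$amplitude),
    data.frame(time = hs$s2$time, label = "S2", amp = hs$s2$amplitude),
    if (include_unclassified && nrow(hs$unclassified)) {
      data.frame(time = hs$unclassified$time, label = "U",
                 amp = hs$unclassified$amplitude)
    }
  )
  df <- df[order(df$time), , drop = FALSE]
  annotation_track(df$time, df$label, df$amp)
}
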