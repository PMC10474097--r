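#' Per-beat scoring windows anchored on the reference ECG
#'
#' For each R peak an S1 window `[R, R + 0.2 * median(RR))` and an S2 window
#' `[R + 1.2 * median(RT), R + 0.6 * median(RR))` are built (half-open).
#' The window lengths scale with heart rate through the medians.  If the S2
#' start formula reaches past its end the S2 window is empty and flagged;
#' if an S2 window would overlap its beat's S1 window, the S1 window takes
#' precedence and the S2 start is clipped (overlaps are counted in
#' `n_clipped`).
#'
#' @param ecg_ann A [annotate_ecg()] result (needs `median_rr`; S2 windows
#'   additionally need `median_rt`).
#' @param s1_frac,s2_start_frac,s2_end_frac Window factors.
#' @return Object of class `pcg_windows`: data frames `s1` and `s2` with
#'   columns `start`, `end` (seconds) plus `n_clipped`.
#' @export
build_windows <- function(ecg_ann, s1_frac = 0.2, s2_start_frac = 1.2,
                          s2_end_frac = 0.6) {
  r <- ecg_ann$r_times
  if (length(r) == 0L || !is.finite(ecg_ann$median_rr)) {
    stop("pcgbeat_missing_reference: no usable R annotations", call. = FALSE)
  }
  rr <- ecg_ann$median_rr
  s1 <- data.frame(start = r, end = r + s1_frac * rr)
  n_clipped <- 0L
  if (is.finite(ecg_ann$median_rt)) {
    start2 <- r + s2_start_frac * ecg_ann$median_rt
    end2 <- r + s2_end_frac * rr
    clip <- start2 < s1$end
    n_clipped <- sum(clip)
    start2[clip] <- s1$end[clip]
    s2 <- data.frame(start = start2, end = end2)
    s2$empty <- s2$start >= s2$end
  } else {
    s2 <- NULL
  }
  structure(list(s1 = s1, s2 = s2, n_clipped = n_clipped,
                 median_rr = rr, median_rt = ecg_ann$median_rt),
            class = "pcg_windows")
}

#' Score detections against per-beat windows
#'
#' A detection inside a window is a true positive, but each window credits
#' at most one: further detections inside an already-hit window count as
#' false positives (this keeps sensitivity at or below 100%).  Detections in
#' no window are false positives; windows containing no detection are false
#' negatives.  `SE = 100 * TP / (TP + FN)` and `PPV = 100 * TP / (TP + FP)`;
#' an undefined ratio (empty denominator) is reported as `NA`, never 0.
#'
#' @param detected_times Detection times in seconds.
#' @param windows Data frame with `start`/`end` columns (half-open
#'   `[start, end)`), non-overlapping and time-ordered; rows with
#'   `empty = TRUE` are ignored.
#' @return List of class `pcg_metrics`: `tp`, `fp`, `fn`, `se`, `ppv`.
#' @export
score_detection <- function(detected_times, windows) {
  w <- windows
  if (!is.null(w$empty)) w <- w[!w$empty, , drop = FALSE]
  nw <- nrow(w)
  if (nw > 1L) {
    if (any(w$start[-1L] < w$end[-nw])) {
      stop("pcgbeat_invalid_windows: scoring windows overlap", call. = FALSE)
    }
  }
  d <- sort(as.numeric(detected_times))
  hit <- integer(nw)   # detections credited per window
  fp <- 0L
  for (x in d) {
    j <- which(w$start <= x & x < w$end)
    if (length(j) == 0L) {
      fp <- fp + 1L
    } else if (hit[j[1]] == 0L) {
      hit[j[1]] <- 1L
    } else {
      fp <- fp + 1L
    }
  }
  tp <- sum(hit)
  fn <- nw - tp
  se <- if (tp + fn > 0L) 100 * tp / (tp + fn) else NA_real_
  ppv <- if (tp + fp > 0L) 100 * tp / (tp + fp) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, se = se, ppv = ppv),
            class = "pcg_metrics")
}

#' @export
print.pcg_metrics <- function(x, ...) {
  cat(sprintf("<pcg_metrics> TP %d, FP %d, FN %d | SE %.1f%%, PPV %.1f%%\n",
              x$tp, x$fp, x$fn, x$se, x$ppv))
  invisible(x)
}

#' Five-number summary with interquartile range
#'
#' Quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7); `iqr = q3 - q1`.
#'
#' @param values Non-empty numeric vector (e.g. per-record SE values in %).
#' @return List with `min`, `q1`, `median`, `q3`, `max`, `iqr`.
#' @export
summarize_metrics <- function(values) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(v) == 0L) {
    stop("pcgbeat_empty_input: no values to summarize", call. = FALSE)
  }
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(min = min(v), q1 = q[1], median = q[2], q3 = q[3], max = max(v),
       iqr = q[3] - q[1])
}

#' Heart-rate series from event times
#'
#' Heart rate is computed per tumbling window (default 2 s) as `60 /
#' median(gaps)`, where the gaps are the consecutive inter-event intervals
#' whose midpoints fall inside the window.  Windows containing no gap
#' midpoint are `NA` (undefined), never zero-filled.
#'
#' @param event_times Event times (s), e.g. detected S1 times or R peaks.
#' @param duration Record duration in seconds.
#' @param window_s Window width in seconds.
#' @return Data frame with `window_start` (s) and `hr_bpm`.
#' @export
heart_rate_series <- function(event_times, duration, window_s = 2) {
  if (window_s <= 0) {
    stop("pcgbeat_invalid_filter: window_s must be positive", call. = FALSE)
  }
  t <- sort(as.numeric(event_times))
  starts <- seq(0, duration, by = window_s)
  starts <- starts[starts < duration]
  hr <- rep(NA_real_, length(starts))
  if (length(t) >= 2L) {
    gaps <- diff(t)
    mid <- (t[-length(t)] + t[-1L]) / 2
    bin <- findInterval(mid, starts)
    for (i in seq_along(starts)) {
      g <- gaps[bin == i]
      if (length(g)) hr[i] <- 60 / stats::median(g)
    }
  }
  data.frame(window_start = starts, hr_bpm = hr)
}

#' Paired Wilcoxon comparison of two heart-rate series
#'
#' Wilcoxon signed-rank test on the per-window pairs where both series are
#' defined.  Zero differences are discarded (classic convention); if all
#' differences are zero the series are indistinguishable and `p = 1` is
#' returned.  The exact null distribution is used for up to 25 non-zero
#' pairs (falling back to the normal approximation when ties make the exact
#' test unavailable), the normal approximation with continuity correction
#' above that.
#'
#' @param hr_a,hr_b Data frames from [heart_rate_series()] on a common
#'   window grid.
#' @param alpha Significance threshold reported alongside.
#' @return List with `statistic`, `p_value`, `n_pairs` (windows defined in
#'   both), `n_nonzero`, `significant`, `alpha`.
#' @export
compare_hr_paired <- function(hr_a, hr_b, alpha = 0.05) {
  if (nrow(hr_a) != nrow(hr_b)) {
    stop("pcgbeat_invalid_windows: series are on different window grids",
         call. = FALSE)
  }
  ok <- is.finite(hr_a$hr_bpm) & is.finite(hr_b$hr_bpm)
  n_pairs <- sum(ok)
  if (n_pairs < 6L) {
    stop("pcgbeat_insufficient_pairs: need at least 6 shared windows (got ",
         n_pairs, ")", call. = FALSE)
  }
  d <- hr_a$hr_bpm[ok] - hr_b$hr_bpm[ok]
  dz <- d[d != 0]
  if (length(dz) == 0L) {
    res <- list(statistic = NA_real_, p_value = 1, n_pairs = n_pairs,
                n_nonzero = 0L, significant = FALSE, alpha = alpha)
    return(res)
  }
  exact <- length(dz) <= 25L
  wt <- suppressWarnings(
    stats::wilcox.test(dz, exact = exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_pairs = n_pairs, n_nonzero = length(dz),
       significant = wt$p.value < alpha, alpha = alpha)
}

#' Evaluate heart-sound detection on a whole recording
#'
#' Runs the detector on every requested PCG channel, annotates the
#' reference ECG, builds per-beat scoring windows, scores S1 and S2
#' detections, computes heart-rate series (S1-, S2- and R-based) and the
#' paired Wilcoxon comparison of each PCG-derived series against the ECG
#' reference.
#'
#' @param rec A [recording()] with at least one PCG and one ECG channel.
#' @param pcg_channels Channel indices to evaluate (default: all PCG
#'   channels).
#' @param config A [pipeline_config()].
#' @return Object of class `pcg_evaluation`: `metrics` (one row per channel
#'   x label: `channel`, `name`, `label`, `tp`, `fp`, `fn`, `se`, `ppv`),
#'   `hr_tests` (channel x label Wilcoxon results), `hr` (list of HR series),
#'   `ecg` (the ECG annotations), `windows`, and `detections`.
#' @export
evaluate_record <- function(rec, pcg_channels = NULL,
                            config = pipeline_config()) {
  stopifnot(inherits(rec, "pcg_recording"))
  chans <- pcg_channels %||% which(rec$channel_roles == "pcg")
  if (length(chans) == 0L) {
    stop("pcgbeat_invalid_recording: no PCG channels to evaluate",
         call. = FALSE)
  }
  ecg_ann <- annotate_ecg(rec, config)
  win <- build_windows(ecg_ann,
                       s1_frac = config$s1_window_frac,
                       s2_start_frac = config$s2_window_start_frac,
                       s2_end_frac = config$s2_window_end_frac)
  hr_r <- heart_rate_series(ecg_ann$r_times, rec$duration, config$hr_window_s)
  metrics <- list()
  hr_tests <- list()
  hr_series <- list(R = hr_r)
  detections <- list()
  for (ch in chans) {
    hs <- detect_heart_sounds(rec, channel = ch, config = config)
    detections[[as.character(ch)]] <- hs
    nm <- rec$channel_names[ch]
    for (lab in c("S1", "S2")) {
      d <- if (lab == "S1") hs$s1$time else hs$s2$time
      w <- if (lab == "S1") win$s1 else win$s2
      if (is.null(w)) next
      m <- score_detection(d, w)
      metrics[[length(metrics) + 1L]] <-
        data.frame(channel = ch, name = nm, label = lab, tp = m$tp,
                   fp = m$fp, fn = m$fn, se = m$se, ppv = m$ppv)
      hr_d <- heart_rate_series(d, rec$duration, config$hr_window_s)
      hr_series[[paste0(lab, "_ch", ch)]] <- hr_d
      test <- tryCatch(compare_hr_paired(hr_d, hr_r),
                       error = function(e) NULL)
      if (!is.null(test)) {
        hr_tests[[length(hr_tests) + 1L]] <-
          data.frame(channel = ch, name = nm, label = lab,
                     statistic = test$statistic %||% NA_real_,
                     p_value = test$p_value, n_pairs = test$n_pairs,
                     significant = test$significant)
      }
    }
  }
  structure(list(metrics = do.call(rbind, metrics),
                 hr_tests = if (length(hr_tests)) do.call(rbind, hr_tests),
                 hr = hr_series,
                 ecg = ecg_ann,
                 windows = win,
                 detections = detections),
            class = "pcg_evaluation")
}

#' @export
print.pcg_evaluation <- function(x, ...) {
  cat("<pcg_evaluation>\n")
  print(x$metrics, row.names = FALSE, digits = 4)
  if (!is.null(x$hr_tests)) {
    cat("HR comparison vs ECG (paired Wilcoxon):\n")
    print(x$hr_tests, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
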