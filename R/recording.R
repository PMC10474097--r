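#' Construct a multichannel recording
#'
#' A recording is a uniformly sampled multichannel waveform with a sampling
#' rate and a role (`"pcg"` or `"ecg"`) per channel.  All channels must have
#' equal length.
#'
#' @param samples Numeric matrix, one column per channel (a vector is treated
#'   as a single channel).
#' @param sample_rate Sampling rate in Hz.
#' @param channel_roles Character vector, one of `"pcg"`, `"ecg"` per channel.
#' @param channel_names Optional channel names (e.g. `"P3"`); defaults to
#'   `ch1`, `ch2`, ...
#' @return An object of class `pcg_recording` with fields `samples`
#'   (matrix), `sample_rate`, `channel_roles`, `channel_names` and derived
#'   `duration` (seconds).
#' @examples
#' rec <- recording(matrix(rnorm(512), ncol = 2), 256, c("ecg", "pcg"))
#' rec$duration
#' @export
recording <- function(samples, sample_rate,
                      channel_roles = rep("pcg", NCOL(samples)),
                      channel_names = NULL) {
  if (is.vector(samples)) samples <- matrix(as.numeric(samples), ncol = 1L)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  nch <- ncol(samples)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nch))
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("pcgbeat_invalid_recording: sample_rate must be a positive scalar",
         call. = FALSE)
  }
  channel_roles <- as.character(channel_roles)
  if (length(channel_roles) != nch || length(channel_names) != nch) {
    stop("pcgbeat_invalid_recording: channel_roles/channel_names length must ",
         "match the number of channels", call. = FALSE)
  }
  if (!all(channel_roles %in% c("pcg", "ecg"))) {
    stop("pcgbeat_invalid_recording: channel roles must be 'pcg' or 'ecg'",
         call. = FALSE)
  }
  structure(
    list(samples = samples,
         sample_rate = as.numeric(sample_rate),
         channel_roles = channel_roles,
         channel_names = as.character(channel_names),
         duration = nrow(samples) / sample_rate),
    class = "pcg_recording"
  )
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording> %d channel(s), %.3f s @ %g Hz\n",
              ncol(x$samples), x$duration, x$sample_rate))
  cat(sprintf("  %s\n", paste(sprintf("%s[%s]", x$channel_names,
                                      x$channel_roles), collapse = " ")))
  invisible(x)
}

pcg_channels <- function(rec) which(rec$channel_roles == "pcg")
ecg_channel <- function(rec) {
  idx <- which(rec$channel_roles == "ecg")
  if (length(idx) == 0L) {
    stop("pcgbeat_missing_reference: recording has no ECG channel",
         call. = FALSE)
  }
  idx[1]
}

#' Construct an annotation track
#'
#' Time-stamped, labelled events: detected or ground-truth heart sounds
#' (`S1`, `S2`, unclassified `U`) or ECG landmarks (`R`, `T`).
#'
#' @param times Event times in seconds from record start, strictly increasing.
#' @param labels Character labels drawn from `S1`, `S2`, `U`, `R`, `T`.
#' @param amplitudes Optional amplitude (envelope or ECG units) per event.
#' @return Object of class `pcg_annotations` (a validated data-frame-like
#'   list).
#' @export
annotation_track <- function(times, labels, amplitudes = rep(NA_real_, length(times))) {
  times <- as.numeric(times)
  labels <- as.character(labels)
  amplitudes <- as.numeric(amplitudes)
  if (length(labels) != length(times) || length(amplitudes) != length(times)) {
    stop("pcgbeat_invalid_annotations: fields must have equal length",
         call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("pcgbeat_invalid_annotations: times must be strictly increasing",
         call. = FALSE)
  }
  if (length(times) && any(times < 0)) {
    stop("pcgbeat_invalid_annotations: negative event time", call. = FALSE)
  }
  ok <- labels %in% c("S1", "S2", "U", "R", "T")
  if (!all(ok)) {
    stop("pcgbeat_invalid_annotations: unknown label(s): ",
         paste(unique(labels[!ok]), collapse = ", "), call. = FALSE)
  }
  structure(list(times = times, labels = labels, amplitudes = amplitudes),
            class = "pcg_annotations")
}

#' @export
print.pcg_annotations <- function(x, ...) {
  cat(sprintf("<pcg_annotations> %d event(s)\n", length(x$times)))
  if (length(x$times)) {
    print(table(x$labels))
  }
  invisible(x)
}

#' @export
as.data.frame.pcg_annotations <- function(x, ...) {
  data.frame(time_s = x$times, label = x$labels, amplitude = x$amplitudes,
             stringsAsFactors = FALSE)
}

# Seconds -> 0-based sample index (round to nearest); single convention used
# package-wide so no module drifts by one sample.
time_to_index <- function(t, fs) as.integer(round(t * fs))
index_to_time <- function(i, fs) i / fs
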