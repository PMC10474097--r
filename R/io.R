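#' Read a recording from disk
#'
#' Supported formats: `wav` (RIFF PCM16 or float32), `csv` (comma separated,
#' one column per channel, optional single header row) and `wfdb` (a `.hea`
#' header plus an interleaved 16-bit `.dat` file).  Integer WAV samples are
#' rescaled to \[-1, 1\]; float WAV and CSV values pass through unchanged.
#'
#' @param path Path to the record.  For `wfdb` give either the `.hea` file or
#'   the record name without extension.
#' @param format One of `"wav"`, `"csv"`, `"wfdb"`; default guesses from the
#'   file extension.
#' @param sample_rate_override Sampling rate in Hz; required for CSV (which
#'   carries no rate), optional override otherwise.
#' @param channel_roles Role per channel (`"pcg"`/`"ecg"`).  Defaults to all
#'   `"pcg"`; WFDB records take roles from the header description when it
#'   says `ecg`.
#' @param channel_names Optional channel names.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("auto", "wav", "csv", "wfdb"),
                           sample_rate_override = NULL,
                           channel_roles = NULL, channel_names = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, wav = "wav", csv = "csv", hea = "wfdb", dat = "wfdb",
                     stop("pcgbeat_io_error: cannot guess format of '", path,
                          "'; pass format=", call. = FALSE))
  }
  res <- switch(format,
                wav = read_wav(path),
                csv = read_csv_record(path),
                wfdb = read_wfdb(path))
  fs <- if (!is.null(sample_rate_override)) sample_rate_override else res$sample_rate
  if (is.null(fs)) {
    stop("pcgbeat_missing_sample_rate: format '", format,
         "' carries no sampling rate; pass sample_rate_override", call. = FALSE)
  }
  nch <- ncol(res$samples)
  roles <- channel_roles %||% res$channel_roles %||% rep("pcg", nch)
  if (length(roles) != nch) {
    stop("pcgbeat_channel_mismatch: ", length(roles), " roles given for ",
         nch, " channels", call. = FALSE)
  }
  recording(res$samples, fs, roles,
            channel_names %||% res$channel_names)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording to disk
#'
#' @param rec A [recording()].
#' @param path Output path (for `wfdb`, the record name; `.hea`/`.dat` are
#'   added).
#' @param format `"wav"` (float32 or PCM16), `"csv"`, or `"wfdb"` (fmt 16).
#' @param bit_depth For WAV: `"float32"` (default, lossless for unit-scale
#'   data) or `"pcm16"`.
#' @return Invisibly, the path(s) written.
#' @export
write_recording <- function(rec, path, format = c("wav", "csv", "wfdb"),
                            bit_depth = c("float32", "pcm16")) {
  format <- match.arg(format)
  bit_depth <- match.arg(bit_depth)
  switch(format,
         wav = write_wav(rec$samples, rec$sample_rate, path, bit_depth),
         csv = {
           df <- as.data.frame(rec$samples)
           names(df) <- rec$channel_names
           utils::write.csv(df, path, row.names = FALSE)
           invisible(path)
         },
         wfdb = write_wfdb(rec, path))
}

## ---- CSV records -----------------------------------------------------------

read_csv_record <- function(path) {
  if (!file.exists(path)) {
    stop("pcgbeat_io_error: file not found: ", path, call. = FALSE)
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  cells <- strsplit(first, ",", fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(cells)))
  df <- utils::read.csv(path, header = has_header)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    stop("pcgbeat_io_error: non-numeric values in CSV record: ", path,
         call. = FALSE)
  }
  nm <- if (has_header) colnames(df) else NULL
  list(samples = m, sample_rate = NULL, channel_roles = NULL,
       channel_names = nm)
}

## ---- WAV (RIFF) ------------------------------------------------------------

read_wav <- function(path) {
  if (!file.exists(path)) {
    stop("pcgbeat_io_error: file not found: ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop("pcgbeat_io_error: not a RIFF/WAV file: ", path, call. = FALSE)
  }
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop("pcgbeat_io_error: not a WAVE file: ", path, call. = FALSE)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2,
                               endian = "little", signed = FALSE),
        n_channels = readBin(fmt_raw[3:4], "integer", 1, 2,
                             endian = "little", signed = FALSE),
        sample_rate = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, 2,
                       endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L))  # pad byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("pcgbeat_io_error: missing fmt/data chunk in WAV: ", path,
         call. = FALSE)
  }
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    vals <- readBin(data_raw, "integer", length(data_raw) / 2L, 2L,
                    endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    vals <- readBin(data_raw, "double", length(data_raw) / 4L, 4L,
                    endian = "little")
  } else {
    stop("pcgbeat_io_error: unsupported WAV encoding (format ",
         fmt$audio_format, ", ", fmt$bits, " bit)", call. = FALSE)
  }
  m <- matrix(vals, ncol = fmt$n_channels, byrow = TRUE)
  list(samples = m, sample_rate = fmt$sample_rate, channel_roles = NULL,
       channel_names = NULL)
}

write_wav <- function(samples, sample_rate, path, bit_depth = "float32") {
  samples <- as.matrix(samples)
  nch <- ncol(samples)
  interleaved <- as.numeric(t(samples))
  if (bit_depth == "pcm16") {
    audio_format <- 1L; bits <- 16L
    payload <- writeBin(as.integer(pmin(pmax(round(interleaved * 32767),
                                             -32768), 32767)),
                        raw(), size = 2L, endian = "little")
  } else {
    audio_format <- 3L; bits <- 32L
    payload <- writeBin(interleaved, raw(), size = 4L, endian = "little")
  }
  block_align <- nch * bits / 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + length(payload)), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(as.integer(audio_format), con, 2L, endian = "little")
  writeBin(as.integer(nch), con, 2L, endian = "little")
  writeBin(as.integer(sample_rate), con, 4L, endian = "little")
  writeBin(as.integer(sample_rate * block_align), con, 4L, endian = "little")
  writeBin(as.integer(block_align), con, 2L, endian = "little")
  writeBin(as.integer(bits), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(length(payload), con, 4L, endian = "little")
  writeBin(payload, con)
  invisible(path)
}

## ---- WFDB (minimal, fmt 16) ------------------------------------------------

read_wfdb <- function(path) {
  hea <- if (tolower(tools::file_ext(path)) == "hea") path else paste0(path, ".hea")
  if (!file.exists(hea)) {
    stop("pcgbeat_io_error: header not found: ", hea, call. = FALSE)
  }
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(hdr[2])
  fs <- as.numeric(hdr[3])
  sig_lines <- lines[1 + seq_len(nsig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gain <- as.numeric(sub("\\(.*\\)", "", sub("/.*$", "", f[3])))
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
    list(file = f[1], fmt = f[2], gain = gain, desc = desc)
  }
  sigs <- lapply(sig_lines, parse_sig)
  if (!all(vapply(sigs, function(s) s$fmt == "16", logical(1)))) {
    stop("pcgbeat_io_error: only WFDB format 16 is supported", call. = FALSE)
  }
  dat <- file.path(dirname(hea), sigs[[1]]$file)
  if (!file.exists(dat)) {
    stop("pcgbeat_io_error: signal file not found: ", dat, call. = FALSE)
  }
  raw_vals <- readBin(dat, "integer", file.info(dat)$size / 2L, 2L,
                      endian = "little")
  m <- matrix(raw_vals, ncol = nsig, byrow = TRUE)
  gains <- vapply(sigs, `[[`, numeric(1), "gain")
  gains[!is.finite(gains) | gains == 0] <- 200
  m <- sweep(m, 2L, gains, "/")
  descs <- vapply(sigs, `[[`, character(1), "desc")
  roles <- ifelse(grepl("ecg", descs, ignore.case = TRUE), "ecg", "pcg")
  nms <- ifelse(nzchar(descs), sub("^(ecg|pcg)\\s*", "", descs,
                                   ignore.case = TRUE), NA)
  if (anyNA(nms) || !any(nzchar(nms))) nms <- NULL
  list(samples = m, sample_rate = fs, channel_roles = roles,
       channel_names = if (!is.null(nms) && all(nzchar(nms))) nms else NULL)
}

write_wfdb <- function(rec, path) {
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  dat <- paste0(base, ".dat")
  nsig <- ncol(rec$samples)
  maxabs <- apply(abs(rec$samples), 2L, max)
  gains <- ifelse(maxabs > 0, floor(32000 / maxabs), 200)
  adc <- round(sweep(rec$samples, 2L, gains, "*"))
  adc <- pmin(pmax(adc, -32768), 32767)
  writeBin(as.integer(t(adc)), dat, size = 2L, endian = "little")
  rel_dat <- basename(dat)
  hdr <- c(sprintf("%s %d %g %d", basename(base), nsig, rec$sample_rate,
                   nrow(rec$samples)),
           sprintf("%s 16 %g/adu 16 0 %d 0 0 %s %s", rel_dat, gains,
                   as.integer(adc[1, ]), rec$channel_roles,
                   rec$channel_names))
  writeLines(hdr, hea)
  invisible(c(hea, dat))
}

## ---- Annotation tracks -----------------------------------------------------

#' Write an annotation track
#'
#' `csv` writes `time_s,label,amplitude` rows with microsecond precision.
#' `wfdb_ann` writes an annotation table in the spirit of WFDB `rdann`
#' output, as text: `sample,time_s,label,amplitude` (requires `sample_rate`).
#'
#' @param track An [annotation_track()].
#' @param path Output file path.
#' @param format `"csv"` or `"wfdb_ann"`.
#' @param sample_rate Sampling rate used to derive sample numbers for
#'   `wfdb_ann`.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(track, path, format = c("csv", "wfdb_ann"),
                              sample_rate = NULL) {
  format <- match.arg(format)
  df <- as.data.frame(track)
  if (format == "wfdb_ann") {
    if (is.null(sample_rate)) {
      stop("pcgbeat_io_error: wfdb_ann export needs sample_rate",
           call. = FALSE)
    }
    df <- cbind(sample = time_to_index(df$time_s, sample_rate), df)
  }
  df$time_s <- sprintf("%.6f", df$time_s)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an annotation track written by [write_annotations()]
#'
#' @param path Annotation file path.
#' @return An [annotation_track()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    stop("pcgbeat_io_error: file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "label") %in% names(df))) {
    stop("pcgbeat_io_error: not an annotation file (missing time_s/label): ",
         path, call. = FALSE)
  }
  amp <- if ("amplitude" %in% names(df)) df$amplitude else NULL
  annotation_track(df$time_s, df$label,
                   amp %||% rep(NA_real_, nrow(df)))
}
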