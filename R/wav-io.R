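# Minimal RIFF/WAVE reader and writer (16-bit PCM and 32-bit IEEE float),
# written against readBin/writeBin: enough to round-trip the two-channel
# stimulus + drum-trigger recordings this package works with.

#' Read a WAV file
#'
#' Supports uncompressed 16-bit PCM and 32-bit IEEE-float mono or stereo
#' files. Stereo files are interpreted as channel 1 = stimulus playback,
#' channel 2 = drum trigger; mono files fill both slots with the same
#' vector. Samples are scaled to [-1, 1].
#'
#' @param path File path.
#' @return List with `sample_rate_hz`, `stimulus`, `drum`, `n_channels`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels = readBin(raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little"))
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", sz)
      break
    } else {
      readBin(con, "raw", sz + sz %% 2)  # skip unknown chunk (word-aligned)
    }
  }
  if (is.null(fmt) || is.null(data)) stop("malformed WAV: missing fmt or data chunk")
  if (fmt$audio_format == 1 && fmt$bits == 16) {
    x <- readBin(data, "integer", length(data) / 2, size = 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 3 && fmt$bits == 32) {
    x <- readBin(data, "numeric", length(data) / 4, size = 4, endian = "little")
  } else {
    stop("unsupported WAV encoding: format ", fmt$audio_format, ", ", fmt$bits, " bits")
  }
  if (fmt$n_channels == 2) {
    stim <- x[seq(1, length(x), by = 2)]
    drum <- x[seq(2, length(x), by = 2)]
  } else if (fmt$n_channels == 1) {
    stim <- x; drum <- x
  } else stop("unsupported channel count: ", fmt$n_channels)
  list(sample_rate_hz = fmt$sample_rate, stimulus = stim, drum = drum,
       n_channels = fmt$n_channels)
}

#' Write a two-channel WAV file
#'
#' @param stimulus,drum Equal-length amplitude vectors in [-1, 1].
#' @param sample_rate_hz Sampling rate.
#' @param path Output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @export
write_wav <- function(stimulus, drum, sample_rate_hz, path, bits = 16) {
  stopifnot(length(stimulus) == length(drum), bits %in% c(16, 32))
  x <- as.vector(rbind(stimulus, drum))  # interleave
  bytes_per <- bits / 8
  data_sz <- length(x) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  wle <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  writeChar("RIFF", con, eos = NULL); wle(36 + data_sz, 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); wle(16, 4)
  wle(if (bits == 16) 1 else 3, 2); wle(2, 2)  # format, channels
  wle(sample_rate_hz, 4); wle(sample_rate_hz * 2 * bytes_per, 4)
  wle(2 * bytes_per, 2); wle(bits, 2)
  writeChar("data", con, eos = NULL); wle(data_sz, 4)
  if (bits == 16) {
    writeBin(as.integer(round(pmax(-1, pmin(1, x)) * 32767)), con,
             size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Render onset timelines to a synthetic two-channel recording
#'
#' Each onset becomes a short decaying click, giving an impulse-train
#' recording that exercises the extraction path end-to-end.
#'
#' @param stim_times_ms,drum_times_ms Onset times on one timeline (ms).
#' @param sample_rate_hz Sampling rate (default 8000; onset timing error is
#'   then at most 1/8 ms).
#' @param duration_ms Total duration; defaults to 200 ms past the last onset.
#' @param click_ms Click length.
#' @return List in the shape [read_wav()] returns.
#' @export
render_recording <- function(stim_times_ms, drum_times_ms,
                             sample_rate_hz = 8000, duration_ms = NULL,
                             click_ms = 10) {
  if (is.null(duration_ms))
    duration_ms <- max(c(stim_times_ms, drum_times_ms, 0)) + 200
  n <- ceiling(duration_ms * sample_rate_hz / 1000)
  click <- 0.9 * exp(-seq(0, 5, length.out = max(2, round(click_ms * sample_rate_hz / 1000))))
  lay <- function(times) {
    ch <- numeric(n)
    for (t in times) {
      i <- round(t * sample_rate_hz / 1000) + 1
      j <- min(n, i + length(click) - 1)
      if (i <= n) ch[i:j] <- pmax(ch[i:j], click[1:(j - i + 1)])
    }
    ch
  }
  list(sample_rate_hz = sample_rate_hz, stimulus = lay(stim_times_ms),
       drum = lay(drum_times_ms), n_channels = 2L)
}
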