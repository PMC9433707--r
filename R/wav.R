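#' Audio waveform container
#'
#' A minimal container for a mono audio signal: a numeric sample vector
#' (nominally in \[-1, 1\]) and its sampling rate in Hz.
#'
#' @param samples Numeric vector of finite sample values.
#' @param rate Sampling rate in Hz (> 0).
#' @return An object of class `audio_waveform` with fields `samples` and
#'   `rate`.
#' @export
audio_waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stopf("`rate` must be a single positive number, got %s", format(rate)[1])
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stopf("audio samples must be finite")
  }
  structure(list(samples = samples, rate = rate), class = "audio_waveform")
}

#' @export
print.audio_waveform <- function(x, ...) {
  cat(sprintf("<audio_waveform> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

audio_duration <- function(audio) length(audio$samples) / audio$rate

#' Read a RIFF/WAV file
#'
#' Reads uncompressed PCM (16-bit integer) or IEEE float32 WAV files. Only the
#' first channel of a multichannel file is kept.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_waveform()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stopf("WAV file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stopf("%s: not a RIFF file", path)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stopf("%s: not a WAVE file", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) stopf("%s: no data chunk found", path)
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        code = readBin(raw_fmt[1:2], "integer", 1, 2, endian = "little"),
        n_channels = readBin(raw_fmt[3:4], "integer", 1, 2, endian = "little"),
        rate = readBin(raw_fmt[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stopf("%s: data chunk before fmt chunk", path)
      if (fmt$code == 1L && fmt$bits == 16L) {
        x <- readBin(con, "integer", sz / 2L, 2, signed = TRUE, endian = "little") / 32768
      } else if (fmt$code == 3L && fmt$bits == 32L) {
        x <- readBin(con, "double", sz / 4L, 4, endian = "little")
      } else {
        stopf("%s: unsupported WAV encoding (format %d, %d bit)",
              path, fmt$code, fmt$bits)
      }
      if (fmt$n_channels > 1L) {
        x <- x[seq(1L, length(x), by = fmt$n_channels)]
      }
      return(audio_waveform(x, fmt$rate))
    } else {
      seek(con, sz + sz %% 2L, origin = "current")
    }
  }
}

#' Write a RIFF/WAV file
#'
#' @param audio An [audio_waveform()].
#' @param path Output path.
#' @param format `"float32"` (default) or `"pcm16"`. PCM samples are clipped
#'   to \[-1, 1\] before quantization.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  x <- audio$samples
  n <- length(x)
  bytes_per <- if (format == "float32") 4L else 2L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(if (format == "float32") 3L else 1L, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                 # mono
  writeBin(as.integer(audio$rate), con, 4, endian = "little")
  writeBin(as.integer(audio$rate * bytes_per), con, 4, endian = "little")
  writeBin(bytes_per, con, 2, endian = "little")          # block align
  writeBin(8L * bytes_per, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (format == "float32") {
    writeBin(x, con, 4, endian = "little")
  } else {
    q <- as.integer(round_half_away(pmax(-1, pmin(1, x)) * 32767))
    writeBin(q, con, 2, endian = "little")
  }
  invisible(path)
}
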