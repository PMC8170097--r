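#' Waveform objects
#'
#' A `waveform` is a mono amplitude sequence with a sampling rate.  All
#' acoustic analysis in the package runs at an internal rate of 16 kHz;
#' [resample_wave()] converts arbitrary input rates, and stereo input is
#' averaged to mono on read.
#'
#' @param samples numeric amplitude vector.
#' @param rate sampling rate in Hz (> 0).
#' @return an object of class `waveform`.
#' @export
waveform <- function(samples, rate) {
  stopifnot(rate > 0, is.numeric(samples))
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %.2f s at %g Hz>\n",
              length(x$samples) / x$rate, x$rate))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w a `waveform`.
#' @export
wave_duration <- function(w) length(w$samples) / w$rate

#' Resample a waveform
#'
#' Linear-interpolation resampling to a target rate (default the package's
#' internal 16 kHz analysis rate).  Adequate for the narrowband analysis
#' done here; pre-filter externally if strong energy lives above the new
#' Nyquist frequency.
#'
#' @param w a `waveform`.
#' @param rate target rate in Hz.
#' @return a `waveform` at `rate`.
#' @export
resample_wave <- function(w, rate = 16000) {
  if (w$rate == rate) return(w)
  n_out <- max(1L, round(length(w$samples) * rate / w$rate))
  t_out <- (seq_len(n_out) - 1) / rate
  t_in <- (seq_along(w$samples) - 1) / w$rate
  waveform(stats::approx(t_in, w$samples, xout = t_out, rule = 2)$y, rate)
}

#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed 8/16/32-bit integer PCM and
#' 32-bit float data.  Multichannel input is averaged to mono; samples are
#' scaled to `[-1, 1]`.
#'
#' @param path path to a `.wav` file.
#' @return a `waveform`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little",
                               signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little"),
        rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little"),
        bits = readBin(con, "integer", 1, 2, endian = "little"))
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("missing fmt or data chunk in ", path)

  x <- switch(as.character(fmt$bits),
    "8"  = (as.numeric(readBin(data_raw, "integer", length(data_raw), 1,
                               signed = FALSE)) - 128) / 128,
    "16" = readBin(data_raw, "integer", length(data_raw) %/% 2, 2,
                   endian = "little") / 32768,
    "32" = if (fmt$audio_format == 3)
             readBin(data_raw, "double", length(data_raw) %/% 4, 4,
                     endian = "little")
           else readBin(data_raw, "integer", length(data_raw) %/% 4, 4,
                        endian = "little") / 2147483648,
    stop("unsupported bit depth: ", fmt$bits))
  if (fmt$channels > 1) {
    n <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(n * fmt$channels)], nrow = fmt$channels))
  }
  waveform(x, fmt$rate)
}

#' Write a 16-bit PCM WAV file
#'
#' @param w a `waveform`; samples are clipped to `[-1, 1]`.
#' @param path output path.
#' @export
write_wav <- function(w, path) {
  x <- pmax(-1, pmin(1, w$samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, 4, endian = "little")
  writeBin(as.integer(1), con, 2, endian = "little")   # PCM
  writeBin(as.integer(1), con, 2, endian = "little")   # mono
  writeBin(as.integer(w$rate), con, 4, endian = "little")
  writeBin(as.integer(w$rate * 2), con, 4, endian = "little")
  writeBin(as.integer(2), con, 2, endian = "little")
  writeBin(as.integer(16), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

# Slice a signal into frames (rows).  Partial tail frames are dropped.
frame_signal <- function(x, rate, frame_len = 0.025, step = 0.010) {
  L <- round(frame_len * rate)
  S <- round(step * rate)
  n <- length(x)
  if (n < L) return(matrix(numeric(0), nrow = 0, ncol = L))
  starts <- seq(1L, n - L + 1L, by = S)
  out <- matrix(0, nrow = length(starts), ncol = L)
  for (i in seq_along(starts)) out[i, ] <- x[starts[i]:(starts[i] + L - 1L)]
  out
}
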