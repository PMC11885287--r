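# Minimal RIFF/WAVE reader and writer.
#
# The pipeline only needs mono/stereo PCM (8/16/24-bit) and IEEE float32
# clips; we parse the RIFF chunk list directly rather than pulling in an
# audio stack for two fixed layouts. The writer always emits 16-bit PCM
# mono, the format the synthetic generator standardizes on.

#' An in-memory audio clip
#'
#' Constructs the unit all DSP operations consume: a mono waveform with its
#' sample rate. Samples must be finite and are expected in `[-1, 1]`.
#'
#' @param samples numeric vector of amplitudes.
#' @param sample_rate sampling rate in Hz.
#' @return an object of class `AudioClip` with fields `samples` and
#'   `sample_rate`.
#' @export
audio_clip <- function(samples, sample_rate) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop_invalid_input("AudioClip requires a non-empty numeric sample vector")
  }
  if (any(!is.finite(samples))) {
    stop_invalid_input("AudioClip samples must all be finite")
  }
  if (!is_num(sample_rate) || sample_rate <= 0) {
    stop_invalid_input("sample_rate must be a positive number")
  }
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "AudioClip")
}

#' @export
print.AudioClip <- function(x, ...) {
  cat(sprintf("<AudioClip: %d samples @ %g Hz (%.3f s)>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

clip_duration <- function(clip) length(clip$samples) / clip$sample_rate

#' Read a WAV file
#'
#' Parses a RIFF/WAVE file (PCM 8/16/24-bit or IEEE float32, mono or
#' stereo). Stereo is mixed to mono by channel averaging; integer samples
#' are scaled to `[-1, 1]` by the conventional `2^(bits-1)` divisor.
#'
#' @param path path to a `.wav` file.
#' @return an [audio_clip()].
#' @export
load_wav <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_format(sprintf("not a readable WAV file: %s", path))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 12L)
  if (length(hdr) < 12L ||
      rawToChar(hdr[1:4]) != "RIFF" || rawToChar(hdr[9:12]) != "WAVE") {
    stop_format(sprintf("not a RIFF/WAVE file: %s", path))
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    chdr <- readBin(con, "raw", 8L)
    if (length(chdr) < 8L) break
    cid <- rawToChar(chdr[1:4])
    csize <- readBin(chdr[5:8], "integer", 1L, size = 4L, endian = "little")
    if (cid == "fmt ") {
      body <- readBin(con, "raw", csize)
      if (length(body) < 16L) stop_format(sprintf("truncated fmt chunk: %s", path))
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1L, 2L, signed = FALSE, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1L, 4L, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1L, 2L, signed = FALSE, endian = "little")
      )
    } else if (cid == "data") {
      data_raw <- readBin(con, "raw", csize)
      if (length(data_raw) < csize) {
        stop_format(sprintf("truncated data chunk: %s", path))
      }
    } else {
      readBin(con, "raw", csize + csize %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop_format(sprintf("missing fmt/data chunk: %s", path))
  }
  x <- decode_wav_samples(data_raw, fmt, path)
  nch <- fmt$n_channels
  if (nch > 1L) {
    n <- length(x) %/% nch
    x <- colMeans(matrix(x[seq_len(n * nch)], nrow = nch))
  }
  if (length(x) == 0L) stop_format(sprintf("empty data chunk: %s", path))
  audio_clip(x, fmt$sample_rate)
}

decode_wav_samples <- function(data_raw, fmt, path) {
  if (fmt$audio_format == 3L && fmt$bits == 32L) {
    return(readBin(data_raw, "double", length(data_raw) %/% 4L, size = 4L,
                   endian = "little"))
  }
  if (fmt$audio_format != 1L) {
    stop_format(sprintf("unsupported WAV encoding (format %d): %s",
                        fmt$audio_format, path))
  }
  switch(as.character(fmt$bits),
    "8"  = (as.numeric(readBin(data_raw, "integer", length(data_raw),
                               size = 1L, signed = FALSE)) - 128) / 128,
    "16" = readBin(data_raw, "integer", length(data_raw) %/% 2L, size = 2L,
                   signed = TRUE, endian = "little") / 32768,
    "24" = {
      n <- length(data_raw) %/% 3L
      b <- matrix(as.integer(data_raw[seq_len(n * 3L)]), nrow = 3L)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    stop_format(sprintf("unsupported PCM bit depth %d: %s", fmt$bits, path))
  )
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param clip an [audio_clip()]; samples are clamped to `[-1, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "AudioClip"))
  x <- pmax(-1, pmin(1, clip$samples))
  pcm <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
  n_bytes <- length(pcm) * 2L
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_io(sprintf("cannot open for writing: %s", path)))
  on.exit(close(con))
  sr <- as.integer(round(clip$sample_rate))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(c(1L, 1L), con, size = 2L, endian = "little")          # PCM, mono
  writeBin(sr, con, size = 4L, endian = "little")
  writeBin(sr * 2L, con, size = 4L, endian = "little")            # byte rate
  writeBin(c(2L, 16L), con, size = 2L, endian = "little")         # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
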