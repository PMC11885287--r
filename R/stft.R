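# Short-time Fourier analysis.
#
# Frames are centered (reflect padding of frame_length/2 on both ends) and
# windowed with a periodic Hann window; the magnitude spectrogram keeps the
# frame_length/2 + 1 non-negative-frequency bins. Defaults (2048/512 at
# 22.05 kHz) are the de facto bioacoustics analysis settings.

#' STFT framing parameters
#'
#' @param frame_length frame size in samples.
#' @param hop hop size in samples, `0 < hop <= frame_length`.
#' @param window window type; only `"hann"` is provided.
#' @return a `FrameSpec` list.
#' @export
frame_spec <- function(frame_length = 2048L, hop = 512L, window = "hann") {
  if (!is_count(frame_length) || !is_count(hop) || hop > frame_length) {
    stop_invalid_config("need 0 < hop <= frame_length, both integers")
  }
  if (!identical(window, "hann")) {
    stop_invalid_config("only the Hann window is supported")
  }
  structure(list(frame_length = as.integer(frame_length),
                 hop = as.integer(hop), window = window),
            class = "FrameSpec")
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

# Mirror-reflection (no edge repeat) index into 1..n for any integer i.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  m <- (i - 1) %% (2 * (n - 1))
  ifelse(m < n, m + 1, 2 * n - 1 - m)
}

reflect_pad <- function(x, p) {
  n <- length(x)
  x[reflect_index((1 - p):(n + p), n)]
}

# Matrix of centered frames (frame_length x n_frames) from a padded signal.
frame_signal <- function(samples, fspec) {
  L <- fspec$frame_length
  hop <- fspec$hop
  n <- length(samples)
  xp <- reflect_pad(samples, L %/% 2L)
  n_frames <- 1L + n %/% hop
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(L), starts, `+`)
  matrix(xp[idx], nrow = L)
}

#' Magnitude spectrogram
#'
#' Windowed DFT magnitude per centered frame. Returned as an object of
#' class `Spectrogram` with fields `magnitudes` (frames x bins), `bin_freqs`
#' (Hz, ascending from 0 to Nyquist), `frame_times` (s), `sample_rate` and
#' the `FrameSpec` used.
#'
#' @param clip an [audio_clip()] at least one frame long.
#' @param fspec a [frame_spec()].
#' @return a `Spectrogram`.
#' @export
spectrogram <- function(clip, fspec = frame_spec()) {
  stopifnot(inherits(clip, "AudioClip"))
  if (length(clip$samples) < fspec$frame_length %/% 2L) {
    stop_invalid_input("clip shorter than one analysis frame")
  }
  frames <- frame_signal(clip$samples, fspec) * hann_window(fspec$frame_length)
  spec <- stats::mvfft(frames)
  n_bins <- fspec$frame_length %/% 2L + 1L
  mag <- t(Mod(spec[seq_len(n_bins), , drop = FALSE]))
  structure(list(
    magnitudes = mag,
    bin_freqs = (seq_len(n_bins) - 1) * clip$sample_rate / fspec$frame_length,
    frame_times = (seq_len(nrow(mag)) - 1) * fspec$hop / clip$sample_rate,
    sample_rate = clip$sample_rate,
    frame_spec = fspec
  ), class = "Spectrogram")
}

#' @export
print.Spectrogram <- function(x, ...) {
  cat(sprintf("<Spectrogram: %d frames x %d bins, 0-%.0f Hz>\n",
              nrow(x$magnitudes), ncol(x$magnitudes), max(x$bin_freqs)))
  invisible(x)
}

# Complex STFT (frames x bins) + inverse, used by spectral subtraction.
stft_complex <- function(samples, fspec) {
  frames <- frame_signal(samples, fspec) * hann_window(fspec$frame_length)
  spec <- stats::mvfft(frames)
  n_bins <- fspec$frame_length %/% 2L + 1L
  t(spec[seq_len(n_bins), , drop = FALSE])
}

istft <- function(stft, fspec, n_out) {
  L <- fspec$frame_length
  hop <- fspec$hop
  n_frames <- nrow(stft)
  full <- matrix(0 + 0i, L, n_frames)
  full[seq_len(ncol(stft)), ] <- t(stft)
  full[(L %/% 2L + 2L):L, ] <- Conj(full[(L %/% 2L):2L, , drop = FALSE])
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / L
  w <- hann_window(L)
  frames <- frames * w
  total <- (n_frames - 1L) * hop + L
  y <- numeric(total)
  wsum <- numeric(total)
  for (f in seq_len(n_frames)) {
    i <- ((f - 1L) * hop + 1L):((f - 1L) * hop + L)
    y[i] <- y[i] + frames[, f]
    wsum[i] <- wsum[i] + w^2
  }
  y <- y / pmax(wsum, 1e-8)
  # drop the centering pad and trim to the original length
  y[(L %/% 2L + 1L):(L %/% 2L + n_out)]
}

#' Spectral-subtraction denoising
#'
#' Estimates the noise magnitude spectrum as the mean magnitude over the
#' first `noise_seconds` of the clip, subtracts `oversubtract` times it
#' from every frame of the magnitude STFT (floored at `floor_beta` times
#' the noise spectrum), reattaches the original phase and inverts. Output
#' length equals input length. The default over-subtraction factor of 2
#' follows standard spectral-subtraction practice: plain subtraction of the
#' mean removes only the mean of the Rayleigh-distributed noise magnitudes
#' and leaves about a third of the noise RMS behind.
#'
#' @param clip an [audio_clip()] longer than `noise_seconds`.
#' @param noise_seconds leading noise-profiling interval, seconds.
#' @param floor_beta spectral floor as a fraction of the noise spectrum.
#' @param oversubtract multiple of the noise spectrum subtracted.
#' @param fspec a [frame_spec()].
#' @return a denoised [audio_clip()].
#' @export
denoise <- function(clip, noise_seconds = 0.5, floor_beta = 0.01,
                    oversubtract = 2, fspec = frame_spec()) {
  stopifnot(inherits(clip, "AudioClip"))
  if (clip_duration(clip) <= noise_seconds) {
    stop_invalid_input("clip must be longer than noise_seconds")
  }
  stft <- stft_complex(clip$samples, fspec)
  mag <- Mod(stft)
  times <- (seq_len(nrow(stft)) - 1) * fspec$hop / clip$sample_rate
  noise_frames <- which(times < noise_seconds)
  noise_spec <- colMeans(mag[noise_frames, , drop = FALSE])
  cleaned <- sweep(mag, 2, oversubtract * noise_spec, `-`)
  floor_mat <- matrix(floor_beta * noise_spec, nrow(mag), ncol(mag), byrow = TRUE)
  cleaned <- pmax(cleaned, floor_mat)
  phase <- stft / pmax(mag, 1e-12)
  y <- istft(cleaned * phase, fspec, length(clip$samples))
  audio_clip(y, clip$sample_rate)
}

#' Segment a clip into fixed-length windows
#'
#' Non-overlapping windows of exactly `seconds`. A final remainder of at
#' least 1 s is zero-padded to full length and kept; a shorter remainder is
#' dropped. A clip shorter than `seconds` yields exactly one zero-padded
#' segment.
#'
#' @param clip an [audio_clip()].
#' @param seconds segment duration, seconds (> 0).
#' @return a list of [audio_clip()]s.
#' @export
segment <- function(clip, seconds = 5) {
  stopifnot(inherits(clip, "AudioClip"))
  if (!is_num(seconds) || seconds <= 0) {
    stop_invalid_input("seconds must be positive")
  }
  n_seg <- as.integer(round(seconds * clip$sample_rate))
  n <- length(clip$samples)
  if (n <= n_seg) {
    return(list(audio_clip(c(clip$samples, numeric(n_seg - n))[seq_len(n_seg)],
                           clip$sample_rate)))
  }
  n_full <- n %/% n_seg
  rem <- n - n_full * n_seg
  out <- lapply(seq_len(n_full), function(i) {
    audio_clip(clip$samples[((i - 1L) * n_seg + 1L):(i * n_seg)],
               clip$sample_rate)
  })
  if (rem >= clip$sample_rate) {   # remainder >= 1 s is kept, zero-padded
    tail <- clip$samples[(n_full * n_seg + 1L):n]
    out <- c(out, list(audio_clip(c(tail, numeric(n_seg - rem)),
                                  clip$sample_rate)))
  }
  out
}
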