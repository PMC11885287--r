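# Acoustic descriptors.
#
# The full per-clip feature table concatenates, in this fixed order:
#   SET1  five spectral descriptors (centroid, zcr, flux, rolloff,
#         bandwidth), each summarized as mean + population std  -> 10
#   SET2  harmonic_ratio, tempo_bpm (clip-level scalars), 12 chroma and
#         39 MFCC (13 static + 13 delta + 13 delta-delta) summaries -> 104
#   SET3  13 gammatone cepstral coefficients, summarized          -> 26
# for 140 named features per clip, plus the species label.

PITCH_CLASSES <- c("A", "As", "B", "C", "Cs", "D", "Ds", "E", "F", "Fs",
                   "G", "Gs")

# Cosine transform of the cepstral stage: c_m = sum_n X_n cos(m (n-1/2) pi/N)
# for m = 1..n_keep, with N = length(X). Applied to each row of a matrix.
cepstral_dct <- function(X, n_keep) {
  N <- ncol(X)
  basis <- sapply(seq_len(n_keep), function(m) {
    cos(m * (seq_len(N) - 0.5) * pi / N)
  })
  X %*% basis
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank as an n_mels x n_bins weight matrix.
mel_filterbank <- function(n_mels, bin_freqs, f_min = 0, f_max = max(bin_freqs)) {
  pts <- mel_to_hz(seq(hz_to_mel(f_min), hz_to_mel(f_max), length.out = n_mels + 2L))
  fb <- matrix(0, n_mels, length(bin_freqs))
  for (j in seq_len(n_mels)) {
    lo <- pts[j]; cen <- pts[j + 1]; hi <- pts[j + 2]
    up <- (bin_freqs - lo) / (cen - lo)
    down <- (hi - bin_freqs) / (hi - cen)
    fb[j, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# First temporal difference by centered differences with replicated edges.
delta_features <- function(m) {
  n <- nrow(m)
  if (n == 1L) return(m * 0)
  padded <- rbind(m[1, , drop = FALSE], m, m[n, , drop = FALSE])
  (padded[3:(n + 2), , drop = FALSE] - padded[1:n, , drop = FALSE]) / 2
}

#' MFCC block with deltas
#'
#' Per frame: triangular mel filterbank energies over the power spectrum
#' (0 Hz to Nyquist), natural log floored at 1e-10, then the cosine
#' transform `c_m = sum_n X_n cos(m (n - 0.5) pi / N)` with `X_n` the log
#' energies, `N = n_mels` and `m = 1..n_keep`. First and second temporal
#' differences (centered, edges replicated) are appended, giving
#' `3 * n_keep` columns. Static coefficients are invariant to global gain.
#'
#' @param spect a [spectrogram()].
#' @param n_mels number of mel filters.
#' @param n_keep number of cepstral coefficients kept.
#' @return a frames x `3 * n_keep` matrix with columns
#'   `mfcc_01..`, `mfcc_d01..`, `mfcc_dd01..`.
#' @export
mfcc_block <- function(spect, n_mels = 26L, n_keep = 13L) {
  stopifnot(inherits(spect, "Spectrogram"))
  if (n_keep > n_mels) stop_invalid_config("n_keep must not exceed n_mels")
  if (n_mels > ncol(spect$magnitudes)) {
    stop_invalid_config("n_mels exceeds the number of spectrogram bins")
  }
  fb <- mel_filterbank(n_mels, spect$bin_freqs)
  energies <- spect$magnitudes^2 %*% t(fb)
  logE <- log(pmax(energies, 1e-10))
  static <- cepstral_dct(logE, n_keep)
  d1 <- delta_features(static)
  d2 <- delta_features(d1)
  out <- cbind(static, d1, d2)
  colnames(out) <- c(sprintf("mfcc_%02d", seq_len(n_keep)),
                     sprintf("mfcc_d%02d", seq_len(n_keep)),
                     sprintf("mfcc_dd%02d", seq_len(n_keep)))
  out
}

hz_to_erb <- function(f) 21.4 * log10(1 + 0.00437 * f)
erb_to_hz <- function(e) (10^(e / 21.4) - 1) / 0.00437

# 4th-order gammatone power response sampled on the FFT bins, row-normalized.
gammatone_filterbank <- function(n_filters, bin_freqs, f_min, f_max) {
  centers <- erb_to_hz(seq(hz_to_erb(f_min), hz_to_erb(f_max),
                           length.out = n_filters))
  fb <- matrix(0, n_filters, length(bin_freqs))
  for (j in seq_len(n_filters)) {
    b <- 1.019 * 24.7 * (0.00437 * centers[j] + 1)
    w <- (1 + ((bin_freqs - centers[j]) / b)^2)^(-4)
    fb[j, ] <- w / sum(w)
  }
  fb
}

#' Gammatone cepstral coefficients (GFCC)
#'
#' ERB-spaced gammatone filterbank (50 Hz to 0.95 x Nyquist) applied to the
#' power spectrum, cube-root amplitude compression, then the same cosine
#' transform as [mfcc_block()], keeping `n_keep` coefficients.
#'
#' @param clip an [audio_clip()].
#' @param n_filters number of gammatone channels.
#' @param n_keep number of cepstral coefficients kept.
#' @param fspec a [frame_spec()].
#' @return a frames x `n_keep` matrix with columns `gfcc_01..`.
#' @export
gfcc_block <- function(clip, n_filters = 26L, n_keep = 13L,
                       fspec = frame_spec()) {
  stopifnot(inherits(clip, "AudioClip"))
  if (n_keep > n_filters) stop_invalid_config("n_keep must not exceed n_filters")
  spect <- spectrogram(clip, fspec)
  if (n_filters > ncol(spect$magnitudes)) {
    stop_invalid_config("n_filters exceeds the number of spectrogram bins")
  }
  fb <- gammatone_filterbank(n_filters, spect$bin_freqs,
                             50, 0.95 * clip$sample_rate / 2)
  energies <- spect$magnitudes^2 %*% t(fb)
  compressed <- energies^(1 / 3)
  out <- cepstral_dct(compressed, n_keep)
  colnames(out) <- sprintf("gfcc_%02d", seq_len(n_keep))
  out
}

#' Frame-level spectral descriptors
#'
#' Computes, per frame: spectral centroid `sum(f S) / sum(S)` (Hz);
#' bandwidth `sqrt(sum(S (f - centroid)^2) / sum(S))`; rolloff (smallest
#' frequency at which the cumulative magnitude reaches 85% of the frame
#' total); flux (Euclidean norm of positive magnitude increments vs. the
#' previous frame, 0 for the first); and zero-crossing rate computed on the
#' identically framed waveform (sign-change pairs over `frame_length - 1`).
#' Silent frames get centroid, bandwidth and rolloff 0.
#'
#' @param spect a [spectrogram()].
#' @param clip the [audio_clip()] the spectrogram came from.
#' @return a frames x 5 matrix with columns
#'   `centroid, zcr, flux, rolloff, bandwidth`.
#' @export
spectral_descriptors <- function(spect, clip) {
  stopifnot(inherits(spect, "Spectrogram"), inherits(clip, "AudioClip"))
  mag <- spect$magnitudes
  f <- spect$bin_freqs
  tot <- rowSums(mag)
  live <- tot > 0
  centroid <- numeric(nrow(mag))
  bandwidth <- numeric(nrow(mag))
  rolloff <- numeric(nrow(mag))
  if (any(live)) {
    centroid[live] <- (mag[live, , drop = FALSE] %*% f) / tot[live]
    dev2 <- sweep(matrix(f, sum(live), length(f), byrow = TRUE), 1,
                  centroid[live], `-`)^2
    bandwidth[live] <- sqrt(rowSums(mag[live, , drop = FALSE] * dev2) / tot[live])
    cum <- t(apply(mag[live, , drop = FALSE], 1, cumsum))
    thresh <- 0.85 * tot[live]
    rolloff[live] <- f[max.col(cum >= thresh, ties.method = "first")]
  }
  dmag <- rbind(0, pmax(diff(mag), 0))
  flux <- sqrt(rowSums(dmag^2))
  flux[1] <- 0
  frames <- frame_signal(clip$samples, spect$frame_spec)
  s1 <- frames[-nrow(frames), , drop = FALSE]
  s2 <- frames[-1, , drop = FALSE]
  zcr <- colSums(s1 * s2 < 0) / (spect$frame_spec$frame_length - 1L)
  out <- cbind(centroid = centroid, zcr = zcr, flux = flux,
               rolloff = rolloff, bandwidth = bandwidth)
  out
}

#' Chroma features
#'
#' Folds spectrogram bin energies onto the 12 pitch classes (A4 = 440 Hz
#' reference, nearest-semitone assignment; bins below 50 Hz ignored), then
#' normalizes each frame to unit maximum (silent frames stay zero).
#'
#' @param spect a [spectrogram()].
#' @return a frames x 12 matrix with columns `chroma_A .. chroma_Gs`.
#' @export
chroma <- function(spect) {
  stopifnot(inherits(spect, "Spectrogram"))
  f <- spect$bin_freqs
  keep <- f >= 50
  pc <- (round(12 * log2(f[keep] / 440)) %% 12) + 1L
  energy <- spect$magnitudes[, keep, drop = FALSE]^2
  out <- matrix(0, nrow(energy), 12L,
                dimnames = list(NULL, paste0("chroma_", PITCH_CLASSES)))
  for (p in 1:12) {
    sel <- pc == p
    if (any(sel)) out[, p] <- rowSums(energy[, sel, drop = FALSE])
  }
  mx <- apply(out, 1, max)
  live <- mx > 0
  out[live, ] <- out[live, , drop = FALSE] / mx[live]
  out
}

#' Tempo and harmonicity
#'
#' Tempo: 60 over the lag (seconds) of the highest peak of the raw
#' autocorrelation of the onset envelope (positive frame-energy
#' increments), searched over lags of 0.25-2 s; 0 if the envelope is
#' silent. Harmonic ratio: fraction of frame spectral energy lying within
#' +/- 3% of the 2nd and 3rd multiples of the frame's peak frequency,
#' averaged over voiced frames (frame energy at least 5% of the maximum).
#'
#' @param clip an [audio_clip()] of at least 1 s.
#' @param fspec a [frame_spec()].
#' @return a list with `tempo_bpm` and `harmonic_ratio`.
#' @export
tempo_harmonics <- function(clip, fspec = frame_spec()) {
  stopifnot(inherits(clip, "AudioClip"))
  if (clip_duration(clip) < 1) stop_invalid_input("clip must be at least 1 s long")
  spect <- spectrogram(clip, fspec)
  power <- spect$magnitudes^2
  e <- rowSums(power)
  onset <- pmax(c(0, diff(e)), 0)
  sr <- clip$sample_rate
  lag_frames <- seq(max(1L, as.integer(ceiling(0.25 * sr / fspec$hop))),
                    min(length(onset) - 2L, as.integer(floor(2 * sr / fspec$hop))))
  tempo <- 0
  if (length(lag_frames) > 0 && any(onset > 0)) {
    ac <- vapply(lag_frames, function(l) {
      sum(onset[seq_len(length(onset) - l)] * onset[(l + 1):length(onset)])
    }, 0)
    if (max(ac) > 0) {
      best <- lag_frames[which.max(ac)]
      tempo <- 60 / (best * fspec$hop / sr)
    }
  }
  voiced <- e >= 0.05 * max(e) & e > 0
  hr <- 0
  if (any(voiced)) {
    f <- spect$bin_freqs
    ratios <- vapply(which(voiced), function(t) {
      p <- which.max(power[t, -1]) + 1L          # skip DC
      fp <- f[p]
      if (fp <= 0) return(0)
      sel <- (abs(f - 2 * fp) <= 0.03 * 2 * fp) | (abs(f - 3 * fp) <= 0.03 * 3 * fp)
      sum(power[t, sel]) / e[t]
    }, 0)
    hr <- mean(ratios)
  }
  list(tempo_bpm = tempo, harmonic_ratio = hr)
}

#' Summarize per-frame features to clip level
#'
#' Column-wise mean and population standard deviation, named
#' `<feature>_mean` / `<feature>_std`, preserving column order.
#'
#' @param per_frame a frames x d matrix with column names.
#' @return a named numeric vector of length `2 d`.
#' @export
summarize_features <- function(per_frame) {
  if (is.null(dim(per_frame))) per_frame <- matrix(per_frame, ncol = 1)
  if (nrow(per_frame) < 1L) stop_invalid_input("need at least one frame")
  mu <- colMeans(per_frame)
  sd_pop <- sqrt(colMeans(sweep(per_frame, 2, mu, `-`)^2))
  nm <- colnames(per_frame)
  if (is.null(nm)) nm <- sprintf("f%02d", seq_along(mu))
  out <- as.vector(rbind(mu, sd_pop))
  names(out) <- as.vector(rbind(paste0(nm, "_mean"), paste0(nm, "_std")))
  out
}

feature_set_names <- function(set_id, selection = NULL) {
  set1 <- as.vector(rbind(paste0(c("centroid", "zcr", "flux", "rolloff",
                                   "bandwidth"), "_mean"),
                          paste0(c("centroid", "zcr", "flux", "rolloff",
                                   "bandwidth"), "_std")))
  chroma_nm <- paste0("chroma_", PITCH_CLASSES)
  mfcc_nm <- c(sprintf("mfcc_%02d", 1:13), sprintf("mfcc_d%02d", 1:13),
               sprintf("mfcc_dd%02d", 1:13))
  set2 <- c("harmonic_ratio", "tempo_bpm",
            as.vector(rbind(paste0(chroma_nm, "_mean"), paste0(chroma_nm, "_std"))),
            as.vector(rbind(paste0(mfcc_nm, "_mean"), paste0(mfcc_nm, "_std"))))
  gfcc_nm <- sprintf("gfcc_%02d", 1:13)
  set3 <- as.vector(rbind(paste0(gfcc_nm, "_mean"), paste0(gfcc_nm, "_std")))
  switch(set_id,
    SET1 = set1, SET2 = set2, SET3 = set3,
    SET4 = {
      if (is.null(selection)) {
        stop_schema("SET4 requires a SelectionResult")
      }
      selection$selected
    },
    stop_schema(sprintf("unknown feature set id: %s", set_id))
  )
}

#' Assemble a named feature set from a feature table row
#'
#' `SET1` is the five spectral descriptor summaries; `SET2` is harmonicity,
#' tempo, chroma and MFCC summaries; `SET3` the GFCC summaries; `SET4` the
#' features chosen by [select_top_k()] (in rank order).
#'
#' @param row a named numeric vector or one-row data.frame of clip features.
#' @param set_id one of `"SET1" .. "SET4"`.
#' @param selection a `SelectionResult`, required for `SET4`.
#' @return an ordered named numeric vector.
#' @export
build_feature_set <- function(row, set_id, selection = NULL) {
  if (is.data.frame(row)) {
    row <- unlist(row[1, setdiff(names(row), c("id", "species", "split")),
                      drop = FALSE])
  }
  wanted <- feature_set_names(set_id, selection)
  missing <- setdiff(wanted, names(row))
  if (length(missing) > 0) {
    stop_schema(sprintf("feature(s) missing from table: %s",
                        paste(missing, collapse = ", ")))
  }
  row[wanted]
}

#' All clip-level features for one audio clip
#'
#' Runs the full descriptor stack (optionally preceded by
#' spectral-subtraction denoising) and returns the canonical 140-feature
#' named vector described in the package vignette.
#'
#' @param clip an [audio_clip()].
#' @param fspec a [frame_spec()].
#' @param denoise_first apply [denoise()] before analysis.
#' @return a named numeric vector of 140 features.
#' @export
extract_clip_features <- function(clip, fspec = frame_spec(),
                                  denoise_first = FALSE) {
  if (denoise_first) clip <- denoise(clip, fspec = fspec)
  spect <- spectrogram(clip, fspec)
  th <- tempo_harmonics(clip, fspec)
  out <- c(
    summarize_features(spectral_descriptors(spect, clip)),
    harmonic_ratio = th$harmonic_ratio,
    tempo_bpm = th$tempo_bpm,
    summarize_features(chroma(spect)),
    summarize_features(mfcc_block(spect)),
    summarize_features(gfcc_block(clip, fspec = fspec))
  )
  out[c(feature_set_names("SET1"), feature_set_names("SET2"),
        feature_set_names("SET3"))]
}

#' Extract a feature table for every clip in a manifest
#'
#' Clips longer than `segment_seconds` are cut into fixed-length segments
#' ([segment()]) and the per-segment feature vectors are averaged, so each
#' manifest row yields exactly one feature row.
#'
#' @param manifest a manifest data.frame from [read_manifest()] or
#'   [generate_dataset()].
#' @param fspec a [frame_spec()].
#' @param denoise_first apply spectral subtraction before analysis.
#' @param segment_seconds fixed segmentation length, seconds.
#' @return a data.frame: `id`, 140 feature columns, `species`, `split`.
#' @export
extract_features <- function(manifest, fspec = frame_spec(),
                             denoise_first = FALSE, segment_seconds = 5) {
  validate_manifest(manifest)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    path <- manifest_path(manifest, manifest$audio_path[i])
    if (!file.exists(path)) {
      stop_io(sprintf("audio file missing for id %s: %s", manifest$id[i], path))
    }
    clip <- load_wav(path)
    segs <- segment(clip, segment_seconds)
    feats <- rowMeans(vapply(
      segs, extract_clip_features, numeric(140),
      fspec = fspec, denoise_first = denoise_first))
    feats
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(id = manifest$id, stringsAsFactors = FALSE),
        out,
        data.frame(species = manifest$species, split = manifest$split,
                   stringsAsFactors = FALSE))
}

#' Write / read a feature table CSV
#'
#' One row per clip; header holds the feature names with `species` (and
#' bookkeeping columns) last.
#'
#' @param features a feature data.frame from [extract_features()].
#' @param path CSV path.
#' @return `path` (write) or the feature data.frame (read).
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("feature table not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"species" %in% names(df)) stop_schema("feature table lacks a species column")
  df
}
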