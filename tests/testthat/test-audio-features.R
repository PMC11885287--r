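test_that("spectrogram matches a direct DFT oracle", {
  set.seed(31)
  clip <- audio_clip(stats::rnorm(4000, 0, 0.3), 8000)
  fs <- frame_spec(512L, 128L)
  sp <- spectrogram(clip, fs)
  expect_equal(ncol(sp$magnitudes), 512 / 2 + 1)
  expect_equal(sp$bin_freqs[1], 0)
  expect_equal(sp$bin_freqs[length(sp$bin_freqs)], 4000)
  for (fi in c(2L, 9L, 20L)) {
    fr <- oracle_frame(clip$samples, 512L, 128L, fi) * oracle_hann(512L)
    expect_lt(max(abs(sp$magnitudes[fi, ] - oracle_dft_mag(fr))) /
                max(sp$magnitudes[fi, ]), 1e-6)
  }
  # silence in, silence out
  zero <- audio_clip(numeric(4000) + 0, 8000)
  expect_true(all(spectrogram(zero, fs)$magnitudes == 0))
  expect_error(spectrogram(audio_clip(1:10 / 10, 8000), fs),
               class = "avifuse_invalid_input")
})

test_that("a pure tone peaks at the right bin in every frame", {
  clip <- sine_clip(1000, sr = 22050, seconds = 0.6)
  sp <- spectrogram(clip, frame_spec())
  target_bin <- which.min(abs(sp$bin_freqs - 1000))
  peaks <- apply(sp$magnitudes, 1, which.max)
  expect_true(all(abs(peaks - target_bin) <= 1))
})

test_that("spectral subtraction suppresses stationary noise, keeps tones", {
  set.seed(71)
  noise <- audio_clip(stats::rnorm(16000, 0, 0.2), 8000)
  out <- denoise(noise, fspec = frame_spec(1024L, 256L))
  expect_length(out$samples, 16000)
  expect_lt(sqrt(mean(out$samples^2)), 0.25 * sqrt(mean(noise$samples^2)))

  # all-zero clip stays zero
  silent <- audio_clip(numeric(8000) + 0, 8000)
  expect_lt(max(abs(denoise(silent, fspec = frame_spec(1024L, 256L))$samples)),
            1e-12)

  # 0.5 s silence then a tone: tone-band energy preserved within 3 dB
  sr <- 8000
  tone <- c(numeric(sr / 2), sin(2 * pi * 750 * (0:(sr - 1)) / sr) * 0.5)
  clip <- audio_clip(tone, sr)
  den <- denoise(clip, noise_seconds = 0.5, fspec = frame_spec(1024L, 256L))
  band_energy <- function(x) {
    L <- 1024L
    fr <- oracle_frame(x, L, 256L, 20L) * oracle_hann(L)   # inside the tone
    mag <- oracle_dft_mag(fr)
    f <- (0:(L / 2)) * sr / L
    sum(mag[abs(f - 750) < 40]^2)
  }
  ratio_db <- 10 * log10(band_energy(den$samples) / band_energy(clip$samples))
  expect_lt(abs(ratio_db), 3)
  expect_error(denoise(audio_clip(1:100 / 100, 8000), noise_seconds = 0.5),
               class = "avifuse_invalid_input")
})

test_that("segmentation follows the pad/drop rules and conserves samples", {
  sr <- 1000
  mk <- function(seconds) audio_clip(seq_len(seconds * sr) / (seconds * sr), sr)
  s12 <- segment(mk(12), 5)
  expect_length(s12, 3)
  expect_true(all(vapply(s12, function(c) length(c$samples), 0L) == 5 * sr))
  expect_true(all(s12[[3]]$samples[(2 * sr + 1):(5 * sr)] == 0))

  expect_length(segment(mk(10.5), 5), 2)
  s3 <- segment(mk(3), 5)
  expect_length(s3, 1)
  expect_length(s3[[1]]$samples, 5 * sr)

  # concatenating unpadded contents reproduces a prefix of the input
  x <- mk(12)
  recon <- unlist(lapply(s12, `[[`, "samples"))[seq_len(12 * sr)]
  expect_identical(recon, x$samples)
})

test_that("MFCC block implements the stated cepstral transform", {
  clip <- fixture("mfcc_clip", function() {
    set.seed(17)
    audio_clip(stats::rnorm(16000, 0, 0.2) +
                 sin(2 * pi * 900 * (0:15999) / 16000), 16000)
  })
  fs <- frame_spec(1024L, 512L)
  sp <- spectrogram(clip, fs)
  mb <- mfcc_block(sp)
  expect_equal(ncol(mb), 39)
  expect_equal(colnames(mb)[c(1, 14, 27)], c("mfcc_01", "mfcc_d01", "mfcc_dd01"))

  # literal term-by-term oracle on the log mel energies of one frame
  fb <- avifuse:::mel_filterbank(26L, sp$bin_freqs)
  logE <- log(pmax(as.vector(sp$magnitudes[5, ]^2 %*% t(fb)), 1e-10))
  expect_lt(max(abs(mb[5, 1:13] - oracle_cepstrum(logE, 13))), 1e-8)

  # equal mel energies make every coefficient vanish
  expect_lt(max(abs(avifuse:::cepstral_dct(matrix(3.7, 1, 26), 13))), 1e-10)

  # global gain leaves static coefficients unchanged
  louder <- audio_clip(clip$samples * 10, clip$sample_rate)
  mb10 <- mfcc_block(spectrogram(louder, fs))
  expect_lt(max(abs(mb10[, 1:13] - mb[, 1:13])), 1e-6)

  expect_error(mfcc_block(sp, n_mels = 2000L),
               class = "avifuse_invalid_config")
  expect_error(mfcc_block(sp, n_mels = 20L, n_keep = 21L),
               class = "avifuse_invalid_config")
})

test_that("GFCC block has 13 columns and matches the direct transform", {
  set.seed(23)
  clip <- audio_clip(stats::rnorm(16000, 0, 0.1), 16000)
  fs <- frame_spec(1024L, 512L)
  g <- gfcc_block(clip, fspec = fs)
  expect_equal(ncol(g), 13)

  # oracle: direct cosine transform of the measured compressed band energies
  sp <- spectrogram(clip, fs)
  fb <- avifuse:::gammatone_filterbank(26L, sp$bin_freqs, 50, 0.95 * 8000)
  comp <- (as.vector(sp$magnitudes[7, ]^2 %*% t(fb)))^(1 / 3)
  expect_lt(max(abs(g[7, ] - oracle_cepstrum(comp, 13))), 1e-8)

  # silence gives constant (zero) coefficients across frames
  gs <- gfcc_block(audio_clip(numeric(16000) + 0, 16000), fspec = fs)
  expect_true(all(apply(gs, 2, function(col) max(col) - min(col)) < 1e-12))
})

test_that("spectral descriptors follow their definitions", {
  # hand-built spectrogram with one nonzero bin at 1000 Hz
  sp <- structure(list(
    magnitudes = matrix(c(0, 1, 0, 0), 1, 4),
    bin_freqs = c(0, 1000, 2000, 3000),
    frame_times = 0, sample_rate = 6000,
    frame_spec = frame_spec(6L, 3L)), class = "Spectrogram")
  clip <- audio_clip(rep(c(1, -1), 6), 6000)
  d <- spectral_descriptors(sp, clip)
  expect_equal(unname(d[1, "centroid"]), 1000)
  expect_equal(unname(d[1, "bandwidth"]), 0)
  expect_equal(unname(d[1, "rolloff"]), 1000)
  expect_equal(unname(d[1, "flux"]), 0)

  # zcr: alternating frame -> 1, constant frame -> 0
  fs <- frame_spec(64L, 64L)
  alt <- audio_clip(rep(c(1, -1), 256), 8000)
  d_alt <- spectral_descriptors(spectrogram(alt, fs), alt)
  expect_true(any(d_alt[, "zcr"] == 1))
  const <- audio_clip(rep(0.5, 512), 8000)
  d_const <- spectral_descriptors(spectrogram(const, fs), const)
  expect_true(all(d_const[, "zcr"] == 0))

  # pure 1 kHz tone: centroid within a bin width of 1 kHz on voiced frames
  tone <- sine_clip(1000, 22050, 0.5)
  spt <- spectrogram(tone, frame_spec())
  dt <- spectral_descriptors(spt, tone)
  bin_width <- 22050 / 2048
  mid <- 5:(nrow(dt) - 5)
  expect_true(all(abs(dt[mid, "centroid"] - 1000) < 2 * bin_width))

  # silence conventions: everything defined and zero
  zs <- audio_clip(numeric(2048) + 0, 8000)
  dz <- spectral_descriptors(spectrogram(zs, frame_spec(512L, 256L)), zs)
  expect_true(all(is.finite(dz)))
  expect_true(all(dz == 0))
})

test_that("chroma folds energy onto pitch classes with octave equivalence", {
  sp440 <- spectrogram(sine_clip(440, 22050, 0.4), frame_spec())
  ch440 <- chroma(sp440)
  expect_equal(ncol(ch440), 12)
  dom440 <- colnames(ch440)[max.col(ch440, ties.method = "first")]
  expect_true(all(dom440 == "chroma_A"))
  expect_true(all(abs(apply(ch440, 1, max) - 1) < 1e-12))

  ch880 <- chroma(spectrogram(sine_clip(880, 22050, 0.4), frame_spec()))
  expect_true(all(colnames(ch880)[max.col(ch880, ties.method = "first")] ==
                    "chroma_A"))

  silent <- audio_clip(numeric(22050) + 0, 22050)
  expect_true(all(chroma(spectrogram(silent, frame_spec())) == 0))
})

test_that("tempo and harmonicity behave on constructed signals", {
  # 2 Hz click train -> 120 BPM within 5%
  sr <- 8000
  x <- numeric(4 * sr)
  x[seq(1, length(x), by = sr / 2)] <- 1
  th <- tempo_harmonics(audio_clip(x, sr), frame_spec(512L, 128L))
  expect_lt(abs(th$tempo_bpm - 120) / 120, 0.05)

  # pure sine has (almost) no harmonic energy
  th_sine <- tempo_harmonics(sine_clip(1000, 8000, 2), frame_spec(1024L, 256L))
  expect_lt(th_sine$harmonic_ratio, 0.05)

  # a noise-free synthetic call carries its 3-harmonic stack
  cfg <- synth_config(n_classes = 2, n_per_class = 1, sample_rate = 16000,
                      clip_seconds = 2, image_size = 32, snr_db = Inf,
                      class_separation = 1, seed = 2)
  call <- render_call(species_spec("h", 800, chirp_rate = 100), cfg, seed = 3)
  th_call <- tempo_harmonics(call, frame_spec(1024L, 256L))
  expect_gt(th_call$harmonic_ratio, 0.2)

  expect_error(tempo_harmonics(audio_clip(numeric(100) + 0, 8000)),
               class = "avifuse_invalid_input")
})

test_that("summaries are exact means and population stds", {
  expect_equal(unname(summarize_features(matrix(4.2, 10, 1))), c(4.2, 0))
  one <- summarize_features(matrix(c(1.5, 2.5), 1, 2,
                                   dimnames = list(NULL, c("a", "b"))))
  expect_equal(unname(one), c(1.5, 0, 2.5, 0))
  expect_equal(names(one), c("a_mean", "a_std", "b_mean", "b_std"))

  set.seed(4)
  m <- matrix(stats::rnorm(60), 20, 3, dimnames = list(NULL, c("x", "y", "z")))
  s <- summarize_features(m)
  for (j in 1:3) {
    o <- oracle_mean_std(m[, j])
    expect_lt(abs(s[[paste0(colnames(m)[j], "_mean")]] - o["mean"]), 1e-10)
    expect_lt(abs(s[[paste0(colnames(m)[j], "_std")]] - o["std"]), 1e-10)
  }
})

test_that("feature sets assemble with the documented widths and order", {
  feats <- fixture_features()
  row <- feats[1, ]
  expect_length(build_feature_set(row, "SET1"), 10)
  s2 <- build_feature_set(row, "SET2")
  expect_length(s2, 2 + 24 + 78)
  expect_equal(names(s2)[1:2], c("harmonic_ratio", "tempo_bpm"))
  expect_length(build_feature_set(row, "SET3"), 26)

  sel <- select_top_k(class_correlation(feats), 21)
  s4 <- build_feature_set(row, "SET4", sel)
  expect_length(s4, 21)
  expect_identical(names(s4), sel$selected)
  expect_error(build_feature_set(row, "SET4"), class = "avifuse_schema_error")
  expect_error(build_feature_set(row, "SET9"), class = "avifuse_schema_error")
  dropped <- row[, setdiff(names(row), "centroid_mean")]
  expect_error(build_feature_set(dropped, "SET1"),
               class = "avifuse_schema_error")
  expect_error(build_feature_set(dropped, "SET1"), regexp = "centroid_mean")
})

test_that("all 140 features are finite for silence and for real clips", {
  silent <- audio_clip(numeric(32000) + 0, 16000)
  fs <- silent
  f <- extract_clip_features(fs, frame_spec(1024L, 512L))
  expect_length(f, 140)
  expect_true(all(is.finite(f)))
  feats <- fixture_features()
  numeric_cols <- setdiff(names(feats), c("id", "species", "split"))
  expect_equal(length(numeric_cols), 140)
  expect_true(all(vapply(feats[numeric_cols],
                         function(col) all(is.finite(col)), TRUE)))
})
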