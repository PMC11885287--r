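# Shared fixtures, built once per test run and cached in an environment.
# Everything is generated in code under tempdir(); nothing binary ships
# with the package.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  got <- .fixture_cache[[name]]
  if (!is.null(got)) return(got)
  val <- builder()
  .fixture_cache[[name]] <- val
  val
}

# Small, fast synthesis settings used throughout the suite: 16 kHz keeps
# every default species (f0 up to ~4 kHz) safely below Nyquist while the
# 2 s clips keep the DSP cheap.
test_synth_config <- function(n_classes = 3L, n_per_class = 10L,
                              class_separation = 1, snr_db = 15,
                              seed = 101L, image_size = 32L) {
  synth_config(n_classes = n_classes, n_per_class = n_per_class,
               sample_rate = 16000, clip_seconds = 2,
               image_size = image_size, snr_db = snr_db,
               class_separation = class_separation, seed = seed)
}

# A generated on-disk dataset (3 classes x 10) shared by pipeline tests.
fixture_dataset <- function() {
  fixture("dataset", function() {
    dir <- file.path(tempdir(), "avifuse_ds")
    cfg <- test_synth_config()
    manifest <- generate_dataset(cfg, dir)
    list(dir = dir, config = cfg, manifest = manifest)
  })
}

fixture_features <- function() {
  fixture("features", function() {
    ds <- fixture_dataset()
    extract_features(ds$manifest)
  })
}

# Complementary-information dataset: within one species pair only audio
# differs, within the other only the image differs.
fixture_comp_dataset <- function(seed = 11L) {
  fixture(paste0("comp", seed), function() {
    dir <- file.path(tempdir(), paste0("avifuse_comp", seed))
    specs <- make_complementary_specs(2L, seed = seed)
    cfg <- synth_config(n_classes = 4L, n_per_class = 14L,
                        sample_rate = 8000, clip_seconds = 2,
                        image_size = 32L, snr_db = 15,
                        class_separation = 1, seed = seed)
    manifest <- generate_dataset(cfg, dir, specs = specs)
    items <- load_multimodal(manifest, 32L, max_frames = 30L)
    list(dir = dir, config = cfg, manifest = manifest, items = items)
  })
}

test_accuracy <- function(model, items) {
  P <- predict_probs(model, items)
  truth <- vapply(items, `[[`, "", "species")
  mean(model$classes[max.col(P, ties.method = "first")] == truth)
}

# A 1 s unit sine clip.
sine_clip <- function(freq, sr = 22050, seconds = 1, amp = 1) {
  t <- (0:(sr * seconds - 1)) / sr
  audio_clip(amp * sin(2 * pi * freq * t), sr)
}

# Write an interleaved stereo PCM16 WAV (the package writer is mono-only).
write_stereo_wav <- function(left, right, sr, path) {
  pcm <- as.integer(round(as.vector(rbind(left, right)) * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(c(1L, 2L), con, size = 2L, endian = "little")
  writeBin(as.integer(sr), con, size = 4L, endian = "little")
  writeBin(as.integer(sr) * 4L, con, size = 4L, endian = "little")
  writeBin(c(4L, 16L), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  path
}
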