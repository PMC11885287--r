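# Synthetic multimodal dataset generator.
#
# Stands in for a field dataset of bird photographs and call recordings:
# each species is assigned a fundamental frequency, chirp slope and syllable
# pattern for its call, and a hue/body-shape for its image. Calls are
# 3-harmonic linear-FM syllable trains in white noise at a configurable SNR;
# images are a coloured ellipse "body" on a noisy grey background. Class
# separation is a single knob that controls both acoustic f0 jitter and
# image pixel noise.

#' Synthetic dataset configuration
#'
#' @param n_classes number of species (>= 2).
#' @param n_per_class clips/images generated per species.
#' @param sample_rate audio sampling rate in Hz.
#' @param clip_seconds duration of each call clip in seconds.
#' @param image_size side length of the square RGB images, pixels (>= 32).
#' @param snr_db signal-to-noise ratio of the calls in dB (RMS over the
#'   whole clip); `Inf` disables noise.
#' @param class_separation in `[0, 1]`; 1 gives maximally distinct,
#'   noise-free classes, lower values add f0 jitter and pixel noise.
#' @param seed integer seed; identical configs produce byte-identical data.
#' @return a `SynthConfig` list.
#' @export
synth_config <- function(n_classes = 8L, n_per_class = 10L,
                         sample_rate = 22050, clip_seconds = 5,
                         image_size = 224L, snr_db = 10,
                         class_separation = 0.8, seed = 1L) {
  if (!is_count(n_classes, 2L)) {
    stop_invalid_config("n_classes must be an integer >= 2")
  }
  if (!is_count(n_per_class, 1L)) {
    stop_invalid_config("n_per_class must be a positive integer")
  }
  if (!is_count(image_size, 32L)) {
    stop_invalid_config("image_size must be an integer >= 32")
  }
  n_samp <- clip_seconds * sample_rate
  if (abs(n_samp - round(n_samp)) > 1e-9) {
    stop_invalid_config("clip_seconds * sample_rate must be an integer sample count")
  }
  if (!is_num(class_separation) || class_separation < 0 || class_separation > 1) {
    stop_invalid_config("class_separation must lie in [0, 1]")
  }
  if (!(is_num(snr_db) || identical(snr_db, Inf))) {
    stop_invalid_config("snr_db must be a number or Inf")
  }
  structure(list(
    n_classes = as.integer(n_classes), n_per_class = as.integer(n_per_class),
    sample_rate = sample_rate, clip_seconds = clip_seconds,
    image_size = as.integer(image_size), snr_db = snr_db,
    class_separation = class_separation, seed = as.integer(seed)
  ), class = "SynthConfig")
}

#' Deterministic species specifications
#'
#' Assigns each species a call and plumage template. Fundamentals are
#' log-spaced over 500-4000 Hz and then jittered multiplicatively with a
#' spread proportional to `1 - class_separation` (no jitter at full
#' separation); hues are evenly spaced on the colour circle.
#'
#' @param n_classes number of species (>= 2).
#' @param class_separation in `[0, 1]`.
#' @param seed integer seed.
#' @return a list of `SpeciesSpec` lists with fields `name`, `f0`,
#'   `chirp_rate`, `n_syllables`, `syllable_dur`, `hue`, `body_aspect`.
#' @export
make_species_specs <- function(n_classes, class_separation = 0.8, seed = 1L) {
  if (!is_count(n_classes, 2L)) {
    stop_invalid_config("n_classes must be an integer >= 2")
  }
  if (!is_num(class_separation) || class_separation < 0 || class_separation > 1) {
    stop_invalid_config("class_separation must lie in [0, 1]")
  }
  f0 <- exp(seq(log(500), log(4000), length.out = n_classes))
  with_seed(derive_seed(seed, "species_specs"), {
    jitter_sd <- 0.08 * (1 - class_separation)
    if (jitter_sd > 0) f0 <- f0 * exp(stats::rnorm(n_classes, 0, jitter_sd))
    hues <- (seq_len(n_classes) - 1) * 360 / n_classes
    lapply(seq_len(n_classes), function(k) {
      species_spec(
        name = sprintf("species_%02d", k),
        f0 = f0[k],
        chirp_rate = stats::runif(1, -400, 400),
        n_syllables = sample(3:6, 1),
        syllable_dur = stats::runif(1, 0.15, 0.35),
        hue = hues[k],
        body_aspect = stats::runif(1, 0.4, 0.9)
      )
    })
  })
}

#' @rdname make_species_specs
#' @param name species name (unique within a dataset).
#' @param f0 fundamental frequency of call syllables, Hz.
#' @param chirp_rate linear FM slope, Hz/s.
#' @param n_syllables syllables per clip.
#' @param syllable_dur syllable duration, seconds.
#' @param hue body hue in degrees `[0, 360)`.
#' @param body_aspect ellipse minor/major axis ratio.
#' @export
species_spec <- function(name, f0, chirp_rate = 0, n_syllables = 4L,
                         syllable_dur = 0.25, hue = 0, body_aspect = 0.6) {
  if (!is_num(f0) || f0 <= 0) stop_invalid_config("f0 must be positive")
  structure(list(name = name, f0 = f0, chirp_rate = chirp_rate,
                 n_syllables = as.integer(n_syllables),
                 syllable_dur = syllable_dur,
                 hue = hue %% 360, body_aspect = body_aspect),
            class = "SpeciesSpec")
}

#' Species specs with complementary visual/acoustic information
#'
#' Builds `2 * n_pairs` species arranged so that, within each pair, one
#' axis is uninformative: pairs at odd positions share their hue (only the
#' call separates them) and pairs at even positions share their call
#' template (only the image separates them). Used to probe what each
#' modality, and their fusion, can and cannot resolve.
#'
#' @param n_pairs number of species pairs.
#' @param seed integer seed.
#' @return list of `SpeciesSpec`.
#' @export
make_complementary_specs <- function(n_pairs = 2L, seed = 1L) {
  if (!is_count(n_pairs, 1L)) stop_invalid_config("n_pairs must be >= 1")
  n <- 2L * n_pairs
  base <- make_species_specs(n, class_separation = 1, seed = seed)
  for (p in seq_len(n_pairs)) {
    i <- 2L * p - 1L
    j <- 2L * p
    if (p %% 2L == 1L) {                       # visually identical twins
      base[[j]]$hue <- base[[i]]$hue
      base[[j]]$body_aspect <- base[[i]]$body_aspect
    } else {                                   # acoustically identical twins
      base[[j]]$f0 <- base[[i]]$f0
      base[[j]]$chirp_rate <- base[[i]]$chirp_rate
      base[[j]]$n_syllables <- base[[i]]$n_syllables
      base[[j]]$syllable_dur <- base[[i]]$syllable_dur
    }
  }
  base
}

#' Render one synthetic call clip
#'
#' The call is `n_syllables` harmonic stacks (3 harmonics with amplitudes
#' 1, 1/2, 1/3) sweeping linearly from `f0` at `chirp_rate` Hz/s, evenly
#' spaced along the clip and separated by silence, mixed with white
#' Gaussian noise at `snr_db` (RMS over the whole clip). The mix is
#' peak-normalized to 0.9. Harmonics whose frequency trajectory would cross
#' Nyquist are omitted; a fundamental crossing Nyquist is an error.
#'
#' @param spec a `SpeciesSpec`.
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return an [audio_clip()] of exactly `clip_seconds`.
#' @export
render_call <- function(spec, config, seed = config$seed) {
  stopifnot(inherits(spec, "SpeciesSpec"), inherits(config, "SynthConfig"))
  sr <- config$sample_rate
  nyq <- sr / 2
  f_end <- spec$f0 + spec$chirp_rate * spec$syllable_dur
  if (max(spec$f0, f_end) >= nyq || min(spec$f0, f_end) <= 0) {
    stop_invalid_config(sprintf(
      "fundamental sweep %.0f..%.0f Hz exceeds (0, Nyquist=%.0f) for %s",
      spec$f0, f_end, nyq, spec$name))
  }
  n <- as.integer(round(config$clip_seconds * sr))
  x <- numeric(n)
  n_syl <- spec$n_syllables
  syl_n <- as.integer(round(spec$syllable_dur * sr))
  slot <- n / n_syl
  t_syl <- (seq_len(syl_n) - 1) / sr
  inst_f <- spec$f0 + spec$chirp_rate * t_syl
  phase <- 2 * pi * cumsum(inst_f) / sr
  syl <- numeric(syl_n)
  for (h in 1:3) {
    if (h * max(inst_f) < nyq * 0.999) syl <- syl + sin(h * phase) / h
  }
  ramp_n <- min(as.integer(0.005 * sr), syl_n %/% 4L)
  if (ramp_n > 0) {                       # 5 ms raised-cosine on/offset ramps
    env <- rep(1, syl_n)
    r <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
    env[seq_len(ramp_n)] <- r
    env[syl_n + 1 - seq_len(ramp_n)] <- r
    syl <- syl * env
  }
  for (s in seq_len(n_syl)) {
    start <- as.integer(round((s - 1) * slot + (slot - syl_n) / 2)) + 1L
    idx <- start:(start + syl_n - 1L)
    keep <- idx >= 1L & idx <= n
    x[idx[keep]] <- x[idx[keep]] + syl[keep]
  }
  with_seed(derive_seed(seed, "call", spec$name), {
    if (is.finite(config$snr_db)) {
      rms_sig <- sqrt(mean(x^2))
      rms_noise <- rms_sig * 10^(-config$snr_db / 20)
      x <- x + stats::rnorm(n, 0, rms_noise)
    }
  })
  peak <- max(abs(x))
  if (peak > 0) x <- x * (0.9 / peak)
  audio_clip(x, sr)
}

# HSV (h in degrees, s, v in [0,1]) -> RGB matrix columns r,g,b
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  rgb <- switch(as.character(i %% 6),
    "0" = c(v, t, p), "1" = c(q, v, p), "2" = c(p, v, t),
    "3" = c(p, q, v), "4" = c(p, t, v), "5" = c(v, p, q))
  rgb
}

#' Render one synthetic bird image
#'
#' An ellipse "body" filled with the species hue (HSV s=0.75, v=0.85) on a
#' mid-grey background, with seeded position jitter and additive Gaussian
#' pixel noise whose standard deviation is `0.15 * (1 - class_separation)`.
#' Values are clipped to `[0, 1]`.
#'
#' @inheritParams render_call
#' @return an `image_size x image_size x 3` array in `[0, 1]`.
#' @export
render_image <- function(spec, config, seed = config$seed) {
  stopifnot(inherits(spec, "SpeciesSpec"), inherits(config, "SynthConfig"))
  sz <- config$image_size
  with_seed(derive_seed(seed, "image", spec$name), {
    img <- array(0.5, dim = c(sz, sz, 3))
    cx <- sz / 2 + stats::runif(1, -0.1, 0.1) * sz
    cy <- sz / 2 + stats::runif(1, -0.1, 0.1) * sz
    a <- 0.30 * sz                       # semi-major axis
    b <- a * spec$body_aspect
    xs <- matrix(seq_len(sz), sz, sz)
    ys <- t(xs)
    inside <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
    col <- hsv_to_rgb(spec$hue, 0.75, 0.85)
    for (c in 1:3) {
      ch <- img[, , c]
      ch[inside] <- col[c]
      img[, , c] <- ch
    }
    noise_sd <- 0.15 * (1 - config$class_separation)
    if (noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim = dim(img))
    }
    img[] <- pmin(1, pmax(0, img))
    img
  })
}

split_counts <- function(n) {
  n_tr <- floor(0.7 * n)
  n_val <- floor(0.15 * n)
  n_te <- floor(0.15 * n)
  n_tr <- n - n_val - n_te                  # remainder goes to train
  c(train = n_tr, val = n_val, test = n_te)
}

#' Generate a full synthetic multimodal dataset on disk
#'
#' Writes one 16-bit PCM WAV and one PNG per item under `out_dir/audio` and
#' `out_dir/images`, plus `manifest.csv`. The split is stratified per class:
#' a deterministic seeded shuffle followed by a contiguous 70/15/15 cut,
#' with remainders assigned to train.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created if absent).
#' @param specs optional list of `SpeciesSpec` overriding the default
#'   [make_species_specs()] call (must have length `n_classes`).
#' @return the manifest as a data.frame
#'   (`id, species, image_path, audio_path, split`), paths relative to
#'   `out_dir`.
#' @export
generate_dataset <- function(config, out_dir, specs = NULL) {
  stopifnot(inherits(config, "SynthConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_io(sprintf("cannot create directory: %s", out_dir))
  for (d in file.path(out_dir, c("audio", "images"))) {
    dir.create(d, showWarnings = FALSE)
  }
  if (is.null(specs)) {
    specs <- make_species_specs(config$n_classes, config$class_separation,
                                config$seed)
  }
  if (length(specs) != config$n_classes) {
    stop_invalid_config("length(specs) must equal n_classes")
  }
  if (anyDuplicated(vapply(specs, `[[`, "", "name"))) {
    stop_invalid_config("species names must be unique")
  }
  rows <- vector("list", config$n_classes * config$n_per_class)
  r <- 0L
  for (k in seq_len(config$n_classes)) {
    spec <- specs[[k]]
    n <- config$n_per_class
    cnt <- split_counts(n)
    ord <- with_seed(derive_seed(config$seed, "split", spec$name),
                     sample.int(n))
    split <- character(n)
    split[ord] <- rep(c("train", "val", "test"), times = cnt)
    for (i in seq_len(n)) {
      id <- sprintf("%s_%03d", spec$name, i)
      wav_rel <- file.path("audio", paste0(id, ".wav"))
      png_rel <- file.path("images", paste0(id, ".png"))
      item_seed <- derive_seed(config$seed, "item", spec$name, i)
      clip <- render_call(spec, config, seed = item_seed)
      img <- render_image(spec, config, seed = item_seed)
      write_wav(clip, file.path(out_dir, wav_rel))
      png::writePNG(img, file.path(out_dir, png_rel))
      r <- r + 1L
      rows[[r]] <- data.frame(id = id, species = spec$name,
                              image_path = png_rel, audio_path = wav_rel,
                              split = split[i], stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  attr(manifest, "root") <- normalizePath(out_dir)
  manifest
}
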