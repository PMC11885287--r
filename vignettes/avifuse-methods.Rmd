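---
title: "avifuse: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{avifuse: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Automated bird species identification from field data has two natural
information channels — what the bird looks like and what it sounds like —
and each fails in a different way: images degrade with light, occlusion and
plumage mimicry; calls degrade with habitat noise and vocal similarity.
`avifuse` implements a complete desk-scale pipeline for *multimodal*
species classification and for a controlled comparison of the two standard
fusion strategies, early (feature-level) and late (decision-level) fusion,
together with the unimodal baselines they are measured against.

This vignette documents the models, the tunable parameters and their
defaults, the synthetic data the tests run on, the numerical choices, and
the places where the design was genuinely open and a decision had to be
made. It states no empirical result that the package's test suite or
acceptance script does not itself compute.

# The acoustic front end

All audio is mono, amplitude in $[-1, 1]$. The analysis unit is a
**spectrogram**: centered frames (mirror-reflect padding), periodic Hann
window, magnitude DFT. Defaults are frame length 2048 and hop 512 at
22.05 kHz — the de facto bioacoustics settings; the source text does not
specify framing, so these are package defaults, exposed via `frame_spec()`.

Preprocessing follows the conventional recipe:

- **Spectral subtraction.** The noise magnitude spectrum is the mean over
  the first `noise_seconds` (default 0.5 s); `oversubtract` times that
  spectrum (default 2) is subtracted from every frame, floored at
  `floor_beta` (default 0.01) times the noise spectrum, and the original
  phase is kept for the inverse transform. Plain subtraction of the mean
  removes only the *mean* of the Rayleigh-distributed noise magnitudes and
  leaves roughly a third of the noise RMS; the standard over-subtraction
  factor fixes that while leaving tonal content intact (a tone preceded by
  silence keeps its band energy within 3 dB — both properties are tested).
  `oversubtract = 1` recovers the literal textbook formula.
- **Segmentation** into non-overlapping 5-s windows; a trailing remainder
  of at least 1 s is zero-padded and kept, shorter remainders are dropped,
  and a short clip yields exactly one padded segment.

Per-frame descriptors (all definitions tested against direct-summation
oracles):

- **MFCC block (39 columns).** Triangular mel filterbank (26 filters,
  HTK mel scale, 0 Hz–Nyquist) on the power spectrum; natural log floored
  at $10^{-10}$; then the cepstral cosine transform
  $c_m = \sum_{n=1}^{N} X_n \cos[m (n - \tfrac12)\pi/N]$ with $X_n$ the log
  energies, $N = 26$ and $m = 1..13$; finally first and second temporal
  differences (centered, replicated edges) giving $3 \times 13 = 39$
  features. With $m \ge 1$ the transform annihilates constant offsets, so
  the static coefficients are exactly invariant to global gain.
- **GFCC block (13 columns).** ERB-spaced 4th-order gammatone filterbank
  (50 Hz to 0.95 × Nyquist, bandwidth $1.019\,\mathrm{ERB}(f_c)$),
  cube-root amplitude compression, same cosine transform. This is the
  established gammatone-cepstrum construction; the source names the
  feature but gives no formula.
- **Spectral descriptors.** Centroid $\sum fS/\sum S$; bandwidth
  $\sqrt{\sum S (f-c)^2 / \sum S}$; rolloff at 85% cumulative magnitude;
  flux as the norm of positive magnitude increments; zero-crossing rate on
  the identically framed waveform. Silent frames take the value 0 — a
  convention the source leaves open; 0 keeps every feature finite.
- **Chroma (12 columns).** Bin energies folded to pitch classes, A4 =
  440 Hz, nearest semitone, bins below 50 Hz ignored, per-frame normalized
  to unit maximum.
- **Tempo and harmonicity.** Tempo from the highest raw autocorrelation
  peak of the onset envelope (positive frame-energy increments) over lags
  0.25–2 s; harmonic ratio as the energy fraction within ±3% of the 2nd
  and 3rd multiples of the per-frame peak frequency, averaged over voiced
  frames (≥5% of the maximum frame energy).

**Clip-level summarization.** The source feeds "per-clip features" to its
classifier without stating an aggregation; the package uses mean and
population standard deviation per dimension, named `<feature>_mean` /
`<feature>_std` in a fixed documented order. The full table has
140 features: SET1 (5 descriptors × 2 = 10), SET2 (harmonic ratio, tempo,
12 chroma × 2, 39 MFCC × 2 = 104), SET3 (13 GFCC × 2 = 26). The
"Perceptual Shock Wave" feature named in the source's feature-set table has
no definition there or in the literature and is excluded; `summarize` and
`build_feature_set` accept any extra user-computed columns, which is the
hook for supplying one.

# Feature selection

Correlation-based feature selection: for each feature, the Pearson
correlation against each one-vs-rest class indicator; the score is the
maximum absolute value; zero-variance features score 0; the top
$k = 21$ (descending score, ties by ascending name for determinism) are
retained. The multiclass handling is the simplest faithful extension of
"correlation to the target species", and the selected features are assumed
to be drawn from the union of SET1–SET3 (the source does not say; SET2
alone already exceeds 21 dimensions, so a union read is the only coherent
one). Pearson correlation is scale-invariant, so whether features are
standardized first is immaterial.

# Encoders

**Visual.** Convolution is cross-correlation plus bias and activation
(deep-learning convention), max pooling takes per-window maxima, residual
blocks compute $y = F(x) + \mathrm{shortcut}(x)$ with an optional 1×1
projection. Two backbones share this machinery:

- `resnet50_ref`: conv 7×7/2 → max pool 3×3/2 → four bottleneck stages
  (3/4/6/3 blocks; 49 convolutional layers in total) → global average pool
  → one dense layer → a 2048-d embedding. The source names three different
  backbones in different sections; its layer-count/dimension table (49
  convs, one dense, 2048 features) fixes the reference as the
  ResNet-50-style embedder, so that is what the dimension-accounting
  acceptance test instantiates (untrained — pretrained weights are an
  optional import, never downloaded).
- `tiny`: two residual stages over 8/16 channels, configurable embedding
  width, cheap enough to *train* end-to-end on a CPU. Batch normalization
  is omitted in both (forward dimension checks do not need it; the tiny
  networks train fine without it at this scale).

Weights are seeded He-style normal ($\sigma = \sqrt{2/\text{fan-in}}$) for
conv/dense and uniform $\pm 1/\sqrt{H}$ for recurrent cells; every
initializer derives its stream from one global seed, so a config rebuilds
identical weights.

**Acoustic.** The reference encoder is an LSTM over MFCC frames: gates
$f, i, o$ and candidate $\tilde C$ computed from $[h_{t-1}, x_t]$,
$C_t = f_t C_{t-1} + i_t \tilde C_t$, $h_t = o_t \tanh C_t$, iterated from
zero state; the *final* hidden state (matching the "one dense layer after
the LSTM" accounting) passes through a dense head to the embedding
(reference 256-d — the source says "128 or 256", and only 256 makes the
fused size come out at 2048 + 256 = 2304). A GRU cell, scaled dot-product
attention and sinusoidal positional encodings are provided as optional
sequence-encoder building blocks, exactly as printed, but the LSTM is the
reference path.

# Fusion and classification

Early fusion concatenates visual-first: $F = [f_{visual}, f_{acoustic}]$;
the classifier is $\mathrm{softmax}(W_c F + b)$ and both encoders and head
are trained jointly by backpropagation. Late fusion trains a visual-only
and an acoustic-only classifier independently (same encoders, separate
heads) and combines posteriors as $\alpha p_{visual} + (1-\alpha)
p_{acoustic}$; $\alpha$ is picked on the validation split over the grid
$\{0, 0.05, \dots, 1\}$, smallest maximizer on ties. The grid step and tie
rule are package choices (the source only says $\alpha$ is optimized on
validation); including both endpoints guarantees validated late fusion is
never worse on the validation split than its better branch.

Training setups follow the stated configurations: the 21-feature MLP is
21 → 256 → 128 → 32 → K (ReLU, softmax, categorical cross-entropy, Adam
$10^{-4}$, batch 16, 75 epochs, L2 0.01 on the output layer weights —
the source says "four hidden layers" but lists three sizes; the three
listed sizes are used, with the output layer as the fourth counted layer,
and K comes from the data rather than the source's printed "nine nodes",
which matches its own 9-species illustration table rather than the full
dataset). The LSTM classifier uses RMSprop $10^{-3}$, batch 64. Fusion
models default to Adam $10^{-3}$, batch 8, 40 epochs — a desk-scale budget
chosen so the late-fusion acoustic expert reliably reaches its accuracy
ceiling on the synthetic data (under-training it was the one way the
robustness ordering test could fail for the wrong reason). Inputs to the
MLP are z-scored with training-split statistics stored in the model (the
source lists "feature scaling" among its preprocessing steps; without it
the mixed-unit features at scales from $10^{-2}$ to $10^{3}$ stall
training).

# Synthetic data: the stated world

The generator emulates the structure of a bird-call/image corpus without
any downloads:

- **Calls.** Each species has a fundamental $f_0$ (log-spaced over
  500–4000 Hz across species), a linear chirp slope (±400 Hz/s), 3–6
  syllables of 0.15–0.35 s, rendered as a 3-harmonic stack (amplitudes 1,
  1/2, 1/3) with 5-ms cosine ramps, placed evenly with silences, plus
  white Gaussian noise at a configurable clip-RMS SNR (default 10 dB);
  the mix is peak-normalized to 0.9. Harmonics whose trajectory would
  cross Nyquist are omitted rather than rejected: the stated $f_0$ range
  at the default 22.05 kHz rate puts the 3rd harmonic of the highest
  species above Nyquist, so a hard error would make the generator's own
  defaults invalid; only a fundamental leaving $(0, \mathrm{Nyquist})$ is
  an error.
- **Images.** A hue/aspect-coded ellipse on mid-grey, jittered position,
  additive Gaussian pixel noise with $\sigma = 0.15 (1 -
  \text{class\_separation})$, clipped to $[0,1]$.
- **`class_separation`** couples both modalities: 1.0 means noise-free
  images and unjittered $f_0$; lower values jitter $f_0$ multiplicatively
  and add pixel noise. A fixed nearest-centroid classifier's held-out
  accuracy is tested to be monotone between separations 1.0 and 0.2.
- **Splits.** Per class: seeded shuffle, contiguous 70/15/15 cut,
  remainders to train. Dataset, WAV, PNG and manifest bytes are identical
  under a fixed seed.
- **Complementary datasets** (`make_complementary_specs`): species pairs
  alternately share their image template (only the call separates them) or
  their call template (only the image separates them). With 2 pairs, each
  unimodal classifier has a 75% accuracy ceiling while fusion can reach
  100% — the construction behind the qualitative acceptance tests.

What a green test does and does not establish: the synthetic world has
exactly one vocalization per clip, stationary white noise, and perfectly
class-pure image cues; it contains none of the intra-species variability,
channel effects, overlapping vocalizers or label noise of field data.
Passing tests establish that the implementations compute their stated
quantities and that the fusion machinery recovers complementary
information *when it is present* — they say nothing about accuracy on any
real corpus, and the source's dataset-scale headline numbers are
deliberately not reproduced (external data, GPU-scale fine-tuning).

# Numerical choices

- Log floors at $10^{-10}$ (mel energies) and probability clipping at
  $10^{-12}$ before logarithms; softmax subtracts the row maximum.
- Population (not sample) standard deviation in clip summaries, so a
  single frame gives 0, not `NA`.
- Argmax ties break to the lowest index everywhere (predictions,
  rolloff bin, pooling backward).
- WAV is 16-bit PCM; samples encode as `round(x * 32768)` clamped to the
  int16 range so the write/read round trip stays within one quantization
  step (1/32768).
- Model archives store arrays as base64 little-endian float64 inside
  JSON, so save → load → predict is bit-identical; an xxhash64 payload
  digest warns on tampering, and a version field hard-errors on format
  mismatch.
- All randomness derives from one integer seed through a documented
  mixing function (`derive_seed`), keeping every derived seed below
  $2^{31}$; training loops, generators and augmentation are therefore
  bit-reproducible single-threaded.

# Known limitations

- No batch normalization or learning-rate schedules; the reference
  ResNet-50 is an untrained embedder unless weights are imported.
- The LSTM trains by full backpropagation through time in plain R:
  perfectly adequate at desk scale, far too slow for field-scale corpora.
- Spectral subtraction assumes the clip opens with representative noise;
  a syllable inside the first half second biases the noise profile.
- The robustness protocol covers additive white noise and
  missing-modality; it does not model reverberation, band-limited channel
  noise, or image corruption.
- `load_wav` reads PCM 8/16/24-bit and float32 RIFF files only (no
  compressed or extensible formats).
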