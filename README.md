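# avifuse

Visual–acoustic fusion for bird species classification, in R.

Field identification of birds is hard with either sense alone: plumage is
ambiguous in bad light and many species are visual near-twins, while calls
are buried in broadband habitat noise and some species are acoustic
near-twins. `avifuse` implements a complete multimodal pipeline that
classifies a bird from a photograph *and* a call recording, and compares the
two canonical ways of combining the modalities:

- **Early fusion** — concatenate the per-modality feature vectors into one
  vector, `F = [f_visual, f_acoustic]`, and train a single softmax
  classifier `y = softmax(W_c F + b)` on the joint representation.
- **Late fusion** — train independent visual and acoustic classifiers and
  average their posteriors, `p = α p_visual + (1 − α) p_acoustic`, with the
  weight `α ∈ [0, 1]` chosen on the validation split by grid search.

The visual branch is a residual CNN embedder (a ResNet-50-style reference
producing 2048-d embeddings, plus a tiny trainable variant), built from
first-principles conv / max-pool / residual blocks. The acoustic branch is
an LSTM over MFCC frames, whose final hidden state feeds a dense head
(reference 256-d), so the early-fused reference vector is 2304-d. All
forward *and* backward passes are implemented in plain R (im2col + BLAS),
which keeps training bit-reproducible under a fixed seed.

The package also contains the full bioacoustic feature stack used for a
features-only baseline: STFT spectrograms; 39 MFCC features (13 cepstra
computed as `c_m = Σ_n X_n cos[m (n − ½)π/N]` on log mel-filterbank
energies, plus Δ and ΔΔ); 13 gammatone cepstral coefficients (ERB-spaced
filterbank, cube-root compression); spectral centroid / bandwidth /
rolloff / flux and zero-crossing rate; 12 chroma bins; tempo and a
harmonicity ratio; spectral-subtraction denoising and fixed 5-s
segmentation. Correlation-based feature selection (max |Pearson r| against
one-vs-rest class indicators) retains the top *k* = 21 features, which feed
a 21 → 256 → 128 → 32 → K MLP (Adam 1e-4, batch 16, 75 epochs, L2 0.01 on
the output layer).

Because the real dataset (≈53 Indian species, with web-sourced images) is
external, the package ships a seeded **synthetic generator**: each species
gets a call template (3-harmonic linear-FM syllables in white noise at a
configurable SNR) and an image template (hue/shape-coded ellipse on a noisy
background), written as WAV + PNG + manifest CSV with a stratified 70/15/15
split. A `class_separation` knob controls how distinct species are, and
`make_complementary_specs()` builds datasets where one species pair is only
separable by ear and another only by eye — the regime where fusion provably
beats either modality.

## Worked example: features-only baseline

```r
library(avifuse)

cfg <- synth_config(n_classes = 4, n_per_class = 12, sample_rate = 16000,
                    clip_seconds = 2, image_size = 32, snr_db = 10,
                    class_separation = 0.9, seed = 42)
manifest <- generate_dataset(cfg, "demo_birds")
feats <- extract_features(manifest)
sel <- select_top_k(class_correlation(feats[feats$split == "train", ]), k = 21)
head(sel$selected)
#> [1] "gfcc_10_mean" "rolloff_mean" "rolloff_std"  "mfcc_13_std"
#> [5] "gfcc_12_mean" "gfcc_04_mean"

tr <- feats[feats$split == "train", ]
X  <- t(sapply(seq_len(nrow(tr)), function(i) build_feature_set(tr[i, ], "SET4", sel)))
mlp <- train_audio_mlp(X, tr$species, train_config("audio_mlp", seed = 42))

te  <- feats[feats$split == "test", ]
Xte <- t(sapply(seq_len(nrow(te)), function(i) build_feature_set(te[i, ], "SET4", sel)))
P <- predict_probs(mlp, Xte)
evaluate(mlp$classes[max.col(P, ties.method = "first")], te$species,
         classes = mlp$classes, probs = P)
#> accuracy 1.000 | macro P 1.000 R 1.000 F1 1.000 AUC 1.000
```

The selection ranks cepstral and rolloff summaries highest — the features
that track each species' fundamental frequency — and the 21-feature MLP
separates the four well-separated synthetic species perfectly. (The test
split here is 1 clip per class; this is a smoke-scale demonstration, not a
benchmark.)

## Worked example: when fusion matters

```r
specs <- make_complementary_specs(n_pairs = 2, seed = 11)  # 4 species:
# species 1/2 share their image, species 3/4 share their call
cfg <- synth_config(n_classes = 4, n_per_class = 14, sample_rate = 8000,
                    clip_seconds = 2, image_size = 32, snr_db = 15,
                    class_separation = 1, seed = 11)
manifest <- generate_dataset(cfg, "demo_comp", specs = specs)
items <- load_multimodal(manifest, image_size = 32)

early <- train_fusion(manifest, "early", train_config("early_fusion", seed = 3), items = items)
late  <- train_fusion(manifest, "late",  train_config("late_fusion",  seed = 3), items = items)
late$alpha
#> [1] 0.35

test_items <- items[sapply(items, `[[`, "split") == "test"]
truth <- sapply(test_items, `[[`, "species")
acc <- function(P, cl) mean(cl[max.col(P, ties.method = "first")] == truth)
acc(predict_probs(late, test_items, alpha = 1), late$classes)  # visual only
#> [1] 0.75
acc(predict_probs(early, test_items), early$classes)           # early fusion
#> [1] 1
acc(predict_probs(late, test_items), late$classes)             # late fusion
#> [1] 1
```

A visual-only classifier cannot exceed 75% here (one species pair is
visually identical), yet both fusion modes resolve all four classes. With
the visual modality removed at test time (`robustness_eval()` with
`drop_modality = "visual"`), the late-fusion model falls back to its
acoustic expert (α forced to 0) while early fusion has its visual slice
zero-filled; on this run early fusion lost 0.25 accuracy and late fusion
lost none — the "late fusion is the more robust backup" ordering the
package's acceptance suite checks over multiple seeds.

## Command line

```
Rscript inst/cli/avifuse synth    --classes 4 --per-class 12 --seed 1 --out data/
Rscript inst/cli/avifuse features --manifest data/manifest.csv
Rscript inst/cli/avifuse select   --features data/features.csv --k 21
Rscript inst/cli/avifuse train    --config train.yml
Rscript inst/cli/avifuse evaluate --model data/audio_mlp_model.json --manifest data/manifest.csv ...
```

Exit codes: 0 success, 1 validation/config error, 2 I/O error. Every stage
appends a JSON-line with seed, config hash and artifact content hashes to
`<out>/run.log`; models are saved as single-file versioned JSON archives
that restore bit-identical predictions.

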