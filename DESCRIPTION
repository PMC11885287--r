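Package: avifuse
Title: Visual-Acoustic Fusion for Bird Species Classification
Version: 0.1.0
Authors@R:
    person("Avifuse", "Developers", email = "avifuse@example.org", role = c("aut", "cre"))
Description: A desk-scale multimodal pipeline for bird species identification
    that fuses image embeddings from a residual convolutional network with
    acoustic embeddings from an LSTM over MFCC sequences. Provides a seeded
    synthetic dataset generator (class-specific harmonic chirp calls and
    colour-coded images), a full bioacoustic feature extractor (spectrogram,
    MFCC with deltas, gammatone cepstra, spectral descriptors, chroma, tempo
    and harmonicity), correlation-based feature selection, early fusion by
    feature concatenation and late fusion by alpha-weighted probability
    averaging, plus reproducible training loops, evaluation metrics and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    yaml,
    digest,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
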