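# Training loops.
#
# Three model families, all trained by plain-R backpropagation so runs are
# bit-reproducible under a fixed seed:
#   audio_mlp      21 -> 256 -> 128 -> 32 -> K on selected clip features
#                  (Adam 1e-4, batch 16, 75 epochs, L2 0.01 on the output
#                  layer)
#   acoustic_lstm  LSTM over MFCC frames -> dense head -> softmax
#                  (RMSprop 1e-3, batch 64)
#   fusion         tiny visual backbone + LSTM, either jointly trained on
#                  the concatenated embedding (early) or as independent
#                  classifiers combined by a validated alpha (late)

#' Training configuration
#'
#' Defaults depend on `model_kind` and follow the reference setups: the
#' feature MLP uses Adam at 1e-4 with batch 16 for 75 epochs and L2 0.01 on
#' its output layer; the acoustic LSTM uses RMSprop at 1e-3 with batch 64.
#' Everything is overridable.
#'
#' @param model_kind one of `"audio_mlp"`, `"acoustic_lstm"`,
#'   `"visual_cnn"`, `"early_fusion"`, `"late_fusion"`.
#' @param optimizer `"adam"` or `"rmsprop"`.
#' @param lr learning rate.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param l2_output L2 coefficient on the output layer weights.
#' @param hidden_size LSTM hidden units.
#' @param embedding_dim per-modality embedding width for fusion models.
#' @param image_size image side length fed to the visual backbone.
#' @param max_frames cap on MFCC sequence length.
#' @param seed integer seed.
#' @return a `TrainConfig` list.
#' @export
train_config <- function(model_kind = c("audio_mlp", "acoustic_lstm",
                                        "visual_cnn", "early_fusion",
                                        "late_fusion"),
                         optimizer = NULL, lr = NULL, batch_size = NULL,
                         epochs = NULL, l2_output = 0.01,
                         hidden_size = 16L, embedding_dim = 16L,
                         image_size = 32L, max_frames = 30L, seed = 1L) {
  model_kind <- match.arg(model_kind)
  defaults <- switch(model_kind,
    audio_mlp     = list(optimizer = "adam", lr = 1e-4, batch_size = 16L,
                         epochs = 75L),
    acoustic_lstm = list(optimizer = "rmsprop", lr = 1e-3, batch_size = 64L,
                         epochs = 30L),
    visual_cnn    = list(optimizer = "adam", lr = 1e-3, batch_size = 8L,
                         epochs = 40L),
    early_fusion  = list(optimizer = "adam", lr = 1e-3, batch_size = 8L,
                         epochs = 40L),
    late_fusion   = list(optimizer = "adam", lr = 1e-3, batch_size = 8L,
                         epochs = 40L))
  cfg <- list(model_kind = model_kind,
              optimizer = optimizer %||% defaults$optimizer,
              lr = lr %||% defaults$lr,
              batch_size = as.integer(batch_size %||% defaults$batch_size),
              epochs = as.integer(epochs %||% defaults$epochs),
              l2_output = l2_output,
              hidden_size = as.integer(hidden_size),
              embedding_dim = as.integer(embedding_dim),
              image_size = as.integer(image_size),
              max_frames = max_frames,
              seed = as.integer(seed))
  if (!cfg$optimizer %in% c("adam", "rmsprop")) {
    stop_invalid_config("optimizer must be adam or rmsprop")
  }
  structure(cfg, class = "TrainConfig")
}

#' Label encoding
#'
#' Sorted unique species names map to indices `0 .. K-1`.
#'
#' @param species_names character vector of labels.
#' @return named integer vector (name -> index).
#' @export
label_encode <- function(species_names) {
  if (length(species_names) == 0L) stop_invalid_input("no species names given")
  classes <- sort(unique(as.character(species_names)))
  stats::setNames(seq_along(classes) - 1L, classes)
}

#' @rdname label_encode
#' @param encoding a map from [label_encode()].
#' @param indices integer indices to decode.
#' @export
label_decode <- function(encoding, indices) {
  names(encoding)[match(indices, encoding)]
}

one_hot <- function(idx, K) {
  Y <- matrix(0, length(idx), K)
  Y[cbind(seq_along(idx), idx)] <- 1
  Y
}

epoch_batches <- function(n, batch_size, seed, epoch) {
  ord <- with_seed(derive_seed(seed, "shuffle", epoch), sample.int(n))
  split(ord, ceiling(seq_along(ord) / batch_size))
}

# Feature MLP ----------------------------------------------------------------

mlp_init <- function(sizes, seed) {
  with_seed(derive_seed(seed, "mlp_init"), {
    params <- list()
    for (i in seq_len(length(sizes) - 1L)) {
      params[[paste0("W", i)]] <-
        matrix(stats::rnorm(sizes[i + 1] * sizes[i], 0, sqrt(2 / sizes[i])),
               sizes[i + 1], sizes[i])
      params[[paste0("b", i)]] <- numeric(sizes[i + 1])
    }
    params
  })
}

mlp_forward <- function(params, X, n_layers) {
  acts <- list(t(X))                      # store as d x n for BLAS-friendly ops
  h <- t(X)
  for (i in seq_len(n_layers)) {
    z <- params[[paste0("W", i)]] %*% h + params[[paste0("b", i)]]
    h <- if (i < n_layers) pmax(z, 0) else z
    acts[[i + 1L]] <- h
  }
  logits <- t(h)
  P <- exp(logits - apply(logits, 1, max))
  P <- P / rowSums(P)
  list(probs = P, acts = acts)
}

mlp_backward <- function(params, fwd, Y, n_layers, l2_output = 0) {
  n <- nrow(Y)
  dz <- t(fwd$probs - Y) / n               # K x n
  grads <- list()
  for (i in rev(seq_len(n_layers))) {
    a_prev <- fwd$acts[[i]]
    dW <- dz %*% t(a_prev)
    if (i == n_layers && l2_output > 0) {
      dW <- dW + l2_output * params[[paste0("W", i)]]
    }
    grads[[paste0("W", i)]] <- dW
    grads[[paste0("b", i)]] <- rowSums(dz)
    if (i > 1L) {
      dz <- (t(params[[paste0("W", i)]]) %*% dz) * (fwd$acts[[i]] > 0)
    }
  }
  grads
}

#' Train the clip-feature MLP
#'
#' Architecture `d -> 256 -> 128 -> 32 -> K` with ReLU hidden units and a
#' softmax output, categorical cross-entropy loss, Adam (lr 1e-4 default)
#' and L2 regularization (0.01) on the output layer weights. The input
#' dimension is taken from the feature matrix (21 when fed SET4 vectors).
#'
#' @param features numeric matrix/data.frame, rows = clips, columns = the
#'   selected features.
#' @param labels character species labels (one per row).
#' @param config a [train_config()] with `model_kind = "audio_mlp"`.
#' @param hidden hidden layer sizes.
#' @return an `avifuse_model` of kind `"audio_mlp"` with a per-epoch mean
#'   training-loss trace.
#' @export
train_audio_mlp <- function(features, labels, config = train_config("audio_mlp"),
                            hidden = c(256L, 128L, 32L)) {
  X <- as.matrix(features)
  if (nrow(X) != length(labels)) stop_schema("features/labels length mismatch")
  if (any(!is.finite(X))) stop_invalid_input("non-finite feature values")
  # feature scaling: z-score on training statistics, stored with the model
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  X <- sweep(sweep(X, 2, mu, `-`), 2, sd_, `/`)
  enc <- label_encode(labels)
  K <- length(enc)
  idx <- enc[as.character(labels)] + 1L
  Y <- one_hot(idx, K)
  sizes <- c(ncol(X), hidden, K)
  n_layers <- length(sizes) - 1L
  params <- mlp_init(sizes, config$seed)
  opt <- optimizer_new(config$optimizer, config$lr)
  loss_trace <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    batches <- epoch_batches(nrow(X), config$batch_size, config$seed, ep)
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      rows <- batches[[bi]]
      fwd <- mlp_forward(params, X[rows, , drop = FALSE], n_layers)
      losses[bi] <- cross_entropy(Y[rows, , drop = FALSE], fwd$probs)
      grads <- mlp_backward(params, fwd, Y[rows, , drop = FALSE], n_layers,
                            config$l2_output)
      step <- optimizer_step(opt, params, grads)
      opt <- step$opt
      params <- step$params
    }
    loss_trace[ep] <- mean(losses)
  }
  structure(list(kind = "audio_mlp", params = params, sizes = sizes,
                 classes = names(enc), feature_names = colnames(X),
                 scale_mu = mu, scale_sd = sd_,
                 config = config, loss_trace = loss_trace),
            class = "avifuse_model")
}

#' Predict class probabilities from a trained model
#'
#' @param model an `avifuse_model`.
#' @param newdata input matching the model kind: a feature matrix for
#'   `audio_mlp`, a list of MFCC sequence matrices for `acoustic_lstm`, or
#'   a multimodal item list (see [load_multimodal()]) for fusion models.
#' @param ... forwarded to kind-specific methods (e.g. `drop_modality`).
#' @return an n x K probability matrix with class-name columns.
#' @export
predict_probs <- function(model, newdata, ...) {
  stopifnot(inherits(model, "avifuse_model"))
  switch(model$kind,
    audio_mlp = {
      X <- as.matrix(newdata)
      if (ncol(X) != model$sizes[1]) {
        stop_schema(sprintf("model expects %d features, got %d",
                            model$sizes[1], ncol(X)))
      }
      X <- sweep(sweep(X, 2, model$scale_mu, `-`), 2, model$scale_sd, `/`)
      P <- mlp_forward(model$params, X, length(model$sizes) - 1L)$probs
      colnames(P) <- model$classes
      P
    },
    acoustic_lstm = lstm_predict(model, newdata),
    acoustic_branch = acoustic_branch_predict(model, newdata, ...),
    visual_cnn = visual_predict(model, newdata, ...),
    early_fusion = early_fusion_predict(model, newdata, ...),
    late_fusion = late_fusion_predict(model, newdata, ...),
    stop_invalid_config(sprintf("unknown model kind: %s", model$kind))
  )
}

# Acoustic LSTM classifier ---------------------------------------------------

lstm_model_forward <- function(params, seqs_rows, keep_cache = FALSE) {
  lapply(seqs_rows, function(s) {
    fw <- lstm_forward(s, params$cell, keep_cache = keep_cache)
    h <- if (keep_cache) fw$h else fw
    e <- as.vector(params$head_W %*% h + params$head_b)
    logits <- as.vector(params$cls_W %*% e + params$cls_b)
    list(h = h, e = e, p = softmax(logits),
         cache = if (keep_cache) fw$cache else NULL)
  })
}

#' Train the acoustic LSTM classifier
#'
#' [lstm_encode()] (final hidden state through a dense head) followed by a
#' softmax classifier, trained end-to-end with truncated-free full
#' backpropagation through time under RMSprop (lr 1e-3 default).
#'
#' @param sequences list of frames x features MFCC matrices.
#' @param labels character species labels.
#' @param config a [train_config()] with `model_kind = "acoustic_lstm"`.
#' @return an `avifuse_model` of kind `"acoustic_lstm"`.
#' @export
train_acoustic_lstm <- function(sequences, labels,
                                config = train_config("acoustic_lstm")) {
  if (length(sequences) == 0L || length(sequences) != length(labels)) {
    stop_schema("sequences/labels length mismatch")
  }
  enc <- label_encode(labels)
  K <- length(enc)
  idx <- enc[as.character(labels)] + 1L
  D <- ncol(sequences[[1]])
  H <- config$hidden_size
  E <- config$embedding_dim
  cell <- lstm_params(D, H, seed = config$seed)
  params <- with_seed(derive_seed(config$seed, "lstm_heads"), {
    list(cell = cell,
         head_W = matrix(stats::rnorm(E * H, 0, sqrt(2 / H)), E, H),
         head_b = numeric(E),
         cls_W = matrix(stats::rnorm(K * E, 0, sqrt(2 / E)), K, E),
         cls_b = numeric(K))
  })
  flat <- lstm_flat_params(params)
  opt <- optimizer_new(config$optimizer, config$lr)
  loss_trace <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    batches <- epoch_batches(length(sequences), config$batch_size,
                             config$seed, ep)
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      rows <- batches[[bi]]
      fwd <- lstm_model_forward(params, sequences[rows], keep_cache = TRUE)
      grads <- NULL
      loss <- 0
      for (j in seq_along(rows)) {
        y <- numeric(K); y[idx[rows[j]]] <- 1
        f <- fwd[[j]]
        loss <- loss + cross_entropy(y, f$p)
        dlogit <- f$p - y
        g <- list(
          cls_W = outer(dlogit, f$e), cls_b = dlogit)
        de <- as.vector(crossprod(params$cls_W, dlogit))
        g$head_W <- outer(de, f$h); g$head_b <- de
        dh <- as.vector(crossprod(params$head_W, de))
        cg <- lstm_backward(params$cell, f$cache, dh)
        for (nm in names(cg)) g[[paste0("cell.", nm)]] <- cg[[nm]]
        grads <- if (is.null(grads)) g else Map(`+`, grads, g)
      }
      grads <- lapply(grads, function(g) g / length(rows))
      losses[bi] <- loss / length(rows)
      step <- optimizer_step(opt, flat, grads)
      opt <- step$opt
      flat <- step$params
      params <- lstm_unflat_params(flat, params)
    }
    loss_trace[ep] <- mean(losses)
  }
  structure(list(kind = "acoustic_lstm", params = params, classes = names(enc),
                 config = config, loss_trace = loss_trace),
            class = "avifuse_model")
}

lstm_flat_params <- function(params) {
  out <- list(head_W = params$head_W, head_b = params$head_b,
              cls_W = params$cls_W, cls_b = params$cls_b)
  for (nm in c("W_f", "W_i", "W_C", "W_o", "b_f", "b_i", "b_C", "b_o")) {
    out[[paste0("cell.", nm)]] <- params$cell[[nm]]
  }
  out
}

lstm_unflat_params <- function(flat, params) {
  params$head_W <- flat$head_W; params$head_b <- flat$head_b
  params$cls_W <- flat$cls_W; params$cls_b <- flat$cls_b
  for (nm in c("W_f", "W_i", "W_C", "W_o", "b_f", "b_i", "b_C", "b_o")) {
    params$cell[[nm]] <- flat[[paste0("cell.", nm)]]
  }
  params
}

lstm_predict <- function(model, sequences) {
  if (is.list(sequences) && length(sequences) > 0 &&
      is.list(sequences[[1]]) && !is.null(sequences[[1]]$seq)) {
    sequences <- lapply(sequences, `[[`, "seq")   # multimodal items
  }
  fwd <- lstm_model_forward(model$params, sequences)
  P <- do.call(rbind, lapply(fwd, `[[`, "p"))
  colnames(P) <- model$classes
  P
}
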