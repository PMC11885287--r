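# Modality encoders.
#
# Visual: a residual CNN backbone walked as a list of typed ops
# (conv / pool / residual / gap / dense) so the same machinery gives the
# 2048-d reference embedder (untrained forward passes) and a tiny trainable
# variant used in desk-scale experiments. Acoustic: an LSTM over MFCC
# frames whose final hidden state feeds a dense head; GRU, scaled
# dot-product attention and sinusoidal positional encodings are provided as
# optional sequence-encoder building blocks.

#' Image preprocessing
#'
#' Bilinear resize to `size x size`, pixel values scaled to `[0, 1]`
#' (inputs with a maximum above 1 are assumed 8-bit and divided by 255).
#' With augmentation on, a seeded random crop of 80-100% area is taken and
#' resized, the image is flipped horizontally with probability 1/2, and
#' brightness is scaled by a factor in `[0.8, 1.2]` with clipping.
#'
#' @param image `[H, W, 3]` RGB array, at least 32x32.
#' @param size output side length, pixels.
#' @param augment `NULL` for off, otherwise a list with optional elements
#'   `crop` (logical), `flip_p` (flip probability) and `brightness`
#'   (length-2 range).
#' @param seed integer seed used when `augment` is active.
#' @return a `size x size x 3` array in `[0, 1]`.
#' @export
preprocess_image <- function(image, size = 224L, augment = NULL, seed = 1L) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) {
    stop_format("expected an RGB image array [H, W, 3]")
  }
  if (d[1] < 32L || d[2] < 32L) stop_format("image must be at least 32x32")
  img <- image
  if (max(img) > 1) img <- img / 255
  img[img < 0] <- 0; img[img > 1] <- 1
  if (!is.null(augment)) {
    img <- with_seed(derive_seed(seed, "augment"), {
      if (isTRUE(augment$crop %||% TRUE)) {
        area <- stats::runif(1, 0.8, 1.0)
        side <- sqrt(area)
        h <- max(1L, as.integer(round(side * dim(img)[1])))
        w <- max(1L, as.integer(round(side * dim(img)[2])))
        y0 <- sample.int(dim(img)[1] - h + 1L, 1L)
        x0 <- sample.int(dim(img)[2] - w + 1L, 1L)
        img <- img[y0:(y0 + h - 1L), x0:(x0 + w - 1L), , drop = FALSE]
      }
      flip_p <- augment$flip_p %||% 0.5
      if (stats::runif(1) < flip_p) {
        img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
      }
      br <- augment$brightness %||% c(0.8, 1.2)
      img * stats::runif(1, br[1], br[2])
    })
    img[img > 1] <- 1
  }
  resize_bilinear(img, size, size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  if (d[1] == out_h && d[2] == out_w) return(img)
  # center-aligned source coordinates
  sy <- (seq_len(out_h) - 0.5) * d[1] / out_h + 0.5
  sx <- (seq_len(out_w) - 0.5) * d[2] / out_w + 0.5
  y0 <- pmin(pmax(floor(sy), 1L), d[1]); y1 <- pmin(y0 + 1L, d[1])
  x0 <- pmin(pmax(floor(sx), 1L), d[2]); x1 <- pmin(x0 + 1L, d[2])
  fy <- pmin(pmax(sy - y0, 0), 1); fx <- pmin(pmax(sx - x0, 0), 1)
  out <- array(0, dim = c(out_h, out_w, d[3]))
  for (c in seq_len(d[3])) {
    A <- img[, , c]
    top <- A[y0, x0, drop = FALSE] * (1 - fx)[col(matrix(0, out_h, out_w))] +
           A[y0, x1, drop = FALSE] * fx[col(matrix(0, out_h, out_w))]
    bot <- A[y1, x0, drop = FALSE] * (1 - fx)[col(matrix(0, out_h, out_w))] +
           A[y1, x1, drop = FALSE] * fx[col(matrix(0, out_h, out_w))]
    out[, , c] <- top * (1 - fy) + bot * fy
  }
  out
}

# Backbone construction ------------------------------------------------------

#' Visual backbone configuration
#'
#' @param variant `"resnet50_ref"` (4-stage bottleneck stack, 49 conv
#'   layers, 2048-d embedding) or `"tiny"` (2 residual stages, configurable
#'   embedding, cheap enough to train on a CPU).
#' @param embedding_dim embedding length; fixed at 2048 for
#'   `resnet50_ref`.
#' @param seed seed for the deterministic weight initialization.
#' @return a `BackboneConfig`.
#' @export
backbone_config <- function(variant = c("resnet50_ref", "tiny"),
                            embedding_dim = NULL, seed = 1L) {
  variant <- match.arg(variant)
  if (variant == "resnet50_ref") {
    if (!is.null(embedding_dim) && embedding_dim != 2048L) {
      stop_invalid_config("resnet50_ref embedding_dim is fixed at 2048")
    }
    embedding_dim <- 2048L
  } else if (is.null(embedding_dim)) {
    embedding_dim <- 32L
  }
  if (!is_count(embedding_dim)) stop_invalid_config("embedding_dim must be positive")
  structure(list(variant = variant, embedding_dim = as.integer(embedding_dim),
                 seed = as.integer(seed)),
            class = "BackboneConfig")
}

bottleneck_block <- function(c_in, c_mid, stride) {
  c_out <- 4L * c_mid
  layers <- list(
    init_conv(1L, 1L, c_in, c_mid, "relu", stride = stride),
    init_conv(3L, 3L, c_mid, c_mid, "relu", pad = 1L),
    init_conv(1L, 1L, c_mid, c_out, "identity")
  )
  shortcut <- if (c_in != c_out || stride != 1L) {
    init_conv(1L, 1L, c_in, c_out, "identity", stride = stride)
  } else NULL
  residual_block(layers, shortcut)
}

#' Build a visual backbone from a configuration
#'
#' Weight initialization is seeded He-style, so the same config always
#' yields the same (untrained) network.
#'
#' @param config a [backbone_config()].
#' @return a `Backbone`: the config plus an ordered op list.
#' @export
build_backbone <- function(config) {
  stopifnot(inherits(config, "BackboneConfig"))
  with_seed(derive_seed(config$seed, "backbone", config$variant), {
    ops <- list()
    push <- function(type, ...) ops[[length(ops) + 1L]] <<- list(type = type, ...)
    if (config$variant == "resnet50_ref") {
      push("conv", layer = init_conv(7L, 7L, 3L, 64L, "relu",
                                     stride = 2L, pad = 3L))
      push("pool", window = 3L, stride = 2L, pad = 1L)
      n_blocks <- c(3L, 4L, 6L, 3L)
      mids <- c(64L, 128L, 256L, 512L)
      c_in <- 64L
      for (s in 1:4) {
        for (b in seq_len(n_blocks[s])) {
          stride <- if (s > 1L && b == 1L) 2L else 1L
          push("res", block = bottleneck_block(c_in, mids[s], stride))
          c_in <- 4L * mids[s]
        }
      }
      push("gap")
      push("dense", layer = init_dense(config$embedding_dim, c_in))
    } else {
      push("conv", layer = init_conv(3L, 3L, 3L, 8L, "relu", pad = 1L))
      push("pool", window = 2L, stride = 2L, pad = 0L)
      push("res", block = residual_block(list(
        init_conv(3L, 3L, 8L, 8L, "relu", pad = 1L),
        init_conv(3L, 3L, 8L, 8L, "identity", pad = 1L))))
      push("conv", layer = init_conv(3L, 3L, 8L, 16L, "relu",
                                     stride = 2L, pad = 1L))
      push("res", block = residual_block(list(
        init_conv(3L, 3L, 16L, 16L, "relu", pad = 1L),
        init_conv(3L, 3L, 16L, 16L, "identity", pad = 1L))))
      push("gap")
      push("dense", layer = init_dense(config$embedding_dim, 16L))
    }
    structure(list(config = config, ops = ops), class = "Backbone")
  })
}

backbone_forward <- function(backbone, x, keep_cache = FALSE) {
  h <- x
  caches <- if (keep_cache) vector("list", length(backbone$ops)) else NULL
  for (i in seq_along(backbone$ops)) {
    op <- backbone$ops[[i]]
    h <- switch(op$type,
      conv = conv_forward(h, op$layer, keep_cache = keep_cache),
      pool = pool_forward(h, op$window, op$stride, op$pad,
                          keep_cache = keep_cache),
      res = residual_forward(h, op$block, keep_cache = keep_cache),
      gap = {
        if (keep_cache) {
          structure(global_avg_pool(h), cache = list(in_dim = dim(as_hwc(h))))
        } else global_avg_pool(h)
      },
      dense = {
        v <- as.vector(h)
        z <- dense_forward(v, op$layer)
        if (keep_cache) structure(z, cache = list(x = v)) else z
      })
    if (keep_cache) {
      caches[[i]] <- attr(h, "cache")
      attr(h, "cache") <- NULL
    }
  }
  if (keep_cache) list(out = h, caches = caches) else h
}

backbone_backward <- function(backbone, caches, dout) {
  grads <- stats::setNames(vector("list", length(backbone$ops)),
                           sprintf("op%02d", seq_along(backbone$ops)))
  dh <- dout
  for (i in rev(seq_along(backbone$ops))) {
    op <- backbone$ops[[i]]
    cache <- caches[[i]]
    if (op$type == "conv") {
      bk <- conv_backward(dh, op$layer, cache)
      grads[[i]] <- list(W = bk$dW, b = bk$db)
      dh <- bk$dx
    } else if (op$type == "pool") {
      dh <- pool_backward(dh, cache)
    } else if (op$type == "res") {
      bk <- residual_backward(dh, op$block, cache)
      grads[[i]] <- bk
      dh <- bk$dx
    } else if (op$type == "gap") {
      d <- cache$in_dim
      dh <- array(rep(dh / (d[1] * d[2]), each = d[1] * d[2]), dim = d)
    } else if (op$type == "dense") {
      dW <- outer(dh, cache$x)
      db <- dh
      dx <- as.vector(t(op$layer$W) %*% dh)
      grads[[i]] <- list(W = dW, b = db)
      dh <- dx
    }
  }
  list(dx = dh, grads = grads)
}

# Flatten backbone weights to a named list the optimizers understand, and
# write an updated flat list back into the backbone.
backbone_params <- function(backbone) {
  out <- list()
  for (i in seq_along(backbone$ops)) {
    op <- backbone$ops[[i]]
    tag <- sprintf("op%02d", i)
    if (op$type == "conv") {
      out[[paste0(tag, ".W")]] <- op$layer$weights
      out[[paste0(tag, ".b")]] <- op$layer$bias
    } else if (op$type == "dense") {
      out[[paste0(tag, ".W")]] <- op$layer$W
      out[[paste0(tag, ".b")]] <- op$layer$b
    } else if (op$type == "res") {
      for (j in seq_along(op$block$layers)) {
        out[[sprintf("%s.l%d.W", tag, j)]] <- op$block$layers[[j]]$weights
        out[[sprintf("%s.l%d.b", tag, j)]] <- op$block$layers[[j]]$bias
      }
      if (!is.null(op$block$shortcut)) {
        out[[paste0(tag, ".sc.W")]] <- op$block$shortcut$weights
        out[[paste0(tag, ".sc.b")]] <- op$block$shortcut$bias
      }
    }
  }
  out
}

backbone_set_params <- function(backbone, flat) {
  for (i in seq_along(backbone$ops)) {
    op <- backbone$ops[[i]]
    tag <- sprintf("op%02d", i)
    if (op$type == "conv") {
      backbone$ops[[i]]$layer$weights <- flat[[paste0(tag, ".W")]]
      backbone$ops[[i]]$layer$bias <- flat[[paste0(tag, ".b")]]
    } else if (op$type == "dense") {
      backbone$ops[[i]]$layer$W <- flat[[paste0(tag, ".W")]]
      backbone$ops[[i]]$layer$b <- flat[[paste0(tag, ".b")]]
    } else if (op$type == "res") {
      for (j in seq_along(op$block$layers)) {
        backbone$ops[[i]]$block$layers[[j]]$weights <-
          flat[[sprintf("%s.l%d.W", tag, j)]]
        backbone$ops[[i]]$block$layers[[j]]$bias <-
          flat[[sprintf("%s.l%d.b", tag, j)]]
      }
      if (!is.null(op$block$shortcut)) {
        backbone$ops[[i]]$block$shortcut$weights <- flat[[paste0(tag, ".sc.W")]]
        backbone$ops[[i]]$block$shortcut$bias <- flat[[paste0(tag, ".sc.b")]]
      }
    }
  }
  backbone
}

backbone_grads_flat <- function(backbone, grads) {
  out <- list()
  for (i in seq_along(backbone$ops)) {
    op <- backbone$ops[[i]]
    tag <- sprintf("op%02d", i)
    g <- grads[[i]]
    if (is.null(g)) next
    if (op$type %in% c("conv", "dense")) {
      out[[paste0(tag, ".W")]] <- g$W
      out[[paste0(tag, ".b")]] <- g$b
    } else if (op$type == "res") {
      for (j in seq_along(g$layer_grads)) {
        out[[sprintf("%s.l%d.W", tag, j)]] <- g$layer_grads[[j]]$dW
        out[[sprintf("%s.l%d.b", tag, j)]] <- g$layer_grads[[j]]$db
      }
      if (!is.null(g$shortcut_grad)) {
        out[[paste0(tag, ".sc.W")]] <- g$shortcut_grad$dW
        out[[paste0(tag, ".sc.b")]] <- g$shortcut_grad$db
      }
    }
  }
  out
}

#' Embed an image with a visual backbone
#'
#' Deterministic given the backbone weights (evaluation mode; no dropout or
#' stochastic layers exist in these networks).
#'
#' @param image a preprocessed `[H, W, 3]` array (see [preprocess_image()]).
#' @param backbone a [build_backbone()] result or a [backbone_config()]
#'   (built on the fly).
#' @return an `Embedding`: numeric vector of length `embedding_dim` with
#'   attribute `modality = "visual"`.
#' @export
visual_embed <- function(image, backbone) {
  if (inherits(backbone, "BackboneConfig")) backbone <- build_backbone(backbone)
  stopifnot(inherits(backbone, "Backbone"))
  out <- backbone_forward(backbone, as_hwc(image))
  embedding(out, "visual")
}

#' Construct an embedding vector
#'
#' @param values numeric vector.
#' @param modality `"visual"` or `"acoustic"`.
#' @return an `Embedding`.
#' @export
embedding <- function(values, modality = c("visual", "acoustic")) {
  modality <- match.arg(modality)
  if (length(values) == 0L || any(!is.finite(values))) {
    stop_invalid_input("embedding values must be non-empty and finite")
  }
  structure(as.numeric(values), modality = modality, class = "Embedding")
}

# Recurrent encoders ---------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

#' LSTM cell parameters
#'
#' Gate weights act on the concatenation `[h_prev, x_t]`; the four gates
#' (forget, input, candidate, output) each have an `H x (H + D)` matrix and
#' a length-`H` bias. Initialization is seeded uniform in
#' `[-1/sqrt(H), 1/sqrt(H)]`.
#'
#' @param input_size dimension `D` of each sequence frame.
#' @param hidden_size hidden state dimension `H` (reference 256).
#' @param seed integer seed.
#' @return an `LSTMCellParams` named list of `W_f, W_i, W_C, W_o, b_f, b_i,
#'   b_C, b_o`.
#' @export
lstm_params <- function(input_size, hidden_size = 256L, seed = 1L) {
  H <- as.integer(hidden_size); D <- as.integer(input_size)
  r <- 1 / sqrt(H)
  with_seed(derive_seed(seed, "lstm", H, D), {
    mk <- function() matrix(stats::runif(H * (H + D), -r, r), H, H + D)
    structure(list(W_f = mk(), W_i = mk(), W_C = mk(), W_o = mk(),
                   b_f = numeric(H), b_i = numeric(H), b_C = numeric(H),
                   b_o = numeric(H), hidden_size = H, input_size = D),
              class = "LSTMCellParams")
  })
}

lstm_forward <- function(sequence, params, keep_cache = FALSE) {
  H <- params$hidden_size
  if (ncol(sequence) != params$input_size) {
    stop_shape(sprintf("LSTM expects %d features per frame, got %d",
                       params$input_size, ncol(sequence)))
  }
  Tn <- nrow(sequence)
  h <- numeric(H); C <- numeric(H)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    z <- c(h, sequence[t, ])
    f <- sigmoid(as.vector(params$W_f %*% z) + params$b_f)
    i <- sigmoid(as.vector(params$W_i %*% z) + params$b_i)
    Ct <- tanh(as.vector(params$W_C %*% z) + params$b_C)
    o <- sigmoid(as.vector(params$W_o %*% z) + params$b_o)
    C_prev <- C
    C <- f * C_prev + i * Ct
    h <- o * tanh(C)
    if (keep_cache) {
      cache[[t]] <- list(z = z, f = f, i = i, Ct = Ct, o = o,
                         C = C, C_prev = C_prev)
    }
  }
  if (keep_cache) list(h = h, cache = cache) else h
}

# Backprop through time; gradient enters at the final hidden state only.
lstm_backward <- function(params, cache, dh_final) {
  H <- params$hidden_size
  gr <- list(W_f = params$W_f * 0, W_i = params$W_i * 0,
             W_C = params$W_C * 0, W_o = params$W_o * 0,
             b_f = numeric(H), b_i = numeric(H),
             b_C = numeric(H), b_o = numeric(H))
  dh <- dh_final
  dC <- numeric(H)
  for (t in rev(seq_along(cache))) {
    cc <- cache[[t]]
    tC <- tanh(cc$C)
    do <- dh * tC
    dC <- dC + dh * cc$o * (1 - tC^2)
    df <- dC * cc$C_prev
    di <- dC * cc$Ct
    dCt <- dC * cc$i
    dzf <- df * cc$f * (1 - cc$f)
    dzi <- di * cc$i * (1 - cc$i)
    dzC <- dCt * (1 - cc$Ct^2)
    dzo <- do * cc$o * (1 - cc$o)
    gr$W_f <- gr$W_f + outer(dzf, cc$z); gr$b_f <- gr$b_f + dzf
    gr$W_i <- gr$W_i + outer(dzi, cc$z); gr$b_i <- gr$b_i + dzi
    gr$W_C <- gr$W_C + outer(dzC, cc$z); gr$b_C <- gr$b_C + dzC
    gr$W_o <- gr$W_o + outer(dzo, cc$z); gr$b_o <- gr$b_o + dzo
    dz <- as.vector(crossprod(params$W_f, dzf) + crossprod(params$W_i, dzi) +
                    crossprod(params$W_C, dzC) + crossprod(params$W_o, dzo))
    dh <- dz[seq_len(H)]
    dC <- dC * cc$f
  }
  gr
}

#' Encode a sequence with an LSTM and dense head
#'
#' Iterates the gated cell from zero initial hidden and cell states and
#' passes the final hidden state through a dense head to produce the
#' acoustic embedding (reference dimension 256).
#'
#' @param sequence a frames x features matrix (e.g. MFCC frames).
#' @param params an [lstm_params()].
#' @param head a [dense_layer()] mapping hidden state to embedding.
#' @return an `Embedding` with `modality = "acoustic"`.
#' @export
lstm_encode <- function(sequence, params, head) {
  stopifnot(inherits(params, "LSTMCellParams"), inherits(head, "DenseLayer"))
  if (!is.matrix(sequence) || nrow(sequence) == 0L) {
    stop_invalid_input("sequence must be a non-empty matrix")
  }
  h <- lstm_forward(sequence, params)
  embedding(dense_forward(h, head), "acoustic")
}

#' GRU cell parameters
#'
#' Update gate `z`, reset gate `r` and candidate state use separate input
#' (`W_z, W_r, W`) and recurrent (`U_z, U_r, U`) matrices with no biases:
#' `z_t = sigmoid(W_z x_t + U_z h_prev)`, `r_t = sigmoid(W_r x_t + U_r
#' h_prev)`, `h~_t = tanh(W x_t + r_t * U h_prev)`,
#' `h_t = (1 - z_t) * h_prev + z_t * h~_t`.
#'
#' @inheritParams lstm_params
#' @return a `GRUCellParams` list.
#' @export
gru_params <- function(input_size, hidden_size = 256L, seed = 1L) {
  H <- as.integer(hidden_size); D <- as.integer(input_size)
  r <- 1 / sqrt(H)
  with_seed(derive_seed(seed, "gru", H, D), {
    mkW <- function() matrix(stats::runif(H * D, -r, r), H, D)
    mkU <- function() matrix(stats::runif(H * H, -r, r), H, H)
    structure(list(W_z = mkW(), U_z = mkU(), W_r = mkW(), U_r = mkU(),
                   W = mkW(), U = mkU(), hidden_size = H, input_size = D),
              class = "GRUCellParams")
  })
}

#' One GRU step
#'
#' @param x_t input frame (length `input_size`).
#' @param h_prev previous hidden state (length `hidden_size`).
#' @param params a [gru_params()].
#' @return the next hidden state `h_t`.
#' @export
gru_step <- function(x_t, h_prev, params) {
  stopifnot(inherits(params, "GRUCellParams"))
  if (length(x_t) != params$input_size || length(h_prev) != params$hidden_size) {
    stop_shape("gru_step input/hidden sizes disagree with params")
  }
  z <- sigmoid(as.vector(params$W_z %*% x_t + params$U_z %*% h_prev))
  r <- sigmoid(as.vector(params$W_r %*% x_t + params$U_r %*% h_prev))
  h_tilde <- tanh(as.vector(params$W %*% x_t + r * (params$U %*% h_prev)))
  (1 - z) * h_prev + z * h_tilde
}

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d_k)) V`, softmax taken row-wise.
#'
#' @param Q query matrix (`n_q x d_k`).
#' @param K key matrix (`n_kv x d_k`).
#' @param V value matrix (`n_kv x d_v`).
#' @return the `n_q x d_v` context matrix, with the attention weights in
#'   attribute `"weights"`.
#' @export
attention <- function(Q, K, V) {
  if (ncol(Q) != ncol(K)) stop_shape("Q and K must share their column count")
  if (nrow(K) != nrow(V)) stop_shape("K and V must have equal row counts")
  scores <- Q %*% t(K) / sqrt(ncol(K))
  w <- t(apply(scores, 1, function(s) {
    e <- exp(s - max(s)); e / sum(e)
  }))
  if (nrow(scores) == 1L) w <- matrix(w, nrow = 1L)
  structure(w %*% V, weights = w)
}

#' Sinusoidal positional encoding
#'
#' `PE(pos, 2i) = sin(pos / 10000^(2i/d))`,
#' `PE(pos, 2i+1) = cos(pos / 10000^(2i/d))`, for positions `0 ..
#' length-1` (rows) and dimensions `0 .. d-1` (columns).
#'
#' @param length sequence length.
#' @param d encoding dimension (even).
#' @return a `length x d` matrix.
#' @export
positional_encoding <- function(length, d) {
  if (!is_count(length) || !is_count(d)) {
    stop_invalid_config("length and d must be positive integers")
  }
  if (d %% 2L != 0L) stop_invalid_config("positional encoding dimension must be even")
  pos <- 0:(length - 1L)
  out <- matrix(0, length, d)
  for (i in 0:(d %/% 2L - 1L)) {
    angle <- pos / 10000^(2 * i / d)
    out[, 2L * i + 1L] <- sin(angle)
    out[, 2L * i + 2L] <- cos(angle)
  }
  out
}

#' MFCC sequence for the acoustic encoder
#'
#' Static MFCC frames (no deltas) from a clip, optionally subsampled to at
#' most `max_frames` evenly spaced frames to keep recurrent training cheap.
#'
#' @param clip an [audio_clip()].
#' @param fspec a [frame_spec()].
#' @param n_keep static coefficients per frame.
#' @param max_frames cap on sequence length (`Inf` to keep all).
#' @return a frames x `n_keep` matrix.
#' @export
mfcc_sequence <- function(clip, fspec = frame_spec(), n_keep = 13L,
                          max_frames = 40L) {
  spect <- spectrogram(clip, fspec)
  m <- mfcc_block(spect, n_keep = n_keep)[, seq_len(n_keep), drop = FALSE]
  if (nrow(m) > max_frames) {
    keep <- unique(as.integer(round(seq(1, nrow(m), length.out = max_frames))))
    m <- m[keep, , drop = FALSE]
  }
  m
}
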