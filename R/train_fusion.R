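# Multimodal data loading and fusion-model training.

#' Load the multimodal items a manifest describes
#'
#' Reads every image (PNG, preprocessed to `image_size`) and audio clip
#' (converted to a capped-length MFCC sequence), keyed by manifest row.
#'
#' @param manifest a manifest data.frame.
#' @param image_size side length images are resized to.
#' @param fspec a [frame_spec()].
#' @param max_frames MFCC sequence length cap.
#' @return a list with one element per row: `id`, `species`, `split`,
#'   `image`, `seq`.
#' @export
load_multimodal <- function(manifest, image_size = 32L, fspec = frame_spec(),
                            max_frames = 30L) {
  validate_manifest(manifest)
  lapply(seq_len(nrow(manifest)), function(i) {
    ipath <- manifest_path(manifest, manifest$image_path[i])
    apath <- manifest_path(manifest, manifest$audio_path[i])
    if (!file.exists(ipath) || !file.exists(apath)) {
      stop_io(sprintf("missing file(s) for manifest id %s (%s / %s)",
                      manifest$id[i], ipath, apath))
    }
    img <- png::readPNG(ipath)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
    if (dim(img)[3] == 4L) img <- img[, , 1:3]
    list(id = manifest$id[i], species = manifest$species[i],
         split = manifest$split[i],
         image = preprocess_image(img, size = image_size),
         seq = mfcc_sequence(load_wav(apath), fspec, max_frames = max_frames))
  })
}

items_split <- function(items, split) {
  items[vapply(items, `[[`, "", "split") == split]
}

item_labels <- function(items) vapply(items, `[[`, "", "species")

# Shared forward/backward over the tiny visual backbone for training.
fusion_param_sets <- function(vis, lstm_pack, head_W, head_b) {
  flat <- list()
  if (!is.null(vis)) {
    vp <- backbone_params(vis)
    names(vp) <- paste0("vis.", names(vp))
    flat <- c(flat, vp)
  }
  if (!is.null(lstm_pack)) {
    lp <- list()
    for (nm in c("W_f", "W_i", "W_C", "W_o", "b_f", "b_i", "b_C", "b_o")) {
      lp[[paste0("ac.cell.", nm)]] <- lstm_pack$cell[[nm]]
    }
    lp[["ac.head_W"]] <- lstm_pack$head_W
    lp[["ac.head_b"]] <- lstm_pack$head_b
    flat <- c(flat, lp)
  }
  flat[["head.W"]] <- head_W
  flat[["head.b"]] <- head_b
  flat
}

fusion_apply_params <- function(flat, vis, lstm_pack) {
  if (!is.null(vis)) {
    vp <- flat[startsWith(names(flat), "vis.")]
    names(vp) <- sub("^vis\\.", "", names(vp))
    vis <- backbone_set_params(vis, vp)
  }
  if (!is.null(lstm_pack)) {
    for (nm in c("W_f", "W_i", "W_C", "W_o", "b_f", "b_i", "b_C", "b_o")) {
      lstm_pack$cell[[nm]] <- flat[[paste0("ac.cell.", nm)]]
    }
    lstm_pack$head_W <- flat[["ac.head_W"]]
    lstm_pack$head_b <- flat[["ac.head_b"]]
  }
  list(vis = vis, lstm_pack = lstm_pack,
       head_W = flat[["head.W"]], head_b = flat[["head.b"]])
}

acoustic_embed_fwd <- function(lstm_pack, s, keep_cache = FALSE) {
  fw <- lstm_forward(s, lstm_pack$cell, keep_cache = keep_cache)
  h <- if (keep_cache) fw$h else fw
  e <- as.vector(lstm_pack$head_W %*% h + lstm_pack$head_b)
  list(h = h, e = e, cache = if (keep_cache) fw$cache else NULL)
}

#' Train a fusion model from a manifest
#'
#' Early mode trains the tiny visual backbone, the acoustic LSTM encoder
#' and a single softmax head over the concatenated embedding jointly.
#' Late mode trains a visual-only and an acoustic-only classifier
#' independently on the train split, then picks the fusion weight alpha by
#' validation-accuracy grid search ([optimize_alpha()]).
#'
#' @param manifest manifest data.frame with both modalities present.
#' @param mode `"early"` or `"late"`.
#' @param config a [train_config()].
#' @param items optionally, pre-loaded [load_multimodal()] items (skips
#'   re-reading files).
#' @return an `avifuse_model` of kind `"early_fusion"` or `"late_fusion"`.
#' @export
train_fusion <- function(manifest, mode = c("early", "late"),
                         config = train_config("early_fusion"),
                         items = NULL) {
  mode <- match.arg(mode)
  if (is.null(items)) {
    items <- load_multimodal(manifest, config$image_size,
                             max_frames = config$max_frames)
  }
  train_items <- items_split(items, "train")
  val_items <- items_split(items, "val")
  if (length(train_items) == 0L) stop_invalid_input("empty training split")
  enc <- label_encode(item_labels(items))
  K <- length(enc)

  if (mode == "early") {
    m <- train_joint(train_items, enc, config, use_visual = TRUE,
                     use_acoustic = TRUE)
    return(structure(list(kind = "early_fusion", vis = m$vis,
                          lstm_pack = m$lstm_pack,
                          head = classifier_head(m$head_W, m$head_b),
                          classes = names(enc), config = config,
                          loss_trace = m$loss_trace),
                     class = "avifuse_model"))
  }
  vis_m <- train_joint(train_items, enc, config, use_visual = TRUE,
                       use_acoustic = FALSE)
  ac_m <- train_joint(train_items, enc, config, use_visual = FALSE,
                      use_acoustic = TRUE)
  vis_model <- structure(list(kind = "visual_cnn", vis = vis_m$vis,
                              head = classifier_head(vis_m$head_W, vis_m$head_b),
                              classes = names(enc), config = config,
                              loss_trace = vis_m$loss_trace),
                         class = "avifuse_model")
  ac_model <- structure(list(kind = "acoustic_branch",
                             lstm_pack = ac_m$lstm_pack,
                             head = classifier_head(ac_m$head_W, ac_m$head_b),
                             classes = names(enc), config = config,
                             loss_trace = ac_m$loss_trace),
                        class = "avifuse_model")
  alpha <- 0.5
  if (length(val_items) > 0) {
    pv <- visual_predict(vis_model, val_items)
    pa <- acoustic_branch_predict(ac_model, val_items)
    truth <- enc[item_labels(val_items)] + 1L
    alpha <- as.numeric(optimize_alpha(pv, pa, truth))
  }
  structure(list(kind = "late_fusion", visual = vis_model,
                 acoustic = ac_model, alpha = alpha, classes = names(enc),
                 config = config),
            class = "avifuse_model")
}

# Joint training of (optionally) tiny backbone + LSTM encoder + one head.
train_joint <- function(train_items, enc, config, use_visual, use_acoustic) {
  K <- length(enc)
  idx <- enc[item_labels(train_items)] + 1L
  vis <- NULL
  lstm_pack <- NULL
  in_dim <- 0L
  if (use_visual) {
    vis <- build_backbone(backbone_config("tiny", config$embedding_dim,
                                          seed = config$seed))
    in_dim <- in_dim + config$embedding_dim
  }
  if (use_acoustic) {
    D <- ncol(train_items[[1]]$seq)
    cell <- lstm_params(D, config$hidden_size, seed = config$seed)
    lstm_pack <- with_seed(derive_seed(config$seed, "ac_head"), list(
      cell = cell,
      head_W = matrix(stats::rnorm(config$embedding_dim * config$hidden_size,
                                   0, sqrt(2 / config$hidden_size)),
                      config$embedding_dim, config$hidden_size),
      head_b = numeric(config$embedding_dim)))
    in_dim <- in_dim + config$embedding_dim
  }
  hw <- with_seed(derive_seed(config$seed, "fusion_head"), {
    matrix(stats::rnorm(K * in_dim, 0, sqrt(2 / in_dim)), K, in_dim)
  })
  flat <- fusion_param_sets(vis, lstm_pack, hw, numeric(K))
  opt <- optimizer_new(config$optimizer, config$lr)
  loss_trace <- numeric(config$epochs)
  vdim <- if (use_visual) config$embedding_dim else 0L
  for (ep in seq_len(config$epochs)) {
    batches <- epoch_batches(length(train_items), config$batch_size,
                             config$seed, ep)
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      rows <- batches[[bi]]
      grads <- NULL
      loss <- 0
      cur <- fusion_apply_params(flat, vis, lstm_pack)
      for (j in rows) {
        it <- train_items[[j]]
        fused <- numeric(0)
        vfwd <- NULL; afwd <- NULL
        if (use_visual) {
          vfwd <- backbone_forward(cur$vis, it$image, keep_cache = TRUE)
          fused <- c(fused, vfwd$out)
        }
        if (use_acoustic) {
          afwd <- acoustic_embed_fwd(cur$lstm_pack, it$seq, keep_cache = TRUE)
          fused <- c(fused, afwd$e)
        }
        logits <- as.vector(cur$head_W %*% fused + cur$head_b)
        p <- softmax(logits)
        y <- numeric(K); y[idx[j]] <- 1
        loss <- loss + cross_entropy(y, p)
        dlogit <- p - y
        g <- list("head.W" = outer(dlogit, fused), "head.b" = dlogit)
        dfused <- as.vector(crossprod(cur$head_W, dlogit))
        if (use_visual) {
          bk <- backbone_backward(cur$vis, vfwd$caches, dfused[seq_len(vdim)])
          vg <- backbone_grads_flat(cur$vis, bk$grads)
          names(vg) <- paste0("vis.", names(vg))
          g <- c(g, vg)
        }
        if (use_acoustic) {
          de <- dfused[(vdim + 1L):length(dfused)]
          g[["ac.head_W"]] <- outer(de, afwd$h)
          g[["ac.head_b"]] <- de
          dh <- as.vector(crossprod(cur$lstm_pack$head_W, de))
          cg <- lstm_backward(cur$lstm_pack$cell, afwd$cache, dh)
          for (nm in names(cg)) g[[paste0("ac.cell.", nm)]] <- cg[[nm]]
        }
        grads <- if (is.null(grads)) g else Map(`+`, grads[names(g)], g)
      }
      grads <- lapply(grads, function(gg) gg / length(rows))
      losses[bi] <- loss / length(rows)
      step <- optimizer_step(opt, flat, grads[names(flat)])
      opt <- step$opt
      flat <- step$params
    }
    loss_trace[ep] <- mean(losses)
  }
  cur <- fusion_apply_params(flat, vis, lstm_pack)
  list(vis = cur$vis, lstm_pack = cur$lstm_pack, head_W = cur$head_W,
       head_b = cur$head_b, loss_trace = loss_trace)
}

#' Train a visual-only classifier
#'
#' Tiny residual backbone plus a softmax head, trained end-to-end; the
#' visual branch of late fusion uses exactly this model.
#'
#' @inheritParams train_fusion
#' @param config a [train_config()] with `model_kind = "visual_cnn"`.
#' @return an `avifuse_model` of kind `"visual_cnn"`.
#' @export
train_visual_cnn <- function(manifest, config = train_config("visual_cnn"),
                             items = NULL) {
  if (is.null(items)) {
    items <- load_multimodal(manifest, config$image_size,
                             max_frames = config$max_frames)
  }
  train_items <- items_split(items, "train")
  if (length(train_items) == 0L) stop_invalid_input("empty training split")
  enc <- label_encode(item_labels(items))
  m <- train_joint(train_items, enc, config, use_visual = TRUE,
                   use_acoustic = FALSE)
  structure(list(kind = "visual_cnn", vis = m$vis,
                 head = classifier_head(m$head_W, m$head_b),
                 classes = names(enc), config = config,
                 loss_trace = m$loss_trace),
            class = "avifuse_model")
}

# Prediction paths -----------------------------------------------------------

visual_predict <- function(model, items, ...) {
  P <- do.call(rbind, lapply(items, function(it) {
    e <- backbone_forward(model$vis, it$image)
    classify(e, model$head)
  }))
  colnames(P) <- model$classes
  P
}

acoustic_branch_predict <- function(model, items, ...) {
  P <- do.call(rbind, lapply(items, function(it) {
    e <- acoustic_embed_fwd(model$lstm_pack, it$seq)$e
    classify(e, model$head)
  }))
  colnames(P) <- model$classes
  P
}

early_fusion_predict <- function(model, items, drop_modality = "none") {
  vdim <- model$config$embedding_dim
  P <- do.call(rbind, lapply(items, function(it) {
    v <- if (drop_modality == "visual") {
      numeric(vdim)                      # zero-fill the visual slice
    } else backbone_forward(model$vis, it$image)
    a <- if (drop_modality == "acoustic") {
      numeric(vdim)
    } else acoustic_embed_fwd(model$lstm_pack, it$seq)$e
    classify(c(v, a), model$head)
  }))
  colnames(P) <- model$classes
  P
}

late_fusion_predict <- function(model, items, drop_modality = "none",
                                alpha = NULL) {
  a <- alpha %||% model$alpha
  if (drop_modality == "visual") a <- 0    # acoustic-only backup
  if (drop_modality == "acoustic") a <- 1
  pv <- if (a > 0) visual_predict(model$visual, items) else
    matrix(1 / length(model$classes), length(items), length(model$classes))
  pa <- if (a < 1) acoustic_branch_predict(model$acoustic, items) else
    matrix(1 / length(model$classes), length(items), length(model$classes))
  P <- a * pv + (1 - a) * pa
  colnames(P) <- model$classes
  P
}
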