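# Evaluation metrics and the robustness protocol.

#' Evaluation metrics
#'
#' Accuracy, macro precision/recall/F1 (unweighted class means) and the
#' per-class confusion matrix (rows = true class, columns = predicted, so
#' row sums equal class supports). Classes never predicted get precision 0
#' by convention; classes with no support get recall 0. Optionally a macro
#' one-vs-rest AUC is computed from a probability matrix by the rank-sum
#' (Mann-Whitney) identity.
#'
#' @param predictions predicted class labels (character) or 1-based indices.
#' @param labels true labels, same type as `predictions`.
#' @param classes class-name ordering; defaults to the sorted union.
#' @param probs optional n x K probability matrix (columns in `classes`
#'   order) for AUC.
#' @return a `MetricsReport` list: `accuracy`, `macro_precision`,
#'   `macro_recall`, `macro_f1`, `macro_auc` (or `NA`), `confusion`,
#'   `per_class`.
#' @export
evaluate <- function(predictions, labels, classes = NULL, probs = NULL) {
  if (length(predictions) != length(labels)) {
    stop_invalid_input("predictions and labels must have equal length")
  }
  if (is.null(classes)) {
    classes <- sort(unique(c(as.character(labels), as.character(predictions))))
  }
  pred <- if (is.numeric(predictions)) classes[predictions] else
    as.character(predictions)
  truth <- if (is.numeric(labels)) classes[labels] else as.character(labels)
  K <- length(classes)
  confusion <- table(factor(truth, levels = classes),
                     factor(pred, levels = classes))
  confusion <- matrix(as.integer(confusion), K, K,
                      dimnames = list(true = classes, predicted = classes))
  tp <- diag(confusion)
  support <- rowSums(confusion)
  predicted_n <- colSums(confusion)
  precision <- ifelse(predicted_n > 0, tp / predicted_n, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  auc <- NA_real_
  if (!is.null(probs)) {
    aucs <- vapply(seq_len(K), function(k) {
      pos <- truth == classes[k]
      if (!any(pos) || all(pos)) return(NA_real_)
      r <- rank(probs[, k])
      (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
        (sum(pos) * sum(!pos))
    }, 0)
    auc <- mean(aucs, na.rm = TRUE)
  }
  structure(list(
    accuracy = mean(pred == truth),
    macro_precision = mean(precision),
    macro_recall = mean(recall),
    macro_f1 = mean(f1),
    macro_auc = auc,
    confusion = confusion,
    per_class = data.frame(class = classes, support = support,
                           precision = precision, recall = recall, f1 = f1,
                           row.names = NULL)
  ), class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f | macro P %.3f R %.3f F1 %.3f%s\n",
    x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1,
    if (is.na(x$macro_auc)) "" else sprintf(" AUC %.3f", x$macro_auc)))
  invisible(x)
}

metrics_to_list <- function(m) {
  list(accuracy = m$accuracy, macro_precision = m$macro_precision,
       macro_recall = m$macro_recall, macro_f1 = m$macro_f1,
       macro_auc = if (is.na(m$macro_auc)) NULL else m$macro_auc)
}

#' Robustness configuration
#'
#' @param audio_snr_db SNR of white noise injected into the audio (dB);
#'   `Inf` for none.
#' @param drop_modality `"none"`, `"visual"` or `"acoustic"`.
#' @param seed integer seed for the noise.
#' @return a `RobustnessConfig`.
#' @export
robustness_config <- function(audio_snr_db = -5, drop_modality = "none",
                              seed = 1L) {
  if (!drop_modality %in% c("none", "visual", "acoustic")) {
    stop_invalid_config("drop_modality must be none, visual or acoustic")
  }
  structure(list(audio_snr_db = audio_snr_db, drop_modality = drop_modality,
                 seed = as.integer(seed)), class = "RobustnessConfig")
}

add_noise_clip <- function(clip, snr_db, seed) {
  if (!is.finite(snr_db)) return(clip)
  rms_sig <- sqrt(mean(clip$samples^2))
  noise <- with_seed(seed, stats::rnorm(length(clip$samples), 0,
                                        max(rms_sig, 1e-6) * 10^(-snr_db / 20)))
  audio_clip(pmax(-1, pmin(1, clip$samples + noise)), clip$sample_rate)
}

#' Evaluate a fusion model under degraded conditions
#'
#' Scores the test split twice: clean, and with white noise injected into
#' the audio at `audio_snr_db` and/or one modality removed. A removed
#' visual modality zero-fills the visual embedding slice for early fusion
#' and forces `alpha = 0` (acoustic-only) for late fusion; a unimodal model
#' asked to drop its only modality is a configuration error.
#'
#' @param model a trained fusion (or unimodal) `avifuse_model`.
#' @param manifest the dataset manifest.
#' @param rc a [robustness_config()].
#' @param items optional pre-loaded [load_multimodal()] items.
#' @return list with `clean` and `degraded` `MetricsReport`s.
#' @export
robustness_eval <- function(model, manifest, rc = robustness_config(),
                            items = NULL) {
  stopifnot(inherits(model, "avifuse_model"), inherits(rc, "RobustnessConfig"))
  if ((model$kind == "visual_cnn" && rc$drop_modality == "visual") ||
      (model$kind %in% c("acoustic_lstm", "acoustic_branch") &&
       rc$drop_modality == "acoustic")) {
    stop_invalid_config("cannot drop the only modality of a unimodal model")
  }
  if (is.null(items)) {
    items <- load_multimodal(manifest, model$config$image_size,
                             max_frames = model$config$max_frames)
  }
  test_items <- items_split(items, "test")
  if (length(test_items) == 0L) stop_invalid_input("empty test split")
  truth <- item_labels(test_items)

  p_clean <- predict_probs(model, test_items)
  clean <- evaluate(model$classes[max.col(p_clean, ties.method = "first")],
                    truth, classes = model$classes, probs = p_clean)

  degraded_items <- test_items
  if (is.finite(rc$audio_snr_db) && rc$drop_modality != "acoustic") {
    validate_manifest(manifest)
    by_id <- stats::setNames(seq_len(nrow(manifest)), manifest$id)
    degraded_items <- lapply(test_items, function(it) {
      row <- by_id[[it$id]]
      clip <- load_wav(manifest_path(manifest, manifest$audio_path[row]))
      noisy <- add_noise_clip(clip, rc$audio_snr_db,
                              derive_seed(rc$seed, "robust", it$id))
      it$seq <- mfcc_sequence(noisy, max_frames = model$config$max_frames)
      it
    })
  }
  p_deg <- predict_probs(model, degraded_items,
                         drop_modality = rc$drop_modality)
  degraded <- evaluate(model$classes[max.col(p_deg, ties.method = "first")],
                       truth, classes = model$classes, probs = p_deg)
  list(clean = clean, degraded = degraded)
}
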