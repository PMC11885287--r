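# Fusion and classification.
#
# Early fusion concatenates the visual and acoustic embeddings (visual
# first) into one vector for a single softmax head; late fusion takes a
# convex alpha-weighted average of the two per-modality posterior vectors,
# with alpha chosen on the validation split by grid search.

#' Early fusion: concatenate modality embeddings
#'
#' @param v visual `Embedding`.
#' @param a acoustic `Embedding`.
#' @return a `FusedVector` of length `|v| + |a|` (visual block first).
#' @export
early_fuse <- function(v, a) {
  stopifnot(inherits(v, "Embedding"), inherits(a, "Embedding"))
  if (identical(attr(v, "modality"), attr(a, "modality"))) {
    stop_invalid_input("early fusion needs one embedding per modality")
  }
  if (attr(v, "modality") != "visual") { tmp <- v; v <- a; a <- tmp }
  structure(c(as.numeric(v), as.numeric(a)),
            visual_dim = length(v), acoustic_dim = length(a),
            class = "FusedVector")
}

#' Numerically stable softmax
#'
#' @param z finite logit vector.
#' @return a probability vector summing to 1.
#' @export
softmax <- function(z) {
  if (length(z) == 0L) stop_invalid_input("softmax of an empty vector")
  if (any(!is.finite(z))) stop_invalid_input("softmax input must be finite")
  e <- exp(z - max(z))
  e / sum(e)
}

#' Linear classification head
#'
#' @param W_c weight matrix, `n_classes x input_dim`.
#' @param b bias, length `n_classes`.
#' @return a `ClassifierHead`.
#' @export
classifier_head <- function(W_c, b = NULL) {
  if (!is.matrix(W_c)) stop_shape("classifier weights must be a matrix")
  if (is.null(b)) b <- numeric(nrow(W_c))
  if (length(b) != nrow(W_c)) stop_shape("bias length must equal n_classes")
  structure(list(W_c = W_c, b = b), class = "ClassifierHead")
}

#' Classify a (fused) feature vector
#'
#' `softmax(W_c f + b)`.
#'
#' @param f a `FusedVector`, `Embedding` or plain numeric vector.
#' @param head a [classifier_head()].
#' @return a probability vector over classes.
#' @export
classify <- function(f, head) {
  stopifnot(inherits(head, "ClassifierHead"))
  f <- as.numeric(f)
  if (length(f) != ncol(head$W_c)) {
    stop_shape(sprintf("head expects input of length %d, got %d",
                       ncol(head$W_c), length(f)))
  }
  softmax(as.vector(head$W_c %*% f + head$b))
}

#' Mean categorical cross-entropy
#'
#' `-mean over rows of sum_j y_j log(yhat_j)` in nats, with predictions
#' clipped at 1e-12 before the log.
#'
#' @param true_labels one-hot matrix (rows = samples) or a single one-hot
#'   vector.
#' @param predicted matching matrix/vector of predicted probabilities.
#' @return the mean loss (nats).
#' @export
cross_entropy <- function(true_labels, predicted) {
  if (is.null(dim(true_labels))) true_labels <- matrix(true_labels, nrow = 1)
  if (is.null(dim(predicted))) predicted <- matrix(predicted, nrow = 1)
  if (!identical(dim(true_labels), dim(predicted))) {
    stop_shape("true and predicted matrices must have identical shapes")
  }
  p <- pmax(predicted, 1e-12)
  mean(-rowSums(true_labels * log(p)))
}

#' Late fusion: convex probability average
#'
#' `alpha * p_visual + (1 - alpha) * p_acoustic`.
#'
#' @param p_visual probability vector from the visual classifier.
#' @param p_acoustic probability vector from the acoustic classifier.
#' @param alpha weight in `[0, 1]`.
#' @return the fused probability vector.
#' @export
late_fuse <- function(p_visual, p_acoustic, alpha) {
  if (length(p_visual) != length(p_acoustic)) {
    stop_shape("probability vectors must have equal length")
  }
  if (!is_num(alpha) || alpha < 0 || alpha > 1) {
    stop_invalid_config("alpha must lie in [0, 1]")
  }
  check_prob <- function(p, nm) {
    if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-6) {
      stop_invalid_input(sprintf("%s is not a probability vector", nm))
    }
  }
  check_prob(p_visual, "p_visual")
  check_prob(p_acoustic, "p_acoustic")
  alpha * p_visual + (1 - alpha) * p_acoustic
}

#' Optimize the late-fusion weight on a validation set
#'
#' Evaluates accuracy of `late_fuse` predictions over the grid
#' `alpha = 0, 0.05, ..., 1` and returns the smallest alpha attaining the
#' maximum.
#'
#' @param val_visual_probs matrix (rows = samples) of visual posteriors.
#' @param val_acoustic_probs matching matrix of acoustic posteriors.
#' @param val_labels integer class indices (1-based) of the truth.
#' @return the selected alpha (scalar), with the accuracy trace over the
#'   grid in attribute `"trace"`.
#' @export
optimize_alpha <- function(val_visual_probs, val_acoustic_probs, val_labels) {
  if (is.null(dim(val_visual_probs)) || nrow(val_visual_probs) == 0L) {
    stop_invalid_input("empty validation set")
  }
  if (!identical(dim(val_visual_probs), dim(val_acoustic_probs)) ||
      nrow(val_visual_probs) != length(val_labels)) {
    stop_shape("validation probabilities/labels are inconsistent")
  }
  grid <- seq(0, 1, by = 0.05)
  acc <- vapply(grid, function(a) {
    fused <- a * val_visual_probs + (1 - a) * val_acoustic_probs
    mean(max.col(fused, ties.method = "first") == val_labels)
  }, 0)
  best <- grid[which.max(acc)]   # which.max takes the first (smallest) tie
  structure(best, trace = stats::setNames(acc, grid))
}

#' Predicted class index from a probability vector
#'
#' Argmax with ties broken toward the lowest index.
#'
#' @param p probability vector.
#' @return the 1-based class index.
#' @export
predict_label <- function(p) {
  which.max(p)
}
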