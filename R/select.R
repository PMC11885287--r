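# Correlation-based feature selection.
#
# Filter method: each feature is scored by the maximum absolute Pearson
# correlation against the one-vs-rest 0/1 indicator of each class, and the
# top k (default 21) are retained.

#' Class-correlation report
#'
#' For every feature column, the Pearson correlation against each
#' one-vs-rest class indicator is computed; the feature's score is the
#' maximum absolute value over classes. Zero-variance features score 0.
#'
#' @param features a data.frame with numeric feature columns and a
#'   `species` label column (bookkeeping columns `id`/`split` are ignored).
#' @return a `CorrelationReport`: data.frame `feature`, `score` in `[0,1]`.
#' @export
class_correlation <- function(features) {
  if (!is.data.frame(features) || !"species" %in% names(features)) {
    stop_invalid_input("features must be a data.frame with a species column")
  }
  labels <- features$species
  if (length(unique(labels)) < 2L) {
    stop_invalid_input("class correlation needs at least 2 distinct classes")
  }
  if (nrow(features) < 3L) {
    stop_invalid_input("class correlation needs at least 3 clips")
  }
  feat_cols <- setdiff(names(features), c("id", "species", "split"))
  X <- as.matrix(features[feat_cols])
  classes <- sort(unique(labels))
  indicators <- sapply(classes, function(cl) as.numeric(labels == cl))
  score <- apply(X, 2, function(x) {
    if (stats::sd(x) == 0) return(0)
    max(abs(suppressWarnings(stats::cor(x, indicators))), na.rm = TRUE)
  })
  structure(data.frame(feature = feat_cols, score = unname(score),
                       stringsAsFactors = FALSE),
            class = c("CorrelationReport", "data.frame"))
}

#' Select the top-k correlated features
#'
#' Orders features by descending score, breaking ties by ascending feature
#' name, and keeps the first `min(k, n_features)`.
#'
#' @param report a `CorrelationReport` from [class_correlation()].
#' @param k number of features to keep (default 21).
#' @return a `SelectionResult` list: `ranked` (all features in rank order),
#'   `selected` (first `k`), `scores` (named, rank order) and `k`.
#' @export
select_top_k <- function(report, k = 21L) {
  if (!is.data.frame(report) || nrow(report) == 0L) {
    stop_invalid_input("empty correlation report")
  }
  if (!is_count(k)) stop_invalid_input("k must be a positive integer")
  ord <- order(-report$score, report$feature)
  ranked <- report$feature[ord]
  scores <- stats::setNames(report$score[ord], ranked)
  n_sel <- min(k, length(ranked))
  structure(list(ranked = ranked, selected = ranked[seq_len(n_sel)],
                 scores = scores, k = as.integer(k)),
            class = "SelectionResult")
}

#' Serialize / restore a SelectionResult as JSON
#'
#' @param selection a `SelectionResult`.
#' @param path JSON path.
#' @return `path` (write) or the `SelectionResult` (read).
#' @export
write_selection <- function(selection, path) {
  stopifnot(inherits(selection, "SelectionResult"))
  jsonlite::write_json(
    list(ranked = selection$ranked, selected = selection$selected,
         scores = as.list(selection$scores), k = selection$k),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("selection file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(ranked = x$ranked, selected = x$selected,
                 scores = unlist(x$scores), k = as.integer(x$k)),
            class = "SelectionResult")
}
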