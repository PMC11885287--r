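# Model archives.
#
# A trained model is persisted as a single JSON file: metadata (format
# version, model kind, class ordering, alpha for late fusion, config) plus
# every numeric array base64-encoded as little-endian float64, so a
# save/load round trip restores bit-identical predictions. An xxhash64
# digest of the payload guards against silent tampering.

MODEL_FORMAT_VERSION <- 1L

pack_value <- function(x) {
  if (is.null(x)) return(list(t = "null"))
  if (is.double(x)) {
    return(list(t = "f64", dim = dim(x),
                data = jsonlite::base64_enc(writeBin(as.vector(x), raw(),
                                                     size = 8L,
                                                     endian = "little"))))
  }
  if (is.integer(x) || is.character(x) || is.logical(x)) {
    return(list(t = "plain", dim = dim(x), data = x,
                mode = storage.mode(x)))
  }
  if (is.list(x)) {
    cls <- setdiff(class(x), "list")
    return(list(t = "list", class = if (length(cls)) cls else NULL,
                names = names(x),
                items = lapply(unclass(x), pack_value)))
  }
  stop_invalid_input(sprintf("cannot serialize object of class %s",
                             paste(class(x), collapse = "/")))
}

unpack_value <- function(p) {
  switch(p$t,
    null = NULL,
    f64 = {
      raw <- jsonlite::base64_dec(p$data)
      v <- readBin(raw, "double", length(raw) %/% 8L, size = 8L,
                   endian = "little")
      if (!is.null(p$dim) && length(p$dim) > 0) dim(v) <- unlist(p$dim)
      v
    },
    plain = {
      v <- p$data
      if (is.list(v)) v <- unlist(v)
      if (!is.null(p$mode)) storage.mode(v) <- p$mode
      if (!is.null(p$dim) && length(p$dim) > 0) dim(v) <- unlist(p$dim)
      v
    },
    list = {
      items <- lapply(p$items, unpack_value)
      if (!is.null(p$names)) names(items) <- unlist(p$names)
      if (!is.null(p$class)) class(items) <- c(unlist(p$class), "list")
      items
    },
    stop_format(sprintf("unknown archive node type: %s", p$t))
  )
}

#' Save a trained model to a single-file archive
#'
#' @param model an `avifuse_model`.
#' @param path output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "avifuse_model"))
  payload <- pack_value(unclass(model))
  payload_json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                   null = "null")
  archive <- list(format = "avifuse_model",
                  version = MODEL_FORMAT_VERSION,
                  kind = model$kind,
                  classes = model$classes,
                  alpha = model$alpha,
                  hash = content_hash(as.character(payload_json)),
                  payload = payload)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_io(sprintf("cannot write model: %s", path)))
  on.exit(close(con))
  writeLines(jsonlite::toJSON(archive, auto_unbox = TRUE, digits = NA,
                              null = "null"), con, useBytes = TRUE)
  invisible(path)
}

#' Load a model archive
#'
#' @param path archive written by [save_model()].
#' @param expect_kind optionally assert the stored model kind; a mismatch
#'   is a type error.
#' @return the restored `avifuse_model`.
#' @export
load_model <- function(path, expect_kind = NULL) {
  if (!file.exists(path)) stop_io(sprintf("model archive not found: %s", path))
  archive <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(archive$format, "avifuse_model")) {
    stop_format(sprintf("not an avifuse model archive: %s", path))
  }
  if (!identical(as.integer(archive$version), MODEL_FORMAT_VERSION)) {
    abort_avifuse(sprintf("unsupported model archive version %s",
                          archive$version), "avifuse_version_error")
  }
  if (!is.null(expect_kind) && !identical(archive$kind, expect_kind)) {
    abort_avifuse(sprintf("archive holds a %s model, not %s",
                          archive$kind, expect_kind), "avifuse_type_error")
  }
  payload_json <- jsonlite::toJSON(archive$payload, auto_unbox = TRUE,
                                   digits = NA, null = "null")
  if (!identical(content_hash(as.character(payload_json)), archive$hash)) {
    warning("model archive integrity check failed (payload hash mismatch)",
            call. = FALSE)
  }
  model <- unpack_value(archive$payload)
  class(model) <- "avifuse_model"
  model
}
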