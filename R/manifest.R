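# Dataset manifest: the CSV contract every pipeline stage shares.

MANIFEST_COLS <- c("id", "species", "image_path", "audio_path", "split")

#' Write a dataset manifest CSV
#'
#' UTF-8, LF line endings, header exactly
#' `id,species,image_path,audio_path,split`.
#'
#' @param manifest a data.frame with the five manifest columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_io(sprintf("cannot write manifest: %s", path)))
  on.exit(close(con))
  lines <- c(paste(MANIFEST_COLS, collapse = ","),
             do.call(paste, c(manifest[MANIFEST_COLS], sep = ",")))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a dataset manifest CSV
#'
#' Columns are matched by name, so header order is free. Relative
#' `image_path`/`audio_path` entries are interpreted against the manifest's
#' own directory; the returned data.frame carries that directory in
#' attribute `"root"`.
#'
#' @param path path to a manifest CSV.
#' @return a validated manifest data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("manifest not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(MANIFEST_COLS, names(df))
  if (length(missing) > 0) {
    stop_schema(sprintf("manifest missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  df <- df[MANIFEST_COLS]
  validate_manifest(df)
  attr(df, "root") <- dirname(normalizePath(path))
  df
}

validate_manifest <- function(manifest) {
  if (!is.data.frame(manifest)) stop_schema("manifest must be a data.frame")
  missing <- setdiff(MANIFEST_COLS, names(manifest))
  if (length(missing) > 0) {
    stop_schema(sprintf("manifest missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(manifest$id)) {
    dup <- manifest$id[duplicated(manifest$id)][1]
    abort_avifuse(sprintf("duplicate manifest id: %s", dup),
                  "avifuse_validation_error")
  }
  bad <- setdiff(unique(manifest$split), c("train", "val", "test"))
  if (length(bad) > 0) {
    abort_avifuse(sprintf("unknown split value(s): %s", paste(bad, collapse = ", ")),
                  "avifuse_validation_error")
  }
  invisible(manifest)
}

# Resolve a manifest-relative path against the manifest root (if recorded).
manifest_path <- function(manifest, rel) {
  root <- attr(manifest, "root")
  if (is.null(root)) return(rel)
  ifelse(grepl("^(/|[A-Za-z]:)", rel), rel, file.path(root, rel))
}
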