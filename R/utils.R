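#' @keywords internal
"_PACKAGE"

# Classed conditions ---------------------------------------------------------
# All package errors carry class "avifuse_error" plus a specific subclass so
# callers (and the CLI exit-code mapping) can dispatch on failure kind.

abort_avifuse <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "avifuse_error", "error", "condition"),
    list(message = msg, call = if (isFALSE(call.)) NULL else sys.call(-1))
  ))
}

stop_invalid_config <- function(msg) abort_avifuse(msg, "avifuse_invalid_config")
stop_invalid_input  <- function(msg) abort_avifuse(msg, "avifuse_invalid_input")
stop_shape          <- function(msg) abort_avifuse(msg, "avifuse_shape_error")
stop_schema         <- function(msg) abort_avifuse(msg, "avifuse_schema_error")
stop_format         <- function(msg) abort_avifuse(msg, "avifuse_format_error")
stop_io             <- function(msg) abort_avifuse(msg, "avifuse_io_error")

# Seed derivation ------------------------------------------------------------

#' Derive a stage-specific seed from a global seed
#'
#' All randomness in the package flows from one user-supplied integer seed.
#' Each pipeline stage (and each item within a stage) derives its own seed
#' through this mixing function so stages are independently reproducible.
#' The result is always a non-negative integer below 2^31.
#'
#' @param seed integer global seed.
#' @param ... further integers or strings identifying the stage/item.
#' @return a single integer in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed %% 2147483647)
  for (p in parts) {
    if (is.character(p)) {
      p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) %% 2147483647
    }
    # 32-bit-safe linear congruential mixing kept below 2^31
    h <- (h * 69069 + as.double(p %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Misc helpers ---------------------------------------------------------------

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

is_num <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

# Short stable content hash (hex) used in run logs and model archives.
content_hash <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    digest::digest(file = x, algo = "xxhash64")
  } else {
    digest::digest(x, algo = "xxhash64")
  }
}
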