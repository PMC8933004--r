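# Internal helpers shared across modules.

AUTOSOMES <- as.character(1:22)

#' Derive a child seed from a master seed and a stream index
#'
#' Deterministic seed fan-out used throughout the pipeline: each stage or
#' replicate gets its own stream so runs are reproducible piecewise. The
#' result stays inside the 32-bit integer range `set.seed()` requires.
#'
#' @param master_seed master integer seed.
#' @param stream integer stream index.
#' @return derived integer seed.
#' @export
derive_seed <- function(master_seed, stream) {
  as.integer((as.numeric(master_seed) * 2654435761 + as.numeric(stream) * 40503) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

assert_aligned_samples <- function(...) {
  mats <- list(...)
  ids <- lapply(mats, function(m) {
    if (is.matrix(m)) colnames(m) else as.character(m)
  })
  ref <- ids[[1]]
  for (i in seq_along(ids)[-1]) {
    if (!identical(ref, ids[[i]])) {
      stop_("sample IDs are misaligned between inputs (position %d differs)",
            which(ref != ids[[i]])[1])
    }
  }
  invisible(ref)
}
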