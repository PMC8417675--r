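#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a master seed and stream name
#'
#' Each generated table/layer draws from its own stream so that adding or
#' reordering layers does not perturb the others. The substream seed is a
#' deterministic 31-bit hash of the master seed and the stream label.
#'
#' @param seed master integer seed
#' @param stream character stream label
#' @return an integer seed
#' @keywords internal
derive_seed <- function(seed, stream) {
  h <- as.double(seed %% 2147483647L)
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

#' Evaluate an expression under a named random substream
#' @noRd
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, stream))
  expr
}

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == round(x)
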