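#' Derive a deterministic substream seed
#'
#' Each synthetic-data generator draws from its own named substream of the
#' master seed, so adding or reordering one generator never perturbs the
#' draws of another. The substream seed is a deterministic hash of the
#' master seed and the stream name, kept within the 32-bit integer range.
#'
#' @param seed Master integer seed.
#' @param name Character name of the substream (e.g. `"proteome"`).
#' @return An integer seed suitable for [set.seed()].
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(name)) {
    # 31-based polynomial rolling hash mod a prime < 2^31
    h <- (h * 31 + ch) %% 2147483563
  }
  as.integer((as.numeric(seed) %% 2147483563 * 40014 + h) %% 2147483563)
}

#' Evaluate an expression under a named substream of a master seed
#'
#' Saves and restores the caller's RNG state, so generator calls do not
#' interfere with user code or with each other.
#'
#' @param seed Master integer seed.
#' @param name Substream name.
#' @param expr Expression to evaluate.
#' @keywords internal
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  expr
}
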