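# Internal helpers.

# Run code under a temporary RNG state; restores the caller's stream so that
# simulation calls are reproducible without clobbering the session seed.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
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
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed for a named pipeline stage, kept within 32-bit
# integer range.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% .Machine$integer.max)
}

`%||%` <- rlang::`%||%`

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) rlang::abort(msg)
  invisible(NULL)
}

# Median/MAD z-score; falls back to mean/SD if the MAD degenerates.
robust_z <- function(x) {
  ctr <- stats::median(x, na.rm = TRUE)
  sc <- stats::mad(x, center = ctr, na.rm = TRUE)
  if (!is.finite(sc) || sc == 0) sc <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(sc) || sc == 0) return(rep(0, length(x)))
  (x - ctr) / sc
}
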