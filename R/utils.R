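# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so seeded operations never perturb the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# z-score columns; zero-variance columns become all-zero rather than NaN
zscore_cols <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  xs <- sweep(x, 2, center)
  if (is.null(scale)) {
    scale <- apply(xs, 2, stats::sd)
  }
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  sweep(xs, 2, scale, "/")
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

# fold a user seed with a stage tag into a derived 32-bit seed
derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(tag) * 7919) %% 2147483647)
}
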