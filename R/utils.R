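#' Run code under a local RNG seed
#'
#' Evaluates `expr` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so library internals never perturb a caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  expr
}

#' Derive a stream seed from a master seed
#'
#' Deterministically maps a (master seed, stream label) pair to a seed
#' below 2^31, so that pipeline stages draw from independent,
#' reproducible streams.
#'
#' @param seed integer master seed.
#' @param stream integer stream label.
#' @return a numeric seed suitable for [set.seed()].
#' @export
derive_seed <- function(seed, stream) {
  (as.double(seed) * 1009 + as.double(stream) * 9176) %% 2147483647
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
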