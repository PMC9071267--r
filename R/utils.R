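# Internal helpers: seeded RNG streams, input validation, image-batch checks.

.get_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

.set_global_seed <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Create an independent, seedable random-number stream
#'
#' Training draws randomness from several logically independent sources (data
#' shuffling, occlusion masks, REM mixing noise, wake noise injection). Each
#' source gets its own stream so that, e.g., disabling a phase does not shift
#' the random numbers seen by the others.
#'
#' @param seed integer seed (kept below 2^31 by the callers).
#' @return an environment holding a saved `.Random.seed` state.
#' @keywords internal
#' @noRd
.rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- .get_global_seed()
  set.seed(as.integer(seed %% 2147483647L))
  e$state <- get(".Random.seed", envir = globalenv())
  .set_global_seed(old)
  e
}

# Evaluate `expr` with the stream's RNG state active, then save the advanced
# state back into the stream and restore the caller's RNG.
.with_stream <- function(stream, expr) {
  old <- .get_global_seed()
  .set_global_seed(stream$state)
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    .set_global_seed(old)
  })
  expr
}

# Derive a bounded child seed from a base seed and a tag.
.child_seed <- function(seed, tag) {
  as.integer((as.double(seed) * 48271 + tag * 16807) %% 2147483647)
}

.check_image_batch <- function(x, what = "x") {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L)
    stop(what, " must be a 4-d array (height, width, channel, sample)", call. = FALSE)
  if (!all(is.finite(x)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(d)
}

.check_latent_batch <- function(z, what = "z") {
  if (!is.matrix(z))
    stop(what, " must be a matrix (samples x latent dimensions)", call. = FALSE)
  if (!all(is.finite(z)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(dim(z))
}

.stopifnot_scalar_prob <- function(p, what) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop(what, " must be a single number in [0, 1]", call. = FALSE)
}
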