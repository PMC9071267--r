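# The hippocampal module: a two-slot episodic buffer holding the current
# wake cycle's latent mini-batch and the previous cycle's (Z, Z_old).

#' Create an empty episodic buffer
#'
#' The buffer mimics hippocampal storage and retrieval: it holds at most two
#' latent mini-batches, the current cycle's `Z` and the previous cycle's
#' `Z_old`. Values are stored by copy; later encoder updates never alter
#' stored memories, and no gradient flows into them.
#'
#' @return an object of class `episodic_buffer` with `current` and `previous`
#'   slots (both initially `NULL`).
#' @export
episodic_buffer <- function() {
  structure(list(current = NULL, previous = NULL), class = "episodic_buffer")
}

#' @export
print.episodic_buffer <- function(x, ...) {
  slot <- function(s) if (is.null(s)) "empty" else paste(dim(s), collapse = "x")
  cat("<episodic_buffer> current:", slot(x$current),
      "| previous:", slot(x$previous), "\n")
  invisible(x)
}

.check_buffer <- function(buffer) {
  if (!inherits(buffer, "episodic_buffer"))
    stop("buffer must be an 'episodic_buffer'")
  invisible(buffer)
}

#' Store a latent batch in the episodic buffer
#'
#' The previous slot receives the old current batch; the new batch becomes
#' current. Called once per wake phase.
#'
#' @param buffer an [episodic_buffer()].
#' @param z latent batch (b x n_z), finite.
#' @return the updated buffer.
#' @export
buffer_store <- function(buffer, z) {
  .check_buffer(buffer)
  .check_latent_batch(z)
  if (!is.null(buffer$current) && !identical(dim(buffer$current), dim(z)))
    stop("stored latent batches must all have the same shape")
  buffer$previous <- buffer$current
  buffer$current <- z
  buffer
}

#' Recall the current memory for NREM replay
#'
#' NREM replays single episodic memories: the current latent batch, unmixed.
#'
#' @param buffer an [episodic_buffer()] with a current batch.
#' @return the current latent batch.
#' @export
recall_nrem <- function(buffer) {
  .check_buffer(buffer)
  if (is.null(buffer$current)) stop("episodic buffer is empty")
  buffer$current
}

#' Recall a mixed memory for REM dreaming
#'
#' On the first cycle (no previous memory) REM replays the current batch
#' unchanged. Afterwards, `mode = "mix"` returns
#' [mix_memories()]`(Z, Z_old, eps)` with fresh standard-normal noise;
#' `mode = "single"` returns the current batch with no noise (the
#' "w/o memory mix" pathology); `mode = "noise_only"` returns pure noise
#' (spontaneous activity only).
#'
#' @param buffer an [episodic_buffer()] with a current batch.
#' @param lam,lam_prime mixing coefficients, see [mix_memories()].
#' @param mode one of `"mix"`, `"single"`, `"noise_only"`.
#' @return a latent batch of the stored shape. Uses the current RNG state for
#'   the noise draw.
#' @export
recall_rem <- function(buffer, lam = 0.5, lam_prime = 0.5,
                       mode = c("mix", "single", "noise_only")) {
  .check_buffer(buffer)
  mode <- match.arg(mode)
  z <- buffer$current
  if (is.null(z)) stop("episodic buffer is empty")
  if (mode == "single") return(z)
  if (mode == "noise_only")
    return(matrix(rnorm(length(z)), nrow(z), ncol(z)))
  if (is.null(buffer$previous)) return(z) # first-iteration rule
  eps <- matrix(rnorm(length(z)), nrow(z), ncol(z))
  mix_memories(z, buffer$previous, eps, lam = lam, lam_prime = lam_prime)
}
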