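# Binary patch-occlusion masks for NREM perturbed dreaming and for the
# occlusion-robustness evaluation.
#
# The 32x32 image plane is tiled, from the top-left corner, into
# square_size x square_size patches (right/bottom remainders are truncated
# rectangles when the size does not divide 32). Each patch is independently
# zeroed with the given probability. Zero is mid-gray in [-1, 1] pixel coding,
# so occlusion paints gray squares.

#' Occlusion specification
#'
#' @param probability probability that any given patch is occluded, in
#'   \[0, 1\] ("occlusion intensity").
#' @param square_size patch edge length in pixels (>= 1). Training draws it
#'   from 1..8; evaluation conventionally fixes size 4.
#' @return an object of class `occlusion_spec`.
#' @export
occlusion_spec <- function(probability, square_size) {
  .stopifnot_scalar_prob(probability, "probability")
  square_size <- as.integer(square_size)
  if (length(square_size) != 1L || is.na(square_size) || square_size < 1L)
    stop("square_size must be a single integer >= 1")
  structure(list(probability = probability, square_size = square_size),
            class = "occlusion_spec")
}

#' @export
print.occlusion_spec <- function(x, ...) {
  cat(sprintf("<occlusion_spec> p = %.3f, s = %d\n", x$probability, x$square_size))
  invisible(x)
}

#' Draw a random occlusion specification
#'
#' Training samples one spec per mini-batch: the probability uniform on
#' \[0, 1\] and the square size uniform on the integers 1..8. Uses the current
#' RNG state.
#'
#' @param max_size largest square size (default 8).
#' @return an `occlusion_spec`.
#' @export
sample_occlusion_spec <- function(max_size = 8L) {
  occlusion_spec(runif(1L), sample.int(max_size, 1L))
}

#' Build a binary occlusion mask
#'
#' @param spec an [occlusion_spec()].
#' @param height,width mask dimensions in pixels (default 32 x 32).
#' @return a (height x width) matrix with entries in \{0, 1\}; zeros form a
#'   union of grid-aligned patches. Uses the current RNG state (one Bernoulli
#'   draw per patch).
#' @export
build_occlusion_mask <- function(spec, height = 32L, width = 32L) {
  if (!inherits(spec, "occlusion_spec")) stop("spec must be an 'occlusion_spec'")
  height <- as.integer(height); width <- as.integer(width)
  if (height < 1L || width < 1L) stop("height and width must be >= 1")
  s <- spec$square_size
  nh <- ceiling(height / s); nw <- ceiling(width / s)
  # one draw per patch, in a fixed (row-major over the patch grid) order
  occluded <- matrix(runif(nh * nw) < spec$probability, nh, nw)
  keep <- 1 - occluded # 0 = occluded patch
  rows <- rep(seq_len(nh), each = s, length.out = height)
  cols <- rep(seq_len(nw), each = s, length.out = width)
  mask <- keep[rows, cols, drop = FALSE]
  storage.mode(mask) <- "double"
  mask
}

#' Apply an occlusion mask to an image batch
#'
#' Elementwise product with the mask, broadcast identically over the channel
#' and sample dimensions; occluded pixels become 0 (mid-gray in \[-1, 1\]
#' coding). Applying the same binary mask twice equals applying it once.
#'
#' @param x image batch array (h, w, channels, b).
#' @param mask binary (h x w) matrix from [build_occlusion_mask()].
#' @return occluded image batch of the same shape.
#' @export
apply_occlusion_mask <- function(x, mask) {
  d <- .check_image_batch(x)
  if (!is.matrix(mask) || nrow(mask) != d[1] || ncol(mask) != d[2])
    stop("mask plane must match the image plane (", d[1], " x ", d[2], ")")
  x * as.vector(mask) # recycles over channels and samples (h*w divides length)
}

#' Occlude a batch with fresh random masks
#'
#' Convenience wrapper used by NREM training and by the evaluation suite:
#' builds mask realizations for a fixed (probability, square size) and applies
#' them. During training the spec is drawn once per mini-batch but each sample
#' gets its own mask realization; set `per_sample = FALSE` to share one mask
#' across the batch.
#'
#' @param x image batch array (h, w, channels, b).
#' @param probability,square_size occlusion parameters (see
#'   [occlusion_spec()]).
#' @param per_sample logical; independent mask per sample (default) or one
#'   shared mask.
#' @return occluded image batch. Uses the current RNG state.
#' @export
occlude_images <- function(x, probability, square_size, per_sample = TRUE) {
  d <- .check_image_batch(x)
  spec <- occlusion_spec(probability, square_size)
  if (!per_sample) {
    return(apply_occlusion_mask(x, build_occlusion_mask(spec, d[1], d[2])))
  }
  for (i in seq_len(d[4])) {
    m <- build_occlusion_mask(spec, d[1], d[2])
    x[, , , i] <- x[, , , i, drop = FALSE] * as.vector(m)
  }
  x
}
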