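# Encoder/discriminator E = (E_z, E_d) and generator G.
#
# The encoder is a DCGAN-style stack of four 4x4 stride-2 convolutions
# (channels c1, c2, c3, latent_dim; padding 1 except 0 for the last), each but
# the last followed by LeakyReLU(0.2). Spatial size halves at every layer:
# 32 -> 16 -> 8 -> 4 -> 1, so the latent code is the flattened (latent_dim x
# 1 x 1) feature map. The discriminator is a single extra 4x4 convolution on
# the third-layer (4x4) feature map followed by a sigmoid; E_z and E_d share
# the three trunk layers. The generator mirrors E_z with four 4x4 stride-2
# transposed convolutions (padding 0 for the first, 1 otherwise), LeakyReLU
# between layers and tanh at the output. No normalization layers anywhere.

.lrelu <- function(a, slope = 0.2) .cpp_lrelu(a, slope)

.lrelu_grad <- function(a, g, slope = 0.2) .cpp_lrelu_bwd(a, g, slope)

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Fan-in-scaled (He) normal init. Without normalization layers the DCGAN
# convention (sd 0.02 everywhere) collapses the latent scale through four
# layers (sd(z) ~ 1e-4), and the KL regularizer's 1/sigma^2 term then blows
# up training; scaling by fan-in keeps activations near unit variance.
.rand_weight <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

#' Initialize encoder/discriminator and generator parameters
#'
#' Weights are drawn from a zero-mean normal with fan-in-scaled standard
#' deviation `sqrt(2 / fan_in)` (He initialization) and biases start at zero.
#' Because the architecture deliberately has no normalization layers, the
#' init must keep activations near unit scale: a fixed small kernel sd would
#' collapse the latent variance and destabilize the KL regularizer.
#' Convolution kernels are 4x4 throughout. `channels` gives the widths of the
#' three shared trunk layers; the fourth (latent head) layer has `latent_dim`
#' channels and the discriminator head maps the 4x4 trunk output to a single
#' scalar.
#'
#' @param latent_dim dimension of the latent code z (default 256).
#' @param channels integer vector of length 3: trunk widths (default
#'   `c(64, 128, 256)`). Smaller widths give desk-scale models.
#' @param in_channels number of image channels (3 for RGB).
#' @param seed optional integer; when given, initialization is reproducible
#'   and the caller's RNG state is left untouched.
#' @return an object of class `pad_params`: nested named list with components
#'   `enc` (trunk `W1,b1,W2,b2,W3,b3`, latent head `Wz,bz`, discriminator head
#'   `Wd,bd`), `gen` (`W1,b1,...,W4,b4`) and `meta`.
#' @examples
#' p <- pad_params(latent_dim = 8, channels = c(4, 8, 8), seed = 1)
#' z <- pad_encode(p, array(0, c(32, 32, 3, 2)))
#' dim(z) # 2 x 8
#' @export
pad_params <- function(latent_dim = 256L, channels = c(64L, 128L, 256L),
                       in_channels = 3L, seed = NULL) {
  latent_dim <- as.integer(latent_dim)
  channels <- as.integer(channels)
  if (latent_dim < 1L) stop("latent_dim must be >= 1")
  if (length(channels) != 3L || any(channels < 1L))
    stop("channels must be three positive integers")
  K2 <- 16L # 4x4 kernel taps

  draw <- function() {
    c1 <- channels[1]; c2 <- channels[2]; c3 <- channels[3]
    # conv fan-in: K*K*C_in; stride-2 transposed conv: K*K*C_in / 4 taps
    # reach each output unit
    list(
      enc = list(
        W1 = .rand_weight(c1, K2 * in_channels, K2 * in_channels),
        b1 = numeric(c1),
        W2 = .rand_weight(c2, K2 * c1, K2 * c1),          b2 = numeric(c2),
        W3 = .rand_weight(c3, K2 * c2, K2 * c2),          b3 = numeric(c3),
        Wz = .rand_weight(latent_dim, K2 * c3, K2 * c3),  bz = numeric(latent_dim),
        Wd = .rand_weight(1L, K2 * c3, K2 * c3),          bd = numeric(1L)
      ),
      gen = list(
        W1 = .rand_weight(latent_dim, K2 * c3, K2 * latent_dim / 4),
        b1 = numeric(c3),
        W2 = .rand_weight(c3, K2 * c2, K2 * c3 / 4),          b2 = numeric(c2),
        W3 = .rand_weight(c2, K2 * c1, K2 * c2 / 4),          b3 = numeric(c1),
        W4 = .rand_weight(c1, K2 * in_channels, K2 * c1 / 4),
        b4 = numeric(in_channels)
      ),
      meta = list(latent_dim = latent_dim, channels = channels,
                  in_channels = in_channels, lrelu_slope = 0.2)
    )
  }
  p <- if (is.null(seed)) draw() else .with_stream(.rng_stream(seed), draw())
  class(p) <- "pad_params"
  p
}

#' @export
print.pad_params <- function(x, ...) {
  m <- x$meta
  n_par <- sum(vapply(unlist(x[c("enc", "gen")], recursive = FALSE),
                      length, integer(1)))
  cat("<pad_params> latent_dim =", m$latent_dim,
      "| trunk channels =", paste(m$channels, collapse = "/"),
      "|", n_par, "parameters\n")
  invisible(x)
}

.check_params <- function(p) {
  if (!inherits(p, "pad_params")) stop("params must be a 'pad_params' object")
  invisible(p)
}

.check_encoder_input <- function(p, x) {
  d <- .check_image_batch(x)
  if (d[1] != 32L || d[2] != 32L || d[3] != p$meta$in_channels)
    stop("images must be 32 x 32 with ", p$meta$in_channels, " channels")
  invisible(d)
}

# Forward pass through the shared trunk plus both heads. Returns z (b x n_z),
# the discriminator pre-activation and score, and (optionally) the
# activations needed for backprop.
.enc_forward <- function(p, x, need_cache = TRUE) {
  sl <- p$meta$lrelu_slope
  e <- p$enc
  a1 <- .cpp_conv2d_fwd(x, e$W1, e$b1, 4L, 2L, 1L); h1 <- .lrelu(a1, sl)
  a2 <- .cpp_conv2d_fwd(h1, e$W2, e$b2, 4L, 2L, 1L); h2 <- .lrelu(a2, sl)
  a3 <- .cpp_conv2d_fwd(h2, e$W3, e$b3, 4L, 2L, 1L); h3 <- .lrelu(a3, sl)
  z4 <- .cpp_conv2d_fwd(h3, e$Wz, e$bz, 4L, 2L, 0L)
  dl <- .cpp_conv2d_fwd(h3, e$Wd, e$bd, 4L, 1L, 0L)
  n <- dim(x)[4]
  z <- t(matrix(z4, p$meta$latent_dim, n))
  dlogit <- as.numeric(dl)
  out <- list(z = z, dlogit = dlogit, d = .sigmoid(dlogit))
  if (need_cache) out$cache <- list(x = x, a1 = a1, h1 = h1, a2 = a2,
                                    h2 = h2, a3 = a3, h3 = h3)
  out
}

# Backprop through the encoder. `gz` (b x n_z) and `gdlogit` (length b) are
# the loss gradients at the latent code and at the discriminator
# pre-activation; either may be NULL. Returns parameter gradients and, when
# `need_gx`, the gradient at the input image (used by the REM generator
# update).
.enc_backward <- function(p, cache, gz = NULL, gdlogit = NULL,
                          need_gx = FALSE) {
  sl <- p$meta$lrelu_slope
  e <- p$enc
  n <- dim(cache$x)[4]
  nz <- p$meta$latent_dim
  g <- list()

  gh3 <- 0
  if (!is.null(gz)) {
    gz4 <- array(t(gz), dim = c(1L, 1L, nz, n))
    bz <- .cpp_conv2d_bwd(cache$h3, e$Wz, gz4, 4L, 2L, 0L, TRUE)
    g$Wz <- bz$gw; g$bz <- as.numeric(bz$gb)
    gh3 <- gh3 + bz$gx
  } else {
    g$Wz <- matrix(0, nrow(e$Wz), ncol(e$Wz)); g$bz <- numeric(nz)
  }
  if (!is.null(gdlogit)) {
    gdl <- array(gdlogit, dim = c(1L, 1L, 1L, n))
    bd <- .cpp_conv2d_bwd(cache$h3, e$Wd, gdl, 4L, 1L, 0L, TRUE)
    g$Wd <- bd$gw; g$bd <- as.numeric(bd$gb)
    gh3 <- gh3 + bd$gx
  } else {
    g$Wd <- matrix(0, 1L, ncol(e$Wd)); g$bd <- 0
  }
  if (identical(gh3, 0)) { # nothing to propagate
    zero <- function(w) matrix(0, nrow(w), ncol(w))
    g <- c(list(W1 = zero(e$W1), b1 = numeric(length(e$b1)),
                W2 = zero(e$W2), b2 = numeric(length(e$b2)),
                W3 = zero(e$W3), b3 = numeric(length(e$b3))), g)
    return(list(grads = g[c("W1", "b1", "W2", "b2", "W3", "b3",
                            "Wz", "bz", "Wd", "bd")], gx = NULL))
  }

  ga3 <- .lrelu_grad(cache$a3, gh3, sl)
  b3 <- .cpp_conv2d_bwd(cache$h2, e$W3, ga3, 4L, 2L, 1L, TRUE)
  ga2 <- .lrelu_grad(cache$a2, b3$gx, sl)
  b2 <- .cpp_conv2d_bwd(cache$h1, e$W2, ga2, 4L, 2L, 1L, TRUE)
  ga1 <- .lrelu_grad(cache$a1, b2$gx, sl)
  b1 <- .cpp_conv2d_bwd(cache$x, e$W1, ga1, 4L, 2L, 1L, need_gx)

  list(grads = list(W1 = b1$gw, b1 = as.numeric(b1$gb),
                    W2 = b2$gw, b2 = as.numeric(b2$gb),
                    W3 = b3$gw, b3 = as.numeric(b3$gb),
                    Wz = g$Wz, bz = g$bz, Wd = g$Wd, bd = g$bd),
       gx = if (need_gx) b1$gx else NULL)
}

.gen_forward <- function(p, z, need_cache = TRUE) {
  sl <- p$meta$lrelu_slope
  gn <- p$gen
  n <- nrow(z)
  zarr <- array(t(z), dim = c(1L, 1L, p$meta$latent_dim, n))
  a1 <- .cpp_convt2d_fwd(zarr, gn$W1, gn$b1, 4L, 2L, 0L); h1 <- .lrelu(a1, sl)
  a2 <- .cpp_convt2d_fwd(h1, gn$W2, gn$b2, 4L, 2L, 1L); h2 <- .lrelu(a2, sl)
  a3 <- .cpp_convt2d_fwd(h2, gn$W3, gn$b3, 4L, 2L, 1L); h3 <- .lrelu(a3, sl)
  a4 <- .cpp_convt2d_fwd(h3, gn$W4, gn$b4, 4L, 2L, 1L)
  x <- tanh(a4)
  out <- list(x = x)
  if (need_cache) out$cache <- list(zarr = zarr, a1 = a1, h1 = h1, a2 = a2,
                                    h2 = h2, a3 = a3, h3 = h3, x = x)
  out
}

# Backprop through the generator given the loss gradient at the output image.
# Returns parameter gradients plus the gradient at the latent input (b x n_z),
# needed when the image-reconstruction loss also trains the encoder.
.gen_backward <- function(p, cache, gx) {
  sl <- p$meta$lrelu_slope
  gn <- p$gen
  ga4 <- .cpp_tanh_bwd(cache$x, gx) # g * (1 - tanh^2)
  b4 <- .cpp_convt2d_bwd(cache$h3, gn$W4, ga4, 4L, 2L, 1L, TRUE)
  ga3 <- .lrelu_grad(cache$a3, b4$gx, sl)
  b3 <- .cpp_convt2d_bwd(cache$h2, gn$W3, ga3, 4L, 2L, 1L, TRUE)
  ga2 <- .lrelu_grad(cache$a2, b3$gx, sl)
  b2 <- .cpp_convt2d_bwd(cache$h1, gn$W2, ga2, 4L, 2L, 1L, TRUE)
  ga1 <- .lrelu_grad(cache$a1, b2$gx, sl)
  b1 <- .cpp_convt2d_bwd(cache$zarr, gn$W1, ga1, 4L, 2L, 0L, TRUE)
  n <- dim(gx)[4]
  gz <- t(matrix(b1$gx, p$meta$latent_dim, n))
  list(grads = list(W1 = b1$gw, b1 = as.numeric(b1$gb),
                    W2 = b2$gw, b2 = as.numeric(b2$gb),
                    W3 = b3$gw, b3 = as.numeric(b3$gb),
                    W4 = b4$gw, b4 = as.numeric(b4$gb)),
       gz = gz)
}

#' Encode images to latent codes
#'
#' @param params a [pad_params()] object.
#' @param x image batch: array (32, 32, channels, b) with finite entries,
#'   pixel values in \[-1, 1\].
#' @return matrix (b x latent_dim) of unbounded real latent codes (the final
#'   convolution has no nonlinearity).
#' @export
pad_encode <- function(params, x) {
  .check_params(params)
  .check_encoder_input(params, x)
  .enc_forward(params, x, need_cache = FALSE)$z
}

#' Discriminator scores for an image batch
#'
#' Scores are sigmoid outputs in (0, 1): the probability assigned to "this
#' low-level activity is externally driven (real)".
#'
#' @inheritParams pad_encode
#' @return numeric vector of length b with entries strictly in (0, 1).
#' @export
pad_discriminate <- function(params, x) {
  .check_params(params)
  .check_encoder_input(params, x)
  .enc_forward(params, x, need_cache = FALSE)$d
}

#' Generate images from latent codes
#'
#' @param params a [pad_params()] object.
#' @param z latent batch: matrix (b x latent_dim).
#' @return image batch array (32, 32, channels, b) with entries in (-1, 1)
#'   (tanh output).
#' @export
pad_generate <- function(params, z) {
  .check_params(params)
  .check_latent_batch(z)
  if (ncol(z) != params$meta$latent_dim)
    stop("latent dimension mismatch: expected ", params$meta$latent_dim,
         ", got ", ncol(z))
  .gen_forward(params, z, need_cache = FALSE)$x
}

#' Save / load network parameters
#'
#' Checkpoints are a single-file archive (RDS) holding the named weight and
#' bias tensors keyed by layer (`enc$W1`, ..., `gen$W4`), the architecture
#' metadata, and any extra named objects supplied by the caller (e.g. the
#' training config or loss trace).
#'
#' @param params a [pad_params()] object.
#' @param path file path for the checkpoint.
#' @param extra named list of additional objects stored alongside the
#'   parameters.
#' @return `pad_save_checkpoint` returns `path` invisibly;
#'   `pad_load_checkpoint` returns the `pad_params` object, with any extras
#'   available via `attr(params, "extra")`.
#' @export
pad_save_checkpoint <- function(params, path, extra = list()) {
  .check_params(params)
  saveRDS(list(format = "padnet-checkpoint", version = 1L,
               params = unclass(params), extra = extra), path)
  invisible(path)
}

#' @rdname pad_save_checkpoint
#' @export
pad_load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "padnet-checkpoint"))
    stop("not a padnet checkpoint: ", path)
  p <- obj$params
  class(p) <- "pad_params"
  attr(p, "extra") <- obj$extra
  p
}
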