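# Phase-specific loss functions and the REM latent mixing rule.
#
# All losses are mini-batch means and permutation-invariant over the batch.
# Discriminator scores are clamped to [1e-7, 1 - 1e-7] inside log terms: the
# binary cross-entropy is undefined at the sigmoid limits.

.CLAMP <- 1e-7
.SIGMA2_FLOOR <- 1e-8

.clamp_scores <- function(d) {
  if (any(!is.finite(d)) || any(d < 0) || any(d > 1))
    stop("discriminator scores must lie in [0, 1]")
  pmin(pmax(d, .CLAMP), 1 - .CLAMP)
}

#' Wake image reconstruction loss
#'
#' Mean over the batch of the squared Euclidean distance between each image
#' and its reconstruction, `mean_i ||x_i - x'_i||^2`, summed over all pixel
#' entries of a sample.
#'
#' @param x,x_recon image batches of identical shape.
#' @return nonnegative scalar.
#' @export
image_reconstruction_loss <- function(x, x_recon) {
  d <- .check_image_batch(x); .check_image_batch(x_recon, "x_recon")
  if (!identical(d, dim(x_recon))) stop("shape mismatch between x and x_recon")
  sum((x - x_recon)^2) / d[4]
}

#' Batch-statistics Kullback-Leibler latent regularizer
#'
#' Encourages the latent code to be standard normal. Per latent dimension j,
#' the empirical batch mean `mu_j` and (population) standard deviation
#' `sigma_j` of the deterministic codes are plugged into the Gaussian KL
#' formula, then averaged:
#' `1/(2 n_z) * sum_j (mu_j^2 + sigma_j^2 - 1 - log sigma_j^2)`.
#' A floor of 1e-8 on `sigma_j^2` guards the log at degenerate batches. This
#' uses batch statistics, not per-sample variational parameters.
#'
#' @param z latent batch, matrix (b x n_z) with b >= 2.
#' @return nonnegative scalar (zero iff every dimension has mean 0, sd 1).
#' @export
kl_batch_loss <- function(z) {
  .check_latent_batch(z)
  if (nrow(z) < 2L) stop("kl_batch_loss needs a batch of at least 2 samples")
  mu <- colMeans(z)
  s2 <- colMeans(z^2) - mu^2       # population variance
  s2 <- pmax(s2, 0)                # numeric guard
  mean(mu^2 + s2 - 1 - log(pmax(s2, .SIGMA2_FLOOR))) / 2
}

# Gradient of kl_batch_loss at z (same shape as z).
.kl_batch_grad <- function(z) {
  b <- nrow(z); nz <- ncol(z)
  mu <- colMeans(z)
  s2 <- pmax(colMeans(z^2) - mu^2, .SIGMA2_FLOOR)
  zc <- sweep(z, 2L, mu)
  (matrix(mu, b, nz, byrow = TRUE) + sweep(zc, 2L, 1 - 1 / s2, `*`)) / (nz * b)
}

#' Discriminator loss on real images
#'
#' Binary cross-entropy with target "real": `-mean_i log d_i`.
#'
#' @param d discriminator scores in (0, 1).
#' @return nonnegative scalar.
#' @export
discriminator_real_loss <- function(d) {
  -mean(log(.clamp_scores(d)))
}

#' NREM latent reconstruction loss
#'
#' Mean squared Euclidean distance between the stored latent memories and the
#' codes recovered from the occluded generated images,
#' `mean_i ||z_i - z'_i||^2`. The stored target is a constant: no gradient
#' flows into the memory.
#'
#' @param z_target stored latent batch (b x n_z).
#' @param z_recon re-encoded latent batch of identical shape.
#' @return nonnegative scalar.
#' @export
nrem_reconstruction_loss <- function(z_target, z_recon) {
  .check_latent_batch(z_target, "z_target"); .check_latent_batch(z_recon, "z_recon")
  if (!identical(dim(z_target), dim(z_recon)))
    stop("shape mismatch between z_target and z_recon")
  sum((z_target - z_recon)^2) / nrow(z_target)
}

#' REM adversarial loss
#'
#' Binary cross-entropy of the discriminator on generated (internal) images
#' with target "fake": `-mean_i log(1 - d_i)`. The encoder/discriminator
#' descends this loss while the generator ascends it (sign switch).
#'
#' @param d_fake discriminator scores on generated images, in (0, 1).
#' @return nonnegative scalar.
#' @export
rem_adversarial_loss <- function(d_fake) {
  -mean(log(1 - .clamp_scores(d_fake)))
}

#' Mix episodic memories with spontaneous noise
#'
#' The REM latent input is the convex combination
#' `lam' * (lam * z + (1 - lam) * z_old) + (1 - lam') * eps`,
#' where `eps` is standard-normal spontaneous activity. With the defaults
#' `lam = lam' = 0.5` this is `0.25 z + 0.25 z_old + 0.5 eps`.
#'
#' @param z,z_old,eps latent batches of identical shape.
#' @param lam weight of the current vs the previous memory, in \[0, 1\].
#' @param lam_prime weight of memories vs noise, in \[0, 1\].
#' @return latent batch of the same shape.
#' @export
mix_memories <- function(z, z_old, eps, lam = 0.5, lam_prime = 0.5) {
  .check_latent_batch(z); .check_latent_batch(z_old, "z_old")
  .check_latent_batch(eps, "eps")
  if (!identical(dim(z), dim(z_old)) || !identical(dim(z), dim(eps)))
    stop("z, z_old and eps must have identical shapes")
  .stopifnot_scalar_prob(lam, "lam"); .stopifnot_scalar_prob(lam_prime, "lam_prime")
  lam_prime * (lam * z + (1 - lam) * z_old) + (1 - lam_prime) * eps
}

#' Noise-injected reconstruction loss (no-REM pathology)
#'
#' In the ablation without a REM phase, plain autoencoding overfits; the wake
#' reconstruction loss is therefore computed through a noisy latent code:
#' `mean_i ||x_i - G(E_z(x_i) + eps_i)||^2` with `eps_i ~ N(0, noise_var * I)`
#' (default covariance scale 0.5). With `noise_var = 0` this equals
#' [image_reconstruction_loss()] on the same batch.
#'
#' @param x image batch.
#' @param params a [pad_params()] object.
#' @param noise_var variance of the injected latent noise (>= 0).
#' @return nonnegative scalar. Draws from the current RNG.
#' @export
noisy_reconstruction_loss <- function(x, params, noise_var = 0.5) {
  .check_params(params)
  .check_encoder_input(params, x)
  if (!is.numeric(noise_var) || length(noise_var) != 1L || noise_var < 0)
    stop("noise_var must be a single nonnegative number")
  z <- .enc_forward(params, x, need_cache = FALSE)$z
  if (noise_var > 0)
    z <- z + matrix(rnorm(length(z), sd = sqrt(noise_var)), nrow(z), ncol(z))
  image_reconstruction_loss(x, .gen_forward(params, z, need_cache = FALSE)$x)
}
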