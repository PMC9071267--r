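# Representation-quality measurements: linear readout separability (clean and
# under occlusion), PCA projection, latent distance ratios, and the Frechet
# distance between feature statistics of real and generated images.

.check_labels <- function(labels, n, num_classes = NULL) {
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels length must match the number of samples")
  if (any(is.na(labels)) || any(labels < 0L))
    stop("labels must be nonnegative integers (0-based classes)")
  if (!is.null(num_classes) && any(labels >= num_classes))
    stop("label out of range: classes are 0..", num_classes - 1L)
  labels
}

# Encode a large image collection in mini-batches to bound memory.
.encode_all <- function(params, images, batch = 256L) {
  n <- dim(images)[4]
  z <- matrix(NA_real_, n, params$meta$latent_dim)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    z[i:j, ] <- pad_encode(params, images[, , , i:j, drop = FALSE])
    i <- j + 1L
  }
  z
}

#' Train a linear softmax readout on frozen latent codes
#'
#' A weight matrix W (num_classes x n_z, no bias) maps a latent code to class
#' scores y = W z; W is trained by mini-batch stochastic gradient descent on
#' the multiclass cross-entropy `-log softmax(y)[t]`, with learning rate 0.2
#' for 20 epochs over the whole training set (the defaults of the evaluation
#' protocol). The encoder is not touched: pass latents from a frozen model.
#'
#' @param latents matrix (n x n_z) of latent codes.
#' @param labels integer class labels in 0..num_classes-1.
#' @param num_classes number of classes (default `max(labels) + 1`).
#' @param learning_rate,epochs,batch_size SGD hyperparameters.
#' @param standardize center and scale each latent dimension (training-set
#'   statistics) before fitting. The composed readout is still linear in z,
#'   so linear separability is unchanged; this only conditions the fixed-rate
#'   SGD, which presumes roughly unit-scale (KL-regularized) latents and
#'   diverges when a desk-scale model drifts to larger scales.
#' @param seed seed for the per-epoch shuffle; the caller's RNG state is
#'   preserved.
#' @return an object of class `linear_readout` holding `W` and the
#'   standardization vectors `center`, `scale`.
#' @export
train_linear_readout <- function(latents, labels, num_classes = NULL,
                                 learning_rate = 0.2, epochs = 20L,
                                 batch_size = 64L, standardize = TRUE,
                                 seed = 1L) {
  .check_latent_batch(latents, "latents")
  n <- nrow(latents)
  if (is.null(num_classes)) num_classes <- max(as.integer(labels)) + 1L
  labels <- .check_labels(labels, n, num_classes)
  if (standardize) {
    center <- colMeans(latents)
    scale <- pmax(apply(latents, 2L, sd), 1e-8)
    latents <- sweep(sweep(latents, 2L, center), 2L, scale, `/`)
  } else {
    center <- numeric(ncol(latents))
    scale <- rep(1, ncol(latents))
  }
  W <- matrix(0, num_classes, ncol(latents))
  stream <- .rng_stream(seed)
  for (ep in seq_len(epochs)) {
    idx <- .with_stream(stream, sample.int(n))
    i <- 1L
    while (i <= n) {
      take <- idx[i:min(i + batch_size - 1L, n)]
      zb <- latents[take, , drop = FALSE]
      y <- zb %*% t(W)
      y <- y - apply(y, 1L, max) # softmax stabilization
      p <- exp(y); p <- p / rowSums(p)
      t1 <- matrix(0, nrow(p), num_classes)
      t1[cbind(seq_along(take), labels[take] + 1L)] <- 1
      W <- W - learning_rate * t(p - t1) %*% zb / length(take)
      i <- i + batch_size
    }
  }
  structure(list(W = W, num_classes = num_classes, center = center,
                 scale = scale),
            class = "linear_readout")
}

# Apply the readout's standardization (identity for hand-built readouts
# without center/scale fields).
.readout_input <- function(readout, latents) {
  if (is.null(readout$center)) return(latents)
  sweep(sweep(latents, 2L, readout$center), 2L, readout$scale, `/`)
}

#' @export
print.linear_readout <- function(x, ...) {
  cat("<linear_readout>", x$num_classes, "classes x", ncol(x$W), "latent dims\n")
  invisible(x)
}

#' Predict classes from latent codes
#'
#' The predicted class is the index of the maximal readout activity; ties
#' break toward the lowest index (deterministic evaluation).
#'
#' @param readout a [train_linear_readout()] object.
#' @param latents matrix (n x n_z).
#' @return integer vector of 0-based class predictions.
#' @export
predict_readout <- function(readout, latents) {
  if (!inherits(readout, "linear_readout")) stop("readout must be a 'linear_readout'")
  .check_latent_batch(latents, "latents")
  z <- .readout_input(readout, latents)
  max.col(z %*% t(readout$W), ties.method = "first") - 1L
}

#' Mean cross-entropy of the readout on labeled latents
#'
#' @inheritParams predict_readout
#' @param labels integer class labels in 0..num_classes-1.
#' @return nonnegative scalar; `log(num_classes)` at uniform logits.
#' @export
readout_loss <- function(readout, latents, labels) {
  labels <- .check_labels(labels, nrow(latents), readout$num_classes)
  y <- .readout_input(readout, latents) %*% t(readout$W)
  y <- y - apply(y, 1L, max)
  logp <- y - log(rowSums(exp(y)))
  -mean(logp[cbind(seq_len(nrow(latents)), labels + 1L)])
}

#' Linear separability: readout accuracy on held-out latents
#'
#' @inheritParams readout_loss
#' @return fraction of correct predictions, in \[0, 1\].
#' @export
linear_separability <- function(readout, latents, labels) {
  labels <- .check_labels(labels, nrow(latents), readout$num_classes)
  mean(predict_readout(readout, latents) == labels)
}

#' Readout accuracy as a function of occlusion intensity
#'
#' For each intensity q (in percent) every test image is occluded with patch
#' probability q/100 and the given square size (an independent mask per
#' sample), encoded, and classified by a readout that was trained on latents
#' of unoccluded images.
#'
#' @param readout a [train_linear_readout()] trained on clean latents.
#' @param params frozen [pad_params()].
#' @param images test image batch (32, 32, 3, n).
#' @param labels integer class labels.
#' @param intensities occlusion intensities in percent (default 0, 10, ..,
#'   100).
#' @param square_size patch size (evaluation convention: 4).
#' @param seed seed for the mask draws.
#' @return named numeric vector: accuracy per intensity.
#' @export
occlusion_robustness_curve <- function(readout, params, images, labels,
                                       intensities = seq(0L, 100L, 10L),
                                       square_size = 4L, seed = 1L) {
  .check_params(params)
  labels <- .check_labels(labels, dim(images)[4], readout$num_classes)
  stream <- .rng_stream(seed)
  acc <- vapply(intensities, function(q) {
    xo <- if (q == 0) images else
      .with_stream(stream, occlude_images(images, q / 100, square_size,
                                          per_sample = TRUE))
    linear_separability(readout, .encode_all(params, xo), labels)
  }, numeric(1))
  names(acc) <- paste0(intensities, "%")
  acc
}

#' Project latent codes onto the first two principal components
#'
#' @param latents matrix (n x n_z), n >= 3.
#' @return matrix (n x 2) of centered PCA scores.
#' @export
pca_projection <- function(latents) {
  .check_latent_batch(latents, "latents")
  if (nrow(latents) < 3L) stop("pca_projection needs at least 3 samples")
  pr <- prcomp(latents, center = TRUE, scale. = FALSE, rank. = 2L)
  sc <- pr$x
  if (ncol(sc) < 2L) stop("latent space has fewer than 2 dimensions")
  sc[, 1:2, drop = FALSE]
}

# Mean Euclidean distance between rows i and j of z for random index pairs.
.mean_pair_distance <- function(z, ii, jj) {
  mean(sqrt(rowSums((z[ii, , drop = FALSE] - z[jj, , drop = FALSE])^2)))
}

# Mean inter-class latent distance over n_inter random different-class pairs
# (sampling with replacement).
.inter_class_distance <- function(z, labels, n_inter) {
  n <- nrow(z)
  ii <- sample.int(n, n_inter, replace = TRUE)
  jj <- sample.int(n, n_inter, replace = TRUE)
  bad <- labels[ii] == labels[jj]
  while (any(bad)) {
    jj[bad] <- sample.int(n, sum(bad), replace = TRUE)
    bad <- labels[ii] == labels[jj]
  }
  .mean_pair_distance(z, ii, jj)
}

#' Intra/inter-class latent distance ratio
#'
#' Intra-class: for each class, the mean Euclidean latent distance over
#' `n_intra` random same-class pairs, averaged over classes. Inter-class: the
#' mean distance over `n_inter` random different-class pairs. The ratio
#' intra/inter is scale-free; lower means tighter semantic clustering.
#' Pairs are sampled with replacement.
#'
#' @param params frozen [pad_params()], or `NULL` when `images` is already a
#'   latent matrix.
#' @param images image batch (32, 32, 3, n), or a latent matrix (n x n_z).
#' @param labels integer class labels (every class needs >= 2 samples).
#' @param n_intra same-class pairs per class (reference protocol: 1000).
#' @param n_inter different-class pairs (reference protocol: 10000).
#' @param seed seed for pair sampling.
#' @return nonnegative scalar.
#' @export
intra_inter_ratio <- function(params, images, labels, n_intra = 1000L,
                              n_inter = 10000L, seed = 1L) {
  z <- if (is.matrix(images)) images else .encode_all(.check_params(params), images)
  labels <- .check_labels(labels, nrow(z))
  classes <- sort(unique(labels))
  if (any(tabulate(labels + 1L) == 1L))
    stop("every class needs at least 2 samples")
  .with_stream(.rng_stream(seed), {
    intra <- vapply(classes, function(cl) {
      members <- which(labels == cl)
      ii <- sample(members, n_intra, replace = TRUE)
      jj <- sample(members, n_intra, replace = TRUE)
      .mean_pair_distance(z, ii, jj)
    }, numeric(1))
    mean(intra) / .inter_class_distance(z, labels, n_inter)
  })
}

#' Clean-occluded latent distance over inter-class distance
#'
#' Samples `n_pairs` images (with replacement), encodes each both clean and
#' under a random occlusion at the given intensity (percent) and square size,
#' and averages the Euclidean distance between the two codes; the result is
#' divided by the mean inter-class distance of the clean codes. Lower means
#' representations more invariant to occlusion.
#'
#' @inheritParams intra_inter_ratio
#' @param n_pairs number of clean/occluded pairs (reference protocol: 10000).
#' @param intensity occlusion intensity in percent (reference protocol: 30).
#' @param square_size patch size (4).
#' @return nonnegative scalar.
#' @export
clean_occluded_ratio <- function(params, images, labels, n_pairs = 10000L,
                                 intensity = 30, square_size = 4L, seed = 1L) {
  .check_params(params)
  n <- dim(images)[4]
  labels <- .check_labels(labels, n)
  z_clean <- .encode_all(params, images)
  .with_stream(.rng_stream(seed), {
    ii <- sample.int(n, n_pairs, replace = TRUE)
    xo <- occlude_images(images[, , , ii, drop = FALSE], intensity / 100,
                         square_size, per_sample = TRUE)
    z_occ <- .encode_all(params, xo)
    num <- mean(sqrt(rowSums((z_clean[ii, , drop = FALSE] - z_occ)^2)))
    num / .inter_class_distance(z_clean, labels, max(n_pairs, 1000L))
  })
}

#' Frechet distance between two feature distributions
#'
#' The squared Frechet (2-Wasserstein) distance between Gaussians fitted to
#' the two feature collections:
#' `||mu1 - mu2||^2 + Tr(S1 + S2 - 2 (S1 S2)^{1/2})`.
#' The matrix square root is computed on the symmetrized product with small
#' negative eigenvalues clipped to zero. With Inception-v3 pool3 activations
#' as features this is the usual FID; any fixed feature extractor gives a
#' consistent relative measure (see [fid_features()]).
#'
#' @param features_real,features_gen matrices (n x d), n >= 2, equal d.
#' @return nonnegative scalar (up to numerical round-off).
#' @export
frechet_distance <- function(features_real, features_gen) {
  f1 <- as.matrix(features_real); f2 <- as.matrix(features_gen)
  if (ncol(f1) != ncol(f2)) stop("feature dimensionality mismatch")
  if (nrow(f1) < 2L || nrow(f2) < 2L) stop("need at least 2 samples per set")
  mu1 <- colMeans(f1); mu2 <- colMeans(f2)
  s1 <- cov(f1); s2 <- cov(f2)
  e1 <- eigen(s1, symmetric = TRUE)
  sq1 <- e1$vectors %*% (pmax(e1$values, 0)^0.5 * t(e1$vectors))
  m <- sq1 %*% s2 %*% sq1
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  sum((mu1 - mu2)^2) + sum(diag(s1)) + sum(diag(s2)) - 2 * sum(sqrt(pmax(ev, 0)))
}

#' Image features for Frechet-distance evaluation
#'
#' The reference protocol projects images through a pretrained Inception-v3
#' network; that embedding needs an external weight download, so the
#' extractor is pluggable. Offline desk-scale choices:
#' `"pixel"` averages each channel over 4x4 blocks (32x32x3 -> 8x8x3 = 192
#' dims); `"random_conv"` encodes with a fixed, seeded, randomly initialized
#' convolutional encoder (64 dims). Use one fixed extractor for both sides of
#' a comparison; values are comparable only within an extractor.
#'
#' @param images image batch (32, 32, 3, n).
#' @param extractor `"pixel"`, `"random_conv"`, or a function
#'   `images -> matrix (n x d)`.
#' @param seed seed of the random-conv embedding (ignored otherwise).
#' @return feature matrix (n x d).
#' @export
fid_features <- function(images, extractor = c("pixel", "random_conv"),
                         seed = 1L) {
  .check_image_batch(images, "images")
  if (is.function(extractor)) return(extractor(images))
  extractor <- match.arg(extractor)
  n <- dim(images)[4]
  if (extractor == "pixel") {
    block <- 4L
    d <- dim(images)
    out <- array(images, c(block, d[1] %/% block, block, d[2] %/% block, d[3], n))
    feats <- apply(out, c(2L, 4L, 5L, 6L), mean)
    return(t(matrix(feats, ncol = n)))
  }
  p <- pad_params(latent_dim = 64L, channels = c(16L, 32L, 64L), seed = seed)
  .encode_all(p, images)
}

#' Evaluate a trained model
#'
#' Runs the complete representation-quality suite against a frozen model:
#' trains the linear readout on latents of the training images, then reports
#' test separability, the occlusion robustness curve (size-4 squares), latent
#' distance ratios, PCA coordinates of the test latents, the naive-classifier
#' baseline (majority-class frequency of the test labels), and Frechet
#' distances of NREM dreams (occluded reconstructions of test latents) and
#' REM dreams (generated from mixed latent batches) to real images.
#'
#' @param params trained [pad_params()].
#' @param train_data,test_data datasets with `images` and `labels` (see
#'   [generate_synthetic()]).
#' @param intensities occlusion intensities (percent) for the robustness
#'   curve.
#' @param n_intra,n_inter,n_pairs pair counts for the distance ratios
#'   (reference protocol: 1000, 10000, 10000; scale down for desk use).
#' @param n_fid number of real/generated samples entering each Frechet
#'   distance.
#' @param fid_extractor see [fid_features()].
#' @param lam,lam_prime REM mixing coefficients used for the REM dream
#'   samples.
#' @param seed seed for all sampling in the evaluation.
#' @return an object of class `pad_metrics` (also a list): `separability`,
#'   `occlusion_curve`, `intra_inter_ratio`, `clean_occluded_ratio`,
#'   `fid_nrem`, `fid_rem`, `naive_baseline`, `pca` (n x 2 matrix),
#'   `readout`.
#' @export
pad_evaluate <- function(params, train_data, test_data,
                         intensities = seq(0L, 100L, 10L),
                         n_intra = 1000L, n_inter = 10000L, n_pairs = 10000L,
                         n_fid = 1000L, fid_extractor = "pixel",
                         lam = 0.5, lam_prime = 0.5, seed = 1L) {
  .check_params(params)
  z_train <- .encode_all(params, train_data$images)
  num_classes <- max(as.integer(train_data$labels),
                     as.integer(test_data$labels)) + 1L
  readout <- train_linear_readout(z_train, train_data$labels,
                                  num_classes = num_classes,
                                  seed = .child_seed(seed, 11L))
  z_test <- .encode_all(params, test_data$images)
  sep <- linear_separability(readout, z_test, test_data$labels)
  curve <- occlusion_robustness_curve(readout, params, test_data$images,
                                      test_data$labels,
                                      intensities = intensities,
                                      seed = .child_seed(seed, 12L))
  ratio_ii <- intra_inter_ratio(params, z_test, test_data$labels,
                                n_intra = n_intra, n_inter = n_inter,
                                seed = .child_seed(seed, 13L))
  ratio_co <- clean_occluded_ratio(params, test_data$images, test_data$labels,
                                   n_pairs = n_pairs,
                                   seed = .child_seed(seed, 14L))
  fids <- .dream_fids(params, train_data$images, n_fid, fid_extractor,
                      lam, lam_prime, seed = .child_seed(seed, 15L))
  naive <- max(tabulate(as.integer(test_data$labels) + 1L)) /
    length(test_data$labels)
  structure(list(separability = sep, occlusion_curve = curve,
                 intra_inter_ratio = ratio_ii, clean_occluded_ratio = ratio_co,
                 fid_nrem = fids["nrem"], fid_rem = fids["rem"],
                 naive_baseline = naive, pca = pca_projection(z_test),
                 readout = readout),
            class = c("pad_metrics", "list"))
}

#' @export
print.pad_metrics <- function(x, ...) {
  cat("<pad_metrics>\n")
  cat(sprintf("  separability          %.3f (naive baseline %.3f)\n",
              x$separability, x$naive_baseline))
  cat("  occlusion curve      ", paste(sprintf("%s=%.2f", names(x$occlusion_curve),
                                               x$occlusion_curve), collapse = " "), "\n")
  cat(sprintf("  intra/inter ratio     %.3f\n", x$intra_inter_ratio))
  cat(sprintf("  clean-occluded ratio  %.3f\n", x$clean_occluded_ratio))
  cat(sprintf("  FID (nrem, rem)       %.2f, %.2f\n", x$fid_nrem, x$fid_rem))
  invisible(x)
}

#' Generate dream samples from a trained model
#'
#' NREM dreams are occlusion-perturbed generator outputs of encoded images;
#' REM dreams are generated from the convex combination of two encoded
#' mini-batches mixed with spontaneous noise (the training-time recipe applied
#' at inference).
#'
#' @param params trained [pad_params()].
#' @param images source images whose latents seed the dreams.
#' @param n number of dream samples.
#' @param phase `"nrem"` or `"rem"`.
#' @param lam,lam_prime REM mixing coefficients.
#' @param seed RNG seed.
#' @return image batch (32, 32, 3, n).
#' @export
pad_dream <- function(params, images, n = 64L, phase = c("nrem", "rem"),
                      lam = 0.5, lam_prime = 0.5, seed = 1L) {
  .check_params(params)
  phase <- match.arg(phase)
  n_img <- dim(images)[4]
  .with_stream(.rng_stream(seed), {
    ii <- sample.int(n_img, n, replace = n > n_img)
    z <- .encode_all(params, images[, , , ii, drop = FALSE])
    if (phase == "nrem") {
      x <- pad_generate(params, z)
      spec <- sample_occlusion_spec()
      occlude_images(x, spec$probability, spec$square_size, per_sample = TRUE)
    } else {
      jj <- sample.int(n_img, n, replace = n > n_img)
      z_old <- .encode_all(params, images[, , , jj, drop = FALSE])
      eps <- matrix(rnorm(length(z)), nrow(z), ncol(z))
      pad_generate(params, mix_memories(z, z_old, eps, lam, lam_prime))
    }
  })
}

# Frechet distances of NREM and REM dream samples against real images.
.dream_fids <- function(params, images, n_fid, extractor, lam, lam_prime, seed) {
  n <- dim(images)[4]
  n_fid <- min(n_fid, n)
  real_idx <- .with_stream(.rng_stream(.child_seed(seed, 1L)),
                           sample.int(n, n_fid))
  f_real <- fid_features(images[, , , real_idx, drop = FALSE], extractor)
  x_nrem <- pad_dream(params, images, n_fid, "nrem", lam, lam_prime,
                      seed = .child_seed(seed, 2L))
  x_rem <- pad_dream(params, images, n_fid, "rem", lam, lam_prime,
                     seed = .child_seed(seed, 3L))
  c(nrem = frechet_distance(f_real, fid_features(x_nrem, extractor)),
    rem = frechet_distance(f_real, fid_features(x_rem, extractor)))
}
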