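# One-hot-separable latents: class c has a spike at coordinate c+1.
one_hot_latents <- function(n_per_class, num_classes, nz = 16, noise = 0,
                            seed = 1) {
  withr_seed(seed, {
    labels <- rep(0:(num_classes - 1), each = n_per_class)
    z <- matrix(rnorm(length(labels) * nz, sd = noise), length(labels), nz)
    z[cbind(seq_along(labels), labels + 1L)] <-
      z[cbind(seq_along(labels), labels + 1L)] + 5
    list(z = z, labels = labels)
  })
}

test_that("readout reaches 100% on one-hot-separable latents, reproducibly", {
  oh <- one_hot_latents(30, 4)
  ro <- train_linear_readout(oh$z, oh$labels, seed = 2)
  expect_identical(dim(ro$W), c(4L, 16L))
  expect_equal(linear_separability(ro, oh$z, oh$labels), 1.0)
  ro2 <- train_linear_readout(oh$z, oh$labels, seed = 2)
  expect_identical(ro$W, ro2$W)
  expect_error(train_linear_readout(oh$z, oh$labels, num_classes = 2),
               "out of range")
})

test_that("uniform logits give loss log(K); zero readout predicts class 0", {
  z <- random_latents(50, 16, seed = 3)
  labels <- withr_seed(4, sample(0:9, 50, replace = TRUE))
  ro0 <- structure(list(W = matrix(0, 10, 16), num_classes = 10L),
                   class = "linear_readout")
  expect_equal(readout_loss(ro0, z, labels), log(10))
  expect_true(all(predict_readout(ro0, z) == 0L)) # lowest-index tie break
  # balanced 10-class labels -> accuracy exactly 0.1 under the 0 readout
  labs <- rep(0:9, each = 5)
  expect_equal(linear_separability(ro0, random_latents(50, 16, seed = 5), labs), 0.1)
})

test_that("readout is robust to the latent scale via standardization", {
  oh <- one_hot_latents(30, 4, noise = 0.3, seed = 21)
  acc <- function(z) {
    ro <- train_linear_readout(z, oh$labels, seed = 2)
    linear_separability(ro, z, oh$labels)
  }
  expect_equal(acc(oh$z), acc(oh$z * 50)) # scale must not break the SGD
  expect_gte(acc(oh$z), 0.95)
})

test_that("readout on random labels stays near chance", {
  z <- random_latents(400, 8, seed = 6)
  labels <- withr_seed(7, sample(0:3, 400, replace = TRUE))
  ro <- train_linear_readout(z, labels, epochs = 5, seed = 8)
  acc <- linear_separability(ro, random_latents(400, 8, seed = 9),
                             withr_seed(10, sample(0:3, 400, replace = TRUE)))
  expect_lt(abs(acc - 0.25), 0.08)
})

test_that("occlusion curve: intensity 0 equals plain separability; 100 is constant input", {
  p <- tiny_params()
  ds <- tiny_dataset(num_classes = 3, n_per_class = 20, n_test_per_class = 10)
  z_tr <- pad_encode(p, ds$train$images)
  ro <- train_linear_readout(z_tr, ds$train$labels, seed = 1)
  curve <- occlusion_robustness_curve(ro, p, ds$test$images, ds$test$labels,
                                      intensities = c(0, 100), seed = 2)
  z_te <- pad_encode(p, ds$test$images)
  expect_equal(unname(curve["0%"]), linear_separability(ro, z_te, ds$test$labels))
  # fully occluded images are all-zero, so every sample gets the same class
  z0 <- pad_encode(p, array(0, c(32, 32, 3, 1)))
  pred0 <- predict_readout(ro, z0)
  expect_equal(unname(curve["100%"]), mean(ds$test$labels == pred0))
})

test_that("pca projection: exact 2-plane recovery and isotropic variance shares", {
  # points on an exact 2-plane embedded in 16 dims
  basis <- qr.Q(qr(matrix(rnorm(32), 16, 2)))
  scores <- matrix(rnorm(100), 50, 2) %*% diag(c(3, 1))
  z <- scores %*% t(basis)
  proj <- pca_projection(z)
  expect_identical(dim(proj), c(50L, 2L))
  # the projection preserves all variance of the 2-plane data
  expect_equal(sum(apply(proj, 2, var)), sum(apply(z, 2, var)))
  expect_error(pca_projection(z[1:2, ]), "at least 3")

  iso <- random_latents(20000, 20, seed = 11)
  pr <- prcomp(iso)
  share <- sum(pr$sdev[1:2]^2) / sum(pr$sdev^2)
  expect_equal(share, 2 / 20, tolerance = 0.1) # finite-sample bias is upward
})

test_that("pca projection is sample-order invariant up to sign", {
  z <- random_latents(40, 10, seed = 14)
  perm <- withr_seed(15, sample.int(40))
  p1 <- pca_projection(z)
  p2 <- pca_projection(z[perm, ])
  for (k in 1:2) {
    same <- max(abs(p2[, k] - p1[perm, k]))
    flip <- max(abs(p2[, k] + p1[perm, k]))
    expect_lt(min(same, flip), 1e-8)
  }
})

test_that("intra/inter ratio: degenerate clusters, isotropy, scale invariance", {
  # zero-variance clusters at distinct centers -> ratio 0
  centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
  z <- centers[rep(1:3, each = 20), ]
  labels <- rep(0:2, each = 20)
  expect_equal(intra_inter_ratio(NULL, z, labels, n_intra = 200,
                                 n_inter = 500, seed = 1), 0)

  # class-independent isotropic latents -> ratio ~ 1
  zi <- random_latents(900, 16, seed = 12)
  li <- rep(0:2, each = 300)
  r <- intra_inter_ratio(NULL, zi, li, n_intra = 2000, n_inter = 6000, seed = 2)
  expect_equal(r, 1, tolerance = 0.05)

  # global scaling cancels
  r1 <- intra_inter_ratio(NULL, zi, li, seed = 3, n_intra = 500, n_inter = 2000)
  r2 <- intra_inter_ratio(NULL, zi * 7, li, seed = 3, n_intra = 500, n_inter = 2000)
  expect_equal(r1, r2)
  expect_error(intra_inter_ratio(NULL, zi[1:4, ], c(0, 0, 1, 2)), "at least 2")
})

test_that("pair metrics are seed-reproducible and stable across seeds", {
  ds <- tiny_dataset(num_classes = 3, n_per_class = 40, n_test_per_class = 5)
  p <- tiny_params(seed = 2)
  z <- pad_encode(p, ds$train$images)
  a <- intra_inter_ratio(NULL, z, ds$train$labels, n_intra = 1000,
                         n_inter = 5000, seed = 5)
  b <- intra_inter_ratio(NULL, z, ds$train$labels, n_intra = 1000,
                         n_inter = 5000, seed = 5)
  expect_identical(a, b)
  c_ <- intra_inter_ratio(NULL, z, ds$train$labels, n_intra = 1000,
                          n_inter = 5000, seed = 6)
  expect_lt(abs(a - c_) / a, 0.05) # < 5% relative across seeds
})

test_that("clean-occluded ratio: zero at zero occlusion, grows with intensity", {
  p <- tiny_params(seed = 3)
  ds <- tiny_dataset(num_classes = 3, n_per_class = 15, n_test_per_class = 5)
  imgs <- ds$train$images
  labs <- ds$train$labels
  r0 <- clean_occluded_ratio(p, imgs, labs, n_pairs = 200, intensity = 0, seed = 4)
  expect_equal(r0, 0)
  r30 <- clean_occluded_ratio(p, imgs, labs, n_pairs = 400, intensity = 30, seed = 4)
  r70 <- clean_occluded_ratio(p, imgs, labs, n_pairs = 400, intensity = 70, seed = 4)
  expect_gt(r30, 0)
  expect_gt(r70, r30)
})

test_that("frechet distance: identity, 1-d closed forms, symmetry, rotation", {
  f <- matrix(rnorm(400), 200, 2)
  expect_equal(frechet_distance(f, f), 0, tolerance = 1e-8)

  # 1-d, means differing by d, equal variances -> d^2
  a <- matrix(rnorm(5000), ncol = 1)
  a <- a - mean(a) # exact zero mean so the closed forms are exact
  expect_equal(frechet_distance(a, a + 3), 9, tolerance = 1e-6)

  # 1-d, equal means, variances v1 and v2 -> (sqrt(v1) - sqrt(v2))^2
  b <- a * 2 # var 4 * var(a)
  v1 <- var(as.numeric(a)); v2 <- var(as.numeric(b))
  expect_equal(frechet_distance(a, b), (sqrt(v1) - sqrt(v2))^2, tolerance = 1e-6)

  # symmetry and invariance under a common orthogonal transform
  x1 <- matrix(rnorm(600), 200, 3); x2 <- matrix(rnorm(600, 1, 2), 200, 3)
  expect_equal(frechet_distance(x1, x2), frechet_distance(x2, x1),
               tolerance = 1e-8)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(frechet_distance(x1 %*% Q, x2 %*% Q), frechet_distance(x1, x2),
               tolerance = 1e-6)
  expect_error(frechet_distance(x1, x1[, 1:2]), "mismatch")
  expect_error(frechet_distance(x1[1, , drop = FALSE], x1), "at least 2")
})

test_that("fid features: pixel block averaging and pluggable extractors", {
  x <- random_images(5, seed = 13)
  f <- fid_features(x, "pixel")
  expect_identical(dim(f), c(5L, 192L))
  # first feature is the mean of the top-left 4x4 block of channel 1
  expect_equal(f[1, 1], mean(x[1:4, 1:4, 1, 1]))
  f2 <- fid_features(x, "random_conv", seed = 1)
  expect_identical(dim(f2), c(5L, 64L))
  expect_identical(f2, fid_features(x, "random_conv", seed = 1))
  f3 <- fid_features(x, extractor = function(img) matrix(1, dim(img)[4], 2))
  expect_identical(dim(f3), c(5L, 2L))
})

test_that("pad_evaluate assembles a coherent metrics report", {
  ds <- tiny_dataset(num_classes = 3, n_per_class = 20, n_test_per_class = 8)
  p <- tiny_params(seed = 5)
  m <- pad_evaluate(p, ds$train, ds$test, intensities = c(0, 50),
                    n_intra = 100, n_inter = 400, n_pairs = 100,
                    n_fid = 50, seed = 3)
  expect_s3_class(m, "pad_metrics")
  expect_true(m$separability >= 0 && m$separability <= 1)
  expect_named(m$occlusion_curve, c("0%", "50%"))
  expect_true(all(m$occlusion_curve >= 0 & m$occlusion_curve <= 1))
  expect_gte(m$intra_inter_ratio, 0)
  expect_gte(m$clean_occluded_ratio, 0)
  expect_gte(m$fid_nrem, 0)
  expect_gte(m$fid_rem, 0)
  expect_equal(m$naive_baseline, 1 / 3)
  expect_identical(dim(m$pca), c(24L, 2L))
  m2 <- pad_evaluate(p, ds$train, ds$test, intensities = c(0, 50),
                     n_intra = 100, n_inter = 400, n_pairs = 100,
                     n_fid = 50, seed = 3)
  expect_equal(m$separability, m2$separability)
  expect_equal(m$fid_rem, m2$fid_rem)
})

test_that("dream sampling is reproducible and in range", {
  p <- tiny_params(seed = 6)
  ds <- tiny_dataset(num_classes = 2, n_per_class = 10, n_test_per_class = 2)
  for (phase in c("nrem", "rem")) {
    d1 <- pad_dream(p, ds$train$images, n = 6, phase = phase, seed = 9)
    d2 <- pad_dream(p, ds$train$images, n = 6, phase = phase, seed = 9)
    expect_identical(d1, d2)
    expect_identical(dim(d1), c(32L, 32L, 3L, 6L))
    expect_true(all(d1 >= -1 & d1 <= 1))
  }
})
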