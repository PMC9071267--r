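test_that("initialization is deterministic, configurable and fan-in-scaled", {
  p1 <- pad_params(latent_dim = 256, seed = 0)
  p2 <- pad_params(latent_dim = 256, seed = 0)
  expect_identical(p1, p2)
  p3 <- pad_params(latent_dim = 256, seed = 1)
  expect_false(identical(p1$enc$W1, p3$enc$W1))

  # configurable latent width
  p8 <- tiny_params(latent_dim = 8)
  z <- pad_encode(p8, random_images(3))
  expect_identical(dim(z), c(3L, 8L))

  # kernels ~ N(0, 2/fan_in), biases zero
  expect_equal(sd(p1$enc$W2), sqrt(2 / (16 * 64)), tolerance = 0.05)
  expect_true(all(p1$enc$b1 == 0) && all(p1$gen$b4 == 0))
  expect_error(pad_params(latent_dim = 0), "latent_dim")
})

test_that("encoder trunk halves feature size down to a 1x1 latent map", {
  p <- tiny_params()
  x <- random_images(2)
  a1 <- padnet:::.cpp_conv2d_fwd(x, p$enc$W1, p$enc$b1, 4L, 2L, 1L)
  expect_identical(dim(a1)[1:2], c(16L, 16L))
  a2 <- padnet:::.cpp_conv2d_fwd(a1, p$enc$W2, p$enc$b2, 4L, 2L, 1L)
  expect_identical(dim(a2)[1:2], c(8L, 8L))
  a3 <- padnet:::.cpp_conv2d_fwd(a2, p$enc$W3, p$enc$b3, 4L, 2L, 1L)
  expect_identical(dim(a3)[1:2], c(4L, 4L))
  a4 <- padnet:::.cpp_conv2d_fwd(a3, p$enc$Wz, p$enc$bz, 4L, 2L, 0L)
  expect_identical(dim(a4), c(1L, 1L, 8L, 2L))
})

test_that("encode: shape, determinism, zero propagation, shape errors", {
  p <- tiny_params()
  x <- random_images(5)
  z <- pad_encode(p, x)
  expect_identical(dim(z), c(5L, p$meta$latent_dim))
  expect_true(all(is.finite(z)))
  expect_identical(z, pad_encode(p, x))

  # all-zero input with all-zero parameters -> all-zero latent
  p0 <- p
  for (k in names(p0$enc)) p0$enc[[k]] <- p0$enc[[k]] * 0
  expect_true(all(pad_encode(p0, array(0, c(32, 32, 3, 2))) == 0))

  expect_error(pad_encode(p, array(0, c(16, 16, 3, 2))), "32 x 32")
  expect_error(pad_encode(p, matrix(0, 4, 4)), "4-d array")
})

test_that("discriminator scores are sigmoid outputs, one per sample", {
  p <- tiny_params()
  d <- pad_discriminate(p, random_images(7))
  expect_length(d, 7L)
  expect_true(all(d > 0 & d < 1))
  # zero head weights force the pre-activation to 0 -> score exactly 0.5
  p0 <- p
  p0$enc$Wd <- p0$enc$Wd * 0
  p0$enc$bd <- 0
  expect_equal(pad_discriminate(p0, random_images(3)), rep(0.5, 3))
})

test_that("generator doubles feature size to a (-1,1) 32x32 image", {
  p <- tiny_params()
  z <- random_latents(6)
  x <- pad_generate(p, z)
  expect_identical(dim(x), c(32L, 32L, 3L, 6L))
  expect_true(all(x > -1 & x < 1))
  expect_identical(x, pad_generate(p, z))
  # intermediate spatial sizes 1 -> 4 -> 8 -> 16 -> 32
  zarr <- array(t(z), c(1, 1, 8, 6))
  a1 <- padnet:::.cpp_convt2d_fwd(zarr, p$gen$W1, p$gen$b1, 4L, 2L, 0L)
  expect_identical(dim(a1)[1:2], c(4L, 4L))
  a2 <- padnet:::.cpp_convt2d_fwd(a1, p$gen$W2, p$gen$b2, 4L, 2L, 1L)
  expect_identical(dim(a2)[1:2], c(8L, 8L))
  expect_error(pad_generate(p, random_latents(2, nz = 5)), "mismatch")
})

test_that("round trip: encode(generate(z)) preserves the latent shape", {
  p <- tiny_params()
  z <- random_latents(4)
  expect_identical(dim(pad_encode(p, pad_generate(p, z))), dim(z))
})

test_that("trunk is shared between heads; each head stays private", {
  p <- tiny_params()
  x <- random_images(3)
  z0 <- pad_encode(p, x); d0 <- pad_discriminate(p, x)

  p_trunk <- p; p_trunk$enc$W2[1] <- p_trunk$enc$W2[1] + 0.5
  expect_gt(max_abs_diff(pad_encode(p_trunk, x), z0), 0)
  expect_gt(max_abs_diff(pad_discriminate(p_trunk, x), d0), 0)

  p_z <- p; p_z$enc$Wz[1] <- p_z$enc$Wz[1] + 0.5
  expect_gt(max_abs_diff(pad_encode(p_z, x), z0), 0)
  expect_identical(pad_discriminate(p_z, x), d0)

  p_d <- p; p_d$enc$Wd[1] <- p_d$enc$Wd[1] + 0.5
  expect_identical(pad_encode(p_d, x), z0)
  expect_gt(max_abs_diff(pad_discriminate(p_d, x), d0), 0)
})

test_that("backprop matches central finite differences", {
  p <- tiny_params(seed = 3)
  x <- random_images(2, seed = 5)
  ef <- padnet:::.enc_forward(p, x)
  R <- random_latents(2, seed = 6)
  S <- c(0.7, -1.1)
  gb <- padnet:::.enc_backward(p, ef$cache, gz = R, gdlogit = S, need_gx = TRUE)
  loss_e <- function(pp, xx = x) {
    e <- padnet:::.enc_forward(pp, xx, need_cache = FALSE)
    sum(e$z * R) + sum(e$dlogit * S)
  }
  eps <- 1e-6
  for (k in c("W1", "W2", "W3", "Wz", "Wd", "bz", "bd")) {
    i <- withr_seed(match(k, names(p$enc)), sample.int(length(p$enc[[k]]), 1))
    pp <- pm <- p
    pp$enc[[k]][i] <- pp$enc[[k]][i] + eps
    pm$enc[[k]][i] <- pm$enc[[k]][i] - eps
    expect_equal(gb$grads[[k]][i], (loss_e(pp) - loss_e(pm)) / (2 * eps),
                 tolerance = 1e-4, label = paste("enc grad", k))
  }
  i <- 1234L
  xp <- xm <- x
  xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
  expect_equal(gb$gx[i], (loss_e(p, xp) - loss_e(p, xm)) / (2 * eps),
               tolerance = 1e-4)

  z <- random_latents(2, seed = 7)
  gf <- padnet:::.gen_forward(p, z)
  Q <- withr_seed(8, array(rnorm(length(gf$x)), dim(gf$x)))
  gg <- padnet:::.gen_backward(p, gf$cache, Q)
  loss_g <- function(pp, zz = z)
    sum(padnet:::.gen_forward(pp, zz, need_cache = FALSE)$x * Q)
  for (k in c("W1", "W2", "W3", "W4")) {
    i <- withr_seed(match(k, names(p$gen)), sample.int(length(p$gen[[k]]), 1))
    pp <- pm <- p
    pp$gen[[k]][i] <- pp$gen[[k]][i] + eps
    pm$gen[[k]][i] <- pm$gen[[k]][i] - eps
    expect_equal(gg$grads[[k]][i], (loss_g(pp) - loss_g(pm)) / (2 * eps),
                 tolerance = 1e-4, label = paste("gen grad", k))
  }
  i <- 5L
  zp <- zm <- z
  zp[i] <- zp[i] + eps; zm[i] <- zm[i] - eps
  expect_equal(gg$gz[i], (loss_g(p, zp) - loss_g(p, zm)) / (2 * eps),
               tolerance = 1e-4)
})

test_that("checkpoints round-trip parameters and extras", {
  p <- tiny_params(seed = 11)
  f <- tempfile(fileext = ".rds")
  pad_save_checkpoint(p, f, extra = list(note = "hello"))
  q <- pad_load_checkpoint(f)
  expect_identical(q$enc, p$enc)
  expect_identical(q$gen, p$gen)
  expect_identical(attr(q, "extra")$note, "hello")
  x <- random_images(2)
  expect_identical(pad_encode(q, x), pad_encode(p, x))
  expect_error(pad_load_checkpoint(tempfile()), "not found")
  bad <- tempfile(fileext = ".rds"); saveRDS(list(a = 1), bad)
  expect_error(pad_load_checkpoint(bad), "not a padnet checkpoint")
})
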