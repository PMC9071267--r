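test_that("pathology configurations map to the documented modifications", {
  full <- pad_pathology_config("full")
  expect_true(full$enable_nrem && full$enable_rem)
  expect_identical(full$memory_mix_mode, "mix")
  expect_equal(c(full$lam, full$lam_prime), c(0.5, 0.5))
  expect_equal(full$nrem_loss_scale, 1)

  worem <- pad_pathology_config("wo_rem")
  expect_false(worem$enable_rem)
  expect_equal(worem$nrem_loss_scale, 0.5) # NREM loss scaled down by 0.5
  expect_equal(worem$wake_noise_var, 0.5)  # latent noise covariance scale 0.5

  expect_false(pad_pathology_config("wo_nrem")$enable_nrem)
  expect_identical(pad_pathology_config("wo_mix")$memory_mix_mode, "single")
  expect_identical(pad_pathology_config("noise_only_rem")$memory_mix_mode,
                   "noise_only")
  expect_identical(pad_pathology_config("swapped_order")$phase_order, "rem_first")
  expect_error(pad_pathology_config("bogus"))
  expect_error(pad_pathology_config("wo_rem", enable_rem = TRUE), "override")
  # defaults carry the reference optimizer settings
  expect_equal(full$learning_rate, 2e-4)
  expect_equal(c(full$adam_beta1, full$adam_beta2), c(0.5, 0.999))
  expect_identical(full$batch_size, 64L)
})

test_that("zero learning rate leaves all parameters unchanged", {
  cfg <- tiny_config(learning_rate = 0, seed = 4)
  st <- pad_init_state(cfg)
  before <- st$params
  x <- random_images(8, seed = 1)
  st <- wake_phase(st, x, cfg)
  st <- nrem_phase(st, cfg)
  st <- rem_phase(st, cfg)
  expect_identical(st$params$enc, before$enc)
  expect_identical(st$params$gen, before$gen)
})

test_that("wake phase stores the pre-update encoding and trains reconstruction", {
  # a fixture learning rate suited to 200 steps on a tiny net
  cfg <- tiny_config(learning_rate = 1e-3, seed = 5)
  st <- pad_init_state(cfg)
  ds <- tiny_dataset(num_classes = 2, n_per_class = 4, n_test_per_class = 1)
  x <- ds$train$images
  z_pre <- pad_encode(st$params, x)
  st <- wake_phase(st, x, cfg)
  expect_identical(st$buffer$current, z_pre)

  # repeated wake-only updates on a fixed tiny batch shrink the image loss
  losses <- numeric(200)
  for (i in seq_len(200)) {
    st$losses <- NULL
    st <- wake_phase(st, x, cfg)
    losses[i] <- st$losses$img
  }
  expect_lt(mean(tail(losses, 20)), 0.6 * mean(head(losses, 20)))
})

test_that("NREM updates only the encoder; zero scale freezes it too", {
  cfg <- tiny_config(seed = 6)
  st <- pad_init_state(cfg)
  st <- wake_phase(st, random_images(8, seed = 3), cfg)
  gen_before <- st$params$gen
  enc_before <- st$params$enc
  st <- nrem_phase(st, cfg)
  expect_identical(st$params$gen, gen_before) # bit-identical generator
  expect_false(identical(st$params$enc, enc_before))

  cfg0 <- tiny_config(nrem_loss_scale = 0, seed = 6)
  st0 <- pad_init_state(cfg0)
  st0 <- wake_phase(st0, random_images(8, seed = 3), cfg0)
  enc0 <- st0$params$enc; gen0 <- st0$params$gen
  st0 <- nrem_phase(st0, cfg0)
  expect_identical(st0$params$enc, enc0)
  expect_identical(st0$params$gen, gen0)
  expect_error(nrem_phase(pad_init_state(cfg), cfg), "empty")
})

test_that("NREM loss is near zero when the generator inverts the encoder", {
  # construct the fixture by training wake-only until reconstruction is good,
  # then check L_NREM with occlusion forced off
  ds <- generate_synthetic(num_classes = 2, n_per_class = 12,
                           n_test_per_class = 2, jitter = 1, noise_sd = 0.02,
                           seed = 7)
  cfg <- tiny_config(epochs = 300, learning_rate = 1e-3,
                     enable_nrem = FALSE, enable_rem = FALSE, seed = 7)
  fit <- pad_train(ds$train, cfg)
  z <- pad_encode(fit$params, ds$train$images[, , , 1:8, drop = FALSE])
  z_rt <- pad_encode(fit$params, pad_generate(fit$params, z)) # no occlusion
  rel <- nrem_reconstruction_loss(z, z_rt) / mean(rowSums(z^2))
  expect_lt(rel, 0.08)
})

test_that("REM phase: sign switch ascends the generator, descends the heads", {
  # freeze the REM latent source (single memory, no noise) so the loss is a
  # deterministic function of the parameters, then compare component-wise
  cfg <- tiny_config(memory_mix_mode = "single", learning_rate = 1e-3, seed = 8)
  st <- pad_init_state(cfg)
  # fresh Adam moments isolate the sign switch from wake-gradient momentum
  st$buffer <- buffer_store(st$buffer,
                            pad_encode(st$params, random_images(8, seed = 4)))
  p0 <- st$params
  z_mix <- st$buffer$current
  l_rem <- function(p) {
    x <- pad_generate(p, z_mix)
    rem_adversarial_loss(pad_discriminate(p, x))
  }
  st2 <- rem_phase(st, cfg)
  # generator update alone: loss goes up (ascent)
  p_gen <- p0; p_gen$gen <- st2$params$gen
  expect_gt(l_rem(p_gen), l_rem(p0))
  # encoder/discriminator update alone: loss goes down (descent)
  p_enc <- p0; p_enc$enc <- st2$params$enc
  expect_lt(l_rem(p_enc), l_rem(p0))
  # after the phase the previous slot holds this cycle's Z
  expect_identical(st2$buffer$previous, st2$buffer$current)
})

test_that("run_training: epoch arithmetic, determinism, phase switches", {
  ds <- tiny_dataset(num_classes = 2, n_per_class = 12, n_test_per_class = 2)
  # 24 images, batch 8 -> exactly 3 cycles per epoch (drop-last)
  cfg <- tiny_config(epochs = 2, seed = 9)
  fit <- pad_train(ds$train, cfg)
  expect_identical(nrow(fit$trace), 6L)
  expect_identical(fit$trace$epoch, rep(c(1, 2), each = 3))

  fit2 <- pad_train(ds$train, cfg)
  expect_identical(fit$trace, fit2$trace) # same seed -> identical traces
  expect_identical(fit$params$enc, fit2$params$enc)
  fit3 <- pad_train(ds$train, tiny_config(epochs = 2, seed = 10))
  expect_false(identical(fit$trace$loss_img, fit3$trace$loss_img))

  worem <- pad_train(ds$train, tiny_config(epochs = 1, enable_rem = FALSE, seed = 9))
  expect_true(all(is.na(worem$trace$loss_rem)))
  expect_false(anyNA(worem$trace$loss_nrem))
  wonrem <- pad_train(ds$train, tiny_config(epochs = 1, enable_nrem = FALSE, seed = 9))
  expect_true(all(is.na(wonrem$trace$loss_nrem)))

  swapped <- pad_train(ds$train,
                       tiny_config(epochs = 1, phase_order = "rem_first", seed = 9))
  expect_false(anyNA(swapped$trace$loss_rem))

  expect_error(pad_train(ds$test, tiny_config(batch_size = 64)), "smaller")

  # snapshots are deep copies from the requested epoch, not the final params
  fit4 <- pad_train(ds$train, tiny_config(epochs = 3, seed = 11),
                    snapshot_epochs = 1L)
  expect_named(fit4$snapshots, "epoch1")
  expect_false(identical(fit4$snapshots$epoch1$enc, fit4$params$enc))
})
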