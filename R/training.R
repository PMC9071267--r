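# The wake -> NREM -> REM training cycle with Adam updates, including the
# sleep-pathology ablations.
#
# One Adam optimizer state per network (encoder incl. both heads; generator),
# shared across phases and never reset. The REM sign switch is implemented as
# gradient ascent for the generator: the REM gradient is negated before the
# Adam step. Stored latents (Z, Z_old, Z_mix) are constants during NREM and
# REM updates: no gradient flows into the memory.

#' Training configuration
#'
#' Defaults follow the reference training regime: Adam with learning rate
#' 0.0002, beta1 = 0.5, beta2 = 0.999, mini-batch size 64, mixing
#' coefficients lam = lam' = 0.5. One epoch is the number of mini-batches
#' needed to cover the dataset (final short batch dropped).
#'
#' @param epochs number of passes over the dataset.
#' @param latent_dim,channels architecture, see [pad_params()].
#' @param learning_rate,adam_beta1,adam_beta2 Adam hyperparameters.
#' @param batch_size mini-batch size (>= 2; the latent KL term uses batch
#'   statistics).
#' @param lam,lam_prime REM mixing coefficients, see [mix_memories()].
#' @param enable_nrem,enable_rem phase switches.
#' @param memory_mix_mode REM latent source: `"mix"` (convex combination of
#'   current and previous memories plus noise), `"single"` (current memory
#'   only, no noise), or `"noise_only"` (spontaneous activity only).
#' @param nrem_loss_scale multiplier on the NREM loss (0.5 in the no-REM
#'   pathology, else 1).
#' @param wake_noise_var variance of Gaussian noise added to the encoded
#'   activities before generation in the wake reconstruction loss (0 in the
#'   full model; 0.5 in the no-REM pathology).
#' @param phase_order `"nrem_first"` (wake, NREM, REM) or `"rem_first"`
#'   (wake, REM, NREM).
#' @param seed integer master seed; all randomness (parameter init, data
#'   shuffling, occlusion, mixing noise, wake noise) derives from it.
#' @return an object of class `pad_config`.
#' @export
pad_config <- function(epochs = 1L,
                       latent_dim = 256L,
                       channels = c(64L, 128L, 256L),
                       learning_rate = 2e-4,
                       adam_beta1 = 0.5,
                       adam_beta2 = 0.999,
                       batch_size = 64L,
                       lam = 0.5,
                       lam_prime = 0.5,
                       enable_nrem = TRUE,
                       enable_rem = TRUE,
                       memory_mix_mode = c("mix", "single", "noise_only"),
                       nrem_loss_scale = 1,
                       wake_noise_var = 0,
                       phase_order = c("nrem_first", "rem_first"),
                       seed = 1L) {
  memory_mix_mode <- match.arg(memory_mix_mode)
  phase_order <- match.arg(phase_order)
  if (!is.numeric(learning_rate) || learning_rate < 0)
    stop("learning_rate must be nonnegative")
  if (adam_beta1 < 0 || adam_beta1 >= 1 || adam_beta2 < 0 || adam_beta2 >= 1)
    stop("Adam betas must lie in [0, 1)")
  batch_size <- as.integer(batch_size)
  if (batch_size < 2L) stop("batch_size must be >= 2")
  if (nrem_loss_scale < 0 || wake_noise_var < 0)
    stop("loss scales must be nonnegative")
  .stopifnot_scalar_prob(lam, "lam"); .stopifnot_scalar_prob(lam_prime, "lam_prime")
  structure(list(epochs = as.integer(epochs), latent_dim = as.integer(latent_dim),
                 channels = as.integer(channels), learning_rate = learning_rate,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 batch_size = batch_size, lam = lam, lam_prime = lam_prime,
                 enable_nrem = isTRUE(enable_nrem), enable_rem = isTRUE(enable_rem),
                 memory_mix_mode = memory_mix_mode,
                 nrem_loss_scale = nrem_loss_scale,
                 wake_noise_var = wake_noise_var, phase_order = phase_order,
                 seed = as.integer(seed)),
            class = "pad_config")
}

#' @export
print.pad_config <- function(x, ...) {
  cat("<pad_config>\n")
  for (k in names(x)) cat(sprintf("  %-16s %s\n", k, paste(x[[k]], collapse = " ")))
  invisible(x)
}

#' Configuration for a named sleep pathology
#'
#' * `full`: the unmodified model (all phases, memory mixing).
#' * `wo_rem`: REM disabled; the wake reconstruction loss injects latent
#'   Gaussian noise with variance 0.5 and the NREM loss is scaled by 0.5.
#' * `wo_nrem`: NREM disabled.
#' * `wo_mix`: REM driven by the single current memory, no noise.
#' * `noise_only_rem`: REM driven by spontaneous activity only.
#' * `swapped_order`: wake, REM, NREM instead of wake, NREM, REM.
#'
#' @param name pathology name.
#' @param ... further arguments passed to [pad_config()] (e.g. `epochs`,
#'   `seed`, `channels`).
#' @return a `pad_config`.
#' @export
pad_pathology_config <- function(name = c("full", "wo_rem", "wo_nrem", "wo_mix",
                                          "noise_only_rem", "swapped_order"),
                                 ...) {
  name <- match.arg(name)
  mods <- switch(name,
    full = list(),
    wo_rem = list(enable_rem = FALSE, wake_noise_var = 0.5, nrem_loss_scale = 0.5),
    wo_nrem = list(enable_nrem = FALSE),
    wo_mix = list(memory_mix_mode = "single"),
    noise_only_rem = list(memory_mix_mode = "noise_only"),
    swapped_order = list(phase_order = "rem_first"))
  user <- list(...)
  clash <- intersect(names(mods), names(user))
  if (length(clash))
    stop("cannot override pathology-defining field(s): ", paste(clash, collapse = ", "))
  cfg <- do.call(pad_config, c(user, mods))
  attr(cfg, "pathology") <- name
  cfg
}

# ---- Adam ----------------------------------------------------------------

.adam_init <- function(theta) {
  list(t = 0L,
       m = lapply(theta, function(w) w * 0),
       v = lapply(theta, function(w) w * 0))
}

.adam_step <- function(theta, grads, opt, lr, beta1, beta2, eps = 1e-8,
                       ascent = FALSE) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (k in names(theta)) {
    g <- grads[[k]]
    if (ascent) g <- -g
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * g
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * g * g
    theta[[k]] <- theta[[k]] -
      lr * (opt$m[[k]] / c1) / (sqrt(opt$v[[k]] / c2) + eps)
  }
  list(theta = theta, opt = opt)
}

# ---- training state -------------------------------------------------------

#' Initialize a training state
#'
#' Builds seeded network parameters, one Adam state per network, an empty
#' episodic buffer and independent RNG streams for data shuffling, occlusion,
#' REM mixing noise and wake noise injection.
#'
#' @param config a [pad_config()].
#' @return an object of class `pad_state`.
#' @export
pad_init_state <- function(config) {
  if (!inherits(config, "pad_config")) stop("config must be a 'pad_config'")
  params <- pad_params(config$latent_dim, config$channels,
                       seed = .child_seed(config$seed, 5L))
  structure(list(
    params = params,
    opt_enc = .adam_init(params$enc),
    opt_gen = .adam_init(params$gen),
    buffer = episodic_buffer(),
    iter = 0L, epoch = 0L,
    losses = NULL,
    streams = list(data = .rng_stream(.child_seed(config$seed, 1L)),
                   occ = .rng_stream(.child_seed(config$seed, 2L)),
                   mix = .rng_stream(.child_seed(config$seed, 3L)),
                   wake = .rng_stream(.child_seed(config$seed, 4L)))),
    class = "pad_state")
}

.check_state <- function(state) {
  if (!inherits(state, "pad_state")) stop("state must be a 'pad_state'")
  invisible(state)
}

# ---- phases ---------------------------------------------------------------

#' Run one wake phase on a mini-batch
#'
#' Encodes the batch, reconstructs it through the generator and scores it
#' with the discriminator. The encoder (trunk + both heads) descends
#' `L_img + L_KL + L_real`; the generator descends `L_img` alone. The latent
#' batch is then stored in the episodic buffer. When
#' `config$wake_noise_var > 0` (no-REM pathology) the reconstruction uses a
#' noise-injected latent code, while the stored memory stays clean.
#'
#' @param state a [pad_init_state()] object.
#' @param x image batch (32, 32, channels, batch_size).
#' @param config the [pad_config()] used throughout training.
#' @return the updated state; per-phase losses are in `state$losses`.
#' @export
wake_phase <- function(state, x, config) {
  .check_state(state)
  p <- state$params
  .check_encoder_input(p, x)
  b <- dim(x)[4]

  ef <- .enc_forward(p, x)
  z <- ef$z
  z_gen <- z
  if (config$wake_noise_var > 0) {
    eps <- .with_stream(state$streams$wake,
                        matrix(rnorm(length(z), sd = sqrt(config$wake_noise_var)),
                               nrow(z), ncol(z)))
    z_gen <- z + eps
  }
  gf <- .gen_forward(p, z_gen)

  l_img <- image_reconstruction_loss(x, gf$x)
  l_kl <- kl_batch_loss(z)
  l_real <- discriminator_real_loss(ef$d)

  g_xrec <- 2 * (gf$x - x) / b
  gb_gen <- .gen_backward(p, gf$cache, g_xrec)
  gz <- gb_gen$gz + .kl_batch_grad(z)
  gdlogit <- (ef$d - 1) / b # d/dlogit of -mean log sigmoid(logit)
  gb_enc <- .enc_backward(p, ef$cache, gz = gz, gdlogit = gdlogit)

  up_e <- .adam_step(p$enc, gb_enc$grads, state$opt_enc, config$learning_rate,
                     config$adam_beta1, config$adam_beta2)
  up_g <- .adam_step(p$gen, gb_gen$grads, state$opt_gen, config$learning_rate,
                     config$adam_beta1, config$adam_beta2)
  state$params$enc <- up_e$theta; state$opt_enc <- up_e$opt
  state$params$gen <- up_g$theta; state$opt_gen <- up_g$opt

  state$buffer <- buffer_store(state$buffer, z)
  state$losses <- c(state$losses,
                    list(img = l_img, kl = l_kl, real = l_real,
                         wake = l_img + l_kl + l_real))
  state
}

#' Run one NREM (perturbed dreaming) phase
#'
#' Replays the stored latent batch through the generator, occludes the
#' generated images with a random patch mask (one spec per mini-batch, a
#' fresh mask realization per sample), re-encodes, and updates the encoder
#' alone by descent on `nrem_loss_scale * L_NREM`. The generator is not
#' touched.
#'
#' @inheritParams wake_phase
#' @return the updated state.
#' @export
nrem_phase <- function(state, config) {
  .check_state(state)
  p <- state$params
  z <- recall_nrem(state$buffer)
  b <- nrow(z)

  x_gen <- .gen_forward(p, z, need_cache = FALSE)$x
  x_occ <- .with_stream(state$streams$occ, {
    spec <- sample_occlusion_spec()
    occlude_images(x_gen, spec$probability, spec$square_size, per_sample = TRUE)
  })
  ef <- .enc_forward(p, x_occ)
  l_nrem <- nrem_reconstruction_loss(z, ef$z)

  if (config$nrem_loss_scale > 0) {
    gz <- config$nrem_loss_scale * 2 * (ef$z - z) / b
    gb <- .enc_backward(p, ef$cache, gz = gz)
    up <- .adam_step(p$enc, gb$grads, state$opt_enc, config$learning_rate,
                     config$adam_beta1, config$adam_beta2)
    state$params$enc <- up$theta; state$opt_enc <- up$opt
  }
  state$losses <- c(state$losses, list(nrem = l_nrem))
  state
}

#' Run one REM (adversarial dreaming) phase
#'
#' Forms the REM latent input according to `config$memory_mix_mode`,
#' generates images, scores them with the discriminator, and updates the
#' encoder/discriminator by descent and the generator by ascent on `L_REM`
#' (the sign switch). Finally the previous-memory slot is set to this cycle's
#' latent batch.
#'
#' @inheritParams wake_phase
#' @return the updated state.
#' @export
rem_phase <- function(state, config) {
  .check_state(state)
  p <- state$params
  if (is.null(state$buffer$current)) stop("episodic buffer is empty")
  z_mix <- .with_stream(state$streams$mix,
                        recall_rem(state$buffer, lam = config$lam,
                                   lam_prime = config$lam_prime,
                                   mode = config$memory_mix_mode))
  b <- nrow(z_mix)

  gf <- .gen_forward(p, z_mix)
  ef <- .enc_forward(p, gf$x)
  l_rem <- rem_adversarial_loss(ef$d)

  gdlogit <- ef$d / b # d/dlogit of -mean log(1 - sigmoid(logit))
  gb_enc <- .enc_backward(p, ef$cache, gdlogit = gdlogit, need_gx = TRUE)
  gb_gen <- .gen_backward(p, gf$cache, gb_enc$gx)

  up_e <- .adam_step(p$enc, gb_enc$grads, state$opt_enc, config$learning_rate,
                     config$adam_beta1, config$adam_beta2)
  up_g <- .adam_step(p$gen, gb_gen$grads, state$opt_gen, config$learning_rate,
                     config$adam_beta1, config$adam_beta2, ascent = TRUE)
  state$params$enc <- up_e$theta; state$opt_enc <- up_e$opt
  state$params$gen <- up_g$theta; state$opt_gen <- up_g$opt

  state$buffer$previous <- state$buffer$current # Z_old <- Z
  state$losses <- c(state$losses, list(rem = l_rem))
  state
}

# ---- full training loop ---------------------------------------------------

#' Train the model with wake-sleep cycles
#'
#' Iterates wake, NREM and REM phases (order per `config$phase_order`,
#' disabled phases skipped) over seeded shuffled mini-batches for
#' `config$epochs` epochs. Fully reproducible given `config$seed`. Labels in
#' the dataset are ignored: training is unsupervised.
#'
#' @param dataset a labeled image dataset as returned by
#'   [generate_synthetic()]`$train`, [load_cifar10()] or [load_svhn()]; any
#'   list with an `images` array (32, 32, 3, n) in \[-1, 1\] works.
#' @param config a [pad_config()].
#' @param snapshot_epochs integer vector; a deep copy of the parameters is
#'   kept after each listed epoch (e.g. `1L` for early-vs-late comparisons).
#' @param verbose print per-epoch mean losses.
#' @return an object of class `pad_fit`: list with `params` (final
#'   [pad_params()]), `trace` (data frame with one row per cycle: epoch,
#'   cycle, loss_img, loss_kl, loss_real, loss_wake, loss_nrem, loss_rem),
#'   `snapshots` (named list of `pad_params`), and `config`.
#' @export
pad_train <- function(dataset, config, snapshot_epochs = integer(0),
                      verbose = FALSE) {
  if (!inherits(config, "pad_config")) stop("config must be a 'pad_config'")
  images <- dataset$images
  .check_image_batch(images, "dataset$images")
  n <- dim(images)[4]
  if (n < config$batch_size)
    stop("dataset smaller than one mini-batch (", n, " < ", config$batch_size, ")")

  state <- pad_init_state(config)
  n_batches <- n %/% config$batch_size
  total <- n_batches * config$epochs
  trace <- matrix(NA_real_, total, 8L,
                  dimnames = list(NULL, c("epoch", "cycle", "loss_img", "loss_kl",
                                          "loss_real", "loss_wake", "loss_nrem",
                                          "loss_rem")))
  snapshots <- list()

  for (epoch in seq_len(config$epochs)) {
    state$epoch <- epoch
    idx <- .with_stream(state$streams$data, sample.int(n))
    for (bi in seq_len(n_batches)) {
      take <- idx[((bi - 1L) * config$batch_size + 1L):(bi * config$batch_size)]
      x <- images[, , , take, drop = FALSE]
      state$losses <- NULL
      state <- wake_phase(state, x, config)
      phases <- if (config$phase_order == "nrem_first") c("nrem", "rem")
                else c("rem", "nrem")
      for (ph in phases) {
        if (ph == "nrem" && config$enable_nrem)
          state <- nrem_phase(state, config)
        if (ph == "rem" && config$enable_rem)
          state <- rem_phase(state, config)
      }
      state$iter <- state$iter + 1L
      ls <- state$losses
      trace[state$iter, ] <- c(epoch, state$iter, ls$img, ls$kl, ls$real,
                               ls$wake,
                               if (is.null(ls$nrem)) NA_real_ else ls$nrem,
                               if (is.null(ls$rem)) NA_real_ else ls$rem)
    }
    if (epoch %in% snapshot_epochs)
      snapshots[[paste0("epoch", epoch)]] <- state$params
    if (verbose) {
      rows <- trace[which(trace[, "epoch"] == epoch), , drop = FALSE]
      message(sprintf("epoch %d | img %.3f kl %.3f real %.3f nrem %s rem %s",
                      epoch, mean(rows[, "loss_img"]), mean(rows[, "loss_kl"]),
                      mean(rows[, "loss_real"]),
                      formatC(mean(rows[, "loss_nrem"]), format = "f", digits = 3),
                      formatC(mean(rows[, "loss_rem"]), format = "f", digits = 3)))
    }
  }
  structure(list(params = state$params, trace = as.data.frame(trace),
                 snapshots = snapshots, config = config),
            class = "pad_fit")
}

#' @export
print.pad_fit <- function(x, ...) {
  cat("<pad_fit>", nrow(x$trace), "cycles,", x$config$epochs, "epochs")
  if (length(x$snapshots))
    cat(", snapshots:", paste(names(x$snapshots), collapse = ", "))
  cat("\n")
  invisible(x)
}
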