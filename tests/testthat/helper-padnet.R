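# Shared fixtures: all tiny models/data are built in code at test time.

tiny_params <- function(latent_dim = 8L, channels = c(4L, 6L, 8L), seed = 1L) {
  pad_params(latent_dim = latent_dim, channels = channels, seed = seed)
}

random_images <- function(n = 4L, seed = 1L) {
  withr_seed(seed, array(runif(32 * 32 * 3 * n, -1, 1), c(32L, 32L, 3L, n)))
}

random_latents <- function(n = 4L, nz = 8L, seed = 1L) {
  withr_seed(seed, matrix(rnorm(n * nz), n, nz))
}

# evaluate expr under a seed without disturbing the session RNG
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

tiny_dataset <- function(num_classes = 3L, n_per_class = 30L,
                         n_test_per_class = 10L, seed = 7L) {
  generate_synthetic(num_classes = num_classes, n_per_class = n_per_class,
                     n_test_per_class = n_test_per_class, seed = seed)
}

tiny_config <- function(...) {
  args <- utils::modifyList(list(latent_dim = 8L, channels = c(4L, 6L, 8L),
                                 batch_size = 8L), list(...))
  do.call(pad_config, args)
}

max_abs_diff <- function(a, b) max(abs(a - b))
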