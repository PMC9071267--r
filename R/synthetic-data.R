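# Dataset access: a procedural generator of labeled 32x32 RGB shape images
# (download-free training and testing) and readers for the CIFAR-10 binary
# batch format and the SVHN cropped-digits MAT format. Pixels are normalized
# to [-1, 1] because the generator ends in tanh and the wake loss compares
# G's output to x directly.

.unit_from_u8 <- function(u8) u8 / 127.5 - 1

.u8_from_unit <- function(x) {
  u8 <- round((x + 1) * 127.5)
  pmin(pmax(u8, 0), 255)
}

#' Convert pixel values between 0..255 and \[-1, 1\]
#'
#' `pixels_to_unit` maps 0..255 to \[-1, 1\]; `unit_to_pixels` maps back to
#' rounded 0..255. A round trip through both reproduces unit-scale pixels to
#' within 1/255.
#'
#' @param x numeric array.
#' @return numeric array of the same shape.
#' @export
pixels_to_unit <- function(x) .unit_from_u8(x)

#' @rdname pixels_to_unit
#' @export
unit_to_pixels <- function(x) .u8_from_unit(x)

.pad_dataset <- function(images, labels, split) {
  structure(list(images = images, labels = as.integer(labels), split = split),
            class = "pad_dataset")
}

#' @export
print.pad_dataset <- function(x, ...) {
  cat("<pad_dataset>", x$split, "split:", dim(x$images)[4], "images,",
      length(unique(x$labels)), "classes\n")
  invisible(x)
}

# One boolean shape mask on a 32x32 grid. `cy`, `cx` center; `h` half-size.
.shape_mask <- function(shape, cy, cx, h) {
  ry <- matrix(seq_len(32), 32, 32) - cy
  rx <- matrix(seq_len(32), 32, 32, byrow = TRUE) - cx
  w0 <- max(1, h / 3)
  switch(shape,
    square = abs(ry) <= h & abs(rx) <= h,
    disc = ry^2 + rx^2 <= h^2,
    triangle = ry >= -h & ry <= h & abs(rx) <= (ry + h) / 2,
    plus = (abs(rx) <= w0 & abs(ry) <= h) | (abs(ry) <= w0 & abs(rx) <= h),
    ring = {
      d2 <- ry^2 + rx^2
      d2 <= h^2 & d2 >= (0.55 * h)^2
    },
    diamond = abs(rx) + abs(ry) <= h,
    cross = abs(abs(rx) - abs(ry)) <= w0 & pmax(abs(rx), abs(ry)) <= h,
    bars = abs(rx) <= h & (abs(ry) <= w0 | (abs(ry) >= 2 * w0 & abs(ry) <= h)),
    stop("unknown shape: ", shape))
}

.SHAPES <- c("square", "disc", "triangle", "plus", "ring", "diamond", "cross", "bars")
.PALETTE <- rbind(c(1.0, 0.25, 0.25), c(0.25, 1.0, 0.25), c(0.35, 0.45, 1.0),
                  c(1.0, 1.0, 0.3), c(1.0, 0.35, 1.0), c(0.3, 1.0, 1.0),
                  c(1.0, 0.65, 0.2), c(0.95, 0.95, 0.95))

#' Generate a labeled synthetic shape-image dataset
#'
#' Renders one geometric shape template per class (up to 8 classes) on a dark
#' noisy background. Each sample gets positional jitter of the shape center
#' (uniform integers in `-jitter..jitter` in both axes), size and brightness
#' jitter, and a fill color drawn per sample from two palette entries that
#' are each shared with a neighboring class (all per-sample variation is
#' disabled when `jitter = 0`, in which case the class color is fixed to its
#' first palette entry); finally additive Gaussian pixel noise is applied and
#' values are clipped to \[-1, 1\]. Because position carries no class
#' information and every color is ambiguous between two classes, the classes
#' are not linearly separable in pixel space at the default jitter, while a
#' convolutional encoder separates them well.
#'
#' @param num_classes number of classes (2..8).
#' @param n_per_class training images per class.
#' @param n_test_per_class held-out test images per class.
#' @param jitter maximal absolute shift of the shape center in pixels;
#'   `0` disables all per-sample appearance variation.
#' @param noise_sd standard deviation of additive pixel noise on the
#'   \[-1, 1\] scale.
#' @param seed integer seed; the dataset is bit-identical given the seed and
#'   the caller's RNG state is preserved.
#' @return list with `train` and `test`, each a `pad_dataset`: `images`
#'   (array 32 x 32 x 3 x n, values in \[-1, 1\]), `labels` (0-based
#'   integers), `split`.
#' @examples
#' ds <- generate_synthetic(num_classes = 3, n_per_class = 20,
#'                          n_test_per_class = 5, seed = 7)
#' dim(ds$train$images) # 32 32 3 60
#' @export
generate_synthetic <- function(num_classes = 4L, n_per_class = 500L,
                               n_test_per_class = 100L, jitter = 4L,
                               noise_sd = 0.1, seed = 1L) {
  num_classes <- as.integer(num_classes)
  n_per_class <- as.integer(n_per_class)
  n_test_per_class <- as.integer(n_test_per_class)
  if (num_classes < 2L || num_classes > length(.SHAPES))
    stop("num_classes must be between 2 and ", length(.SHAPES))
  if (n_per_class < 2L || n_test_per_class < 1L)
    stop("need at least 2 training and 1 test image per class")
  if (jitter < 0 || noise_sd < 0) stop("jitter and noise_sd must be >= 0")

  render_split <- function(n_each, split) {
    n <- n_each * num_classes
    labels <- rep(seq_len(num_classes) - 1L, each = n_each)
    images <- array(NA_real_, c(32L, 32L, 3L, n))
    for (i in seq_len(n)) {
      cl <- labels[i] + 1L
      if (jitter > 0) {
        cy <- 16.5 + sample.int(2L * jitter + 1L, 1L) - jitter - 1L
        cx <- 16.5 + sample.int(2L * jitter + 1L, 1L) - jitter - 1L
        h <- 7 * runif(1L, 0.8, 1.2)
        bright <- runif(1L, 0.7, 1.0)
        # class cl draws from palette entries cl and cl+1 (cyclic), so every
        # color is shared by two classes and identifies neither
        pick <- if (runif(1L) < 0.5) cl else cl %% num_classes + 1L
        col <- .PALETTE[pick, ]
      } else {
        cy <- 16.5; cx <- 16.5; h <- 7; bright <- 1.0
        col <- .PALETTE[cl, ]
      }
      m <- .shape_mask(.SHAPES[cl], cy, cx, h)
      img <- array(-0.8, c(32L, 32L, 3L))
      for (ch in 1:3)
        img[, , ch][m] <- 2 * (col[ch] * bright) - 1
      if (noise_sd > 0)
        img <- img + array(rnorm(length(img), sd = noise_sd), dim(img))
      images[, , , i] <- pmin(pmax(img, -1), 1)
    }
    .pad_dataset(images, labels, split)
  }
  .with_stream(.rng_stream(seed), {
    train <- render_split(n_per_class, "train")
    test <- render_split(n_test_per_class, "test")
    list(train = train, test = test)
  })
}

#' Read the CIFAR-10 binary batch format
#'
#' Expects the standard binary batches (`data_batch_1.bin` ..
#' `data_batch_5.bin` for the train split, `test_batch.bin` for the test
#' split) under `root` or `root/cifar-10-batches-bin`. Each 3073-byte record
#' is one label byte followed by 1024 red, green and blue row-major pixels.
#' Pixels are rescaled from 0..255 to \[-1, 1\]. Files are never downloaded by
#' the package.
#'
#' @param root directory containing the batch files.
#' @param split `"train"` or `"test"`.
#' @return a `pad_dataset`.
#' @export
load_cifar10 <- function(root, split = c("train", "test")) {
  split <- match.arg(split)
  base <- if (dir.exists(file.path(root, "cifar-10-batches-bin")))
    file.path(root, "cifar-10-batches-bin") else root
  files <- if (split == "train")
    file.path(base, paste0("data_batch_", 1:5, ".bin"))
  else file.path(base, "test_batch.bin")
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("CIFAR-10 file(s) not found: ", paste(missing, collapse = ", "),
         "\nExpected the binary batch files under ", base)

  read_batch <- function(f) {
    sz <- file.size(f)
    if (sz == 0 || sz %% 3073 != 0)
      stop("corrupt CIFAR-10 batch (size not a multiple of 3073 bytes): ", f)
    n <- sz %/% 3073
    raw <- readBin(f, "raw", sz)
    rec <- matrix(as.integer(raw), 3073L, n)
    labels <- rec[1L, ]
    if (any(labels > 9L)) stop("corrupt CIFAR-10 batch (label > 9): ", f)
    # record layout: fastest index is the column within a row
    px <- array(rec[-1L, ], c(32L, 32L, 3L, n))
    list(images = .unit_from_u8(aperm(px, c(2L, 1L, 3L, 4L))), labels = labels)
  }
  parts <- lapply(files, read_batch)
  images <- array(unlist(lapply(parts, `[[`, "images"), use.names = FALSE),
                  c(32L, 32L, 3L, sum(vapply(parts, function(p) length(p$labels),
                                             integer(1)))))
  .pad_dataset(images, unlist(lapply(parts, `[[`, "labels")), split)
}

#' Read the SVHN cropped-digits MAT format
#'
#' Expects `train_32x32.mat` / `test_32x32.mat` under `root` (MATLAB v5
#' files holding a 32 x 32 x 3 x n uint8 array `X` and labels `y`). The
#' format's label 10 denotes digit zero and is remapped to class 0; class
#' frequencies are preserved (no rebalancing). Pixels are rescaled to
#' \[-1, 1\].
#'
#' @inheritParams load_cifar10
#' @return a `pad_dataset`.
#' @export
load_svhn <- function(root, split = c("train", "test")) {
  split <- match.arg(split)
  f <- file.path(root, paste0(split, "_32x32.mat"))
  if (!file.exists(f))
    stop("SVHN file not found: ", f,
         "\nExpected the cropped-digits MAT file ", basename(f), " under ", root)
  vars <- .read_mat5(f)
  if (is.null(vars$X) || is.null(vars$y))
    stop("corrupt SVHN file (missing X or y): ", f)
  dx <- dim(vars$X)
  if (length(dx) != 4L || any(dx[1:3] != c(32L, 32L, 3L)))
    stop("unexpected SVHN image array shape: ", paste(dx, collapse = "x"))
  labels <- as.integer(vars$y)
  labels[labels == 10L] <- 0L
  if (length(labels) != dx[4]) stop("SVHN label/image count mismatch")
  .pad_dataset(.unit_from_u8(array(as.double(vars$X), dx)), labels, split)
}

#' Split a dataset into training mini-batches
#'
#' Optionally shuffles with a seed, then cuts the dataset into consecutive
#' batches of exactly `batch_size` samples; a final short batch is dropped so
#' that the batch statistics of the latent KL loss stay well-conditioned.
#'
#' @param dataset a `pad_dataset`.
#' @param batch_size samples per batch (>= 2, <= dataset size).
#' @param shuffle_seed integer seed for the shuffle, or `NULL` to keep the
#'   stored order.
#' @return list of batches, each a list with `x` (image array) and `y`
#'   (labels).
#' @export
batch_iterator <- function(dataset, batch_size = 64L, shuffle_seed = NULL) {
  images <- dataset$images
  d <- .check_image_batch(images, "dataset$images")
  n <- d[4]
  batch_size <- as.integer(batch_size)
  if (batch_size < 2L) stop("batch_size must be >= 2")
  if (batch_size > n) stop("batch_size exceeds dataset size")
  idx <- if (is.null(shuffle_seed)) seq_len(n)
         else .with_stream(.rng_stream(shuffle_seed), sample.int(n))
  n_batches <- n %/% batch_size
  lapply(seq_len(n_batches), function(bi) {
    take <- idx[((bi - 1L) * batch_size + 1L):(bi * batch_size)]
    list(x = images[, , , take, drop = FALSE], y = dataset$labels[take])
  })
}

#' Export a dataset as PNG files plus a CSV label manifest
#'
#' @param dataset a `pad_dataset`.
#' @param dir output directory (created if needed).
#' @param max_images cap on the number of exported images.
#' @return the manifest path, invisibly.
#' @export
export_dataset_png <- function(dataset, dir, max_images = Inf) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- min(dim(dataset$images)[4], max_images)
  manifest <- data.frame(file = sprintf("img_%05d.png", seq_len(n)),
                         label = dataset$labels[seq_len(n)])
  for (i in seq_len(n)) {
    img <- (dataset$images[, , , i] + 1) / 2
    grDevices::png(file.path(dir, manifest$file[i]), width = 32L, height = 32L)
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot.new()
    graphics::rasterImage(img, 0, 0, 1, 1, interpolate = FALSE)
    grDevices::dev.off()
  }
  path <- file.path(dir, "labels.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
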