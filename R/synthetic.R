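#' Synthetic class-structured image datasets
#'
#' Deterministic generator for small multi-class image sets that mimic
#' desk-scale medical classification benchmarks (2-7 classes, a few
#' hundred images per class, class-dependent structure plus pixel
#' noise). Three structure families are available:
#'
#' * `"blob-count"` — class k carries k bright Gaussian blobs on a dark
#'   background, placed on distinct cells of a jittered 3x3 grid so
#'   blobs never merge (a noiseless peak count recovers k exactly).
#' * `"texture-frequency"` — a sinusoidal grating whose spatial
#'   frequency grows with the class index.
#' * `"ring-lesion"` — a bright annulus whose radius grows with the
#'   class index, loosely emulating lesion-size classes.
#'
#' Images are single-channel in `[0, 1]` (replicated to 3 channels by
#' the loader) and are written to disk as plain-text PGM.
#'
#' @name synthetic_data
NULL

#' Specify a synthetic dataset
#'
#' @param n_classes number of classes, 2-7.
#' @param images_per_class images per class before imbalance weighting.
#' @param image_size square image side in pixels.
#' @param family structure family, see [synthetic_data].
#' @param noise_sd Gaussian pixel noise standard deviation, in `[0,1]`
#'   intensity units.
#' @param imbalance optional positive per-class weights; class k gets
#'   `round(images_per_class * w_k / max(w))` images, at least 1.
#' @param seed integer seed; generation is bit-reproducible given it.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(n_classes = 3L, images_per_class = 100L,
                       image_size = 256L,
                       family = c("blob-count", "texture-frequency", "ring-lesion"),
                       noise_sd = 0.05, imbalance = NULL, seed = 1L) {
  family <- match.arg(family)
  if (!(n_classes >= 2L && n_classes <= 7L)) stop("n_classes must be in 2..7")
  if (images_per_class < 1L) stop("images_per_class must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  counts <- rep(as.integer(images_per_class), n_classes)
  if (!is.null(imbalance)) {
    if (length(imbalance) != n_classes || any(imbalance <= 0)) {
      stop("imbalance must be positive, one weight per class")
    }
    counts <- pmax(1L, as.integer(round(images_per_class * imbalance / max(imbalance))))
  }
  structure(list(
    n_classes = as.integer(n_classes), images_per_class = as.integer(images_per_class),
    image_size = as.integer(image_size), family = family, noise_sd = noise_sd,
    counts = counts, seed = as.integer(seed)
  ), class = "synth_spec")
}

# one noiseless class image on [0,1]; rng state supplies placement jitter
synth_base_image <- function(spec, class_k) {
  s <- spec$image_size
  xy <- seq_len(s)
  img <- matrix(0.1, s, s)
  if (spec$family == "blob-count") {
    cells <- as.matrix(expand.grid(gi = 1:3, gj = 1:3))
    pick <- sample.int(9L, class_k)
    sigma <- s / 14
    for (q in pick) {
      ci <- (cells[q, 1L] - 0.5) * s / 3 + stats::runif(1, -s / 24, s / 24)
      cj <- (cells[q, 2L] - 0.5) * s / 3 + stats::runif(1, -s / 24, s / 24)
      img <- img + 0.8 * outer(exp(-(xy - ci)^2 / (2 * sigma^2)),
                               exp(-(xy - cj)^2 / (2 * sigma^2)))
    }
  } else if (spec$family == "texture-frequency") {
    freq <- 2 * class_k
    phase <- stats::runif(1, 0, 2 * pi)
    img <- 0.5 + 0.4 * outer(sin(2 * pi * freq * xy / s + phase),
                             rep(1, s))
  } else { # ring-lesion
    r0 <- s * (0.10 + 0.05 * class_k)
    wdt <- s / 16
    ci <- s / 2 + stats::runif(1, -s / 16, s / 16)
    cj <- s / 2 + stats::runif(1, -s / 16, s / 16)
    r <- sqrt(outer((xy - ci)^2, (xy - cj)^2, `+`))
    img <- 0.1 + 0.8 * exp(-(r - r0)^2 / (2 * wdt^2))
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic dataset
#'
#' Produces the images and a labels table. When `dir` is given the
#' images are written as plain-text PGM files (`class<k>_<i>.pgm`)
#' together with `labels.csv` (filename, class_id, class_name); the
#' same quantised `[0, 255]` intensities back the in-memory arrays, so
#' disk and memory routes agree bit-exactly.
#'
#' @param spec a [synth_spec()].
#' @param dir optional output directory (created if missing).
#' @return list with `labels` (data.frame) and `images` (list of
#'   `image_size^2` matrices in `[0, 1]`), invisibly when written.
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  images <- list()
  rows <- list()
  n <- 0L
  for (k in seq_len(spec$n_classes)) {
    for (i in seq_len(spec$counts[k])) {
      img <- synth_base_image(spec, k)
      if (spec$noise_sd > 0) {
        img <- img + matrix(stats::rnorm(length(img), sd = spec$noise_sd), nrow(img))
        img <- pmin(pmax(img, 0), 1)
      }
      img <- round(img * 255) / 255   # quantise like the on-disk 8-bit form
      n <- n + 1L
      images[[n]] <- img
      rows[[n]] <- data.frame(
        filename = sprintf("class%d_%04d.pgm", k, i),
        class_id = k, class_name = sprintf("class%d", k),
        stringsAsFactors = FALSE
      )
    }
  }
  labels <- do.call(rbind, rows)
  out <- list(labels = labels, images = images)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (j in seq_len(nrow(labels))) {
      write_pgm(images[[j]], file.path(dir, labels$filename[j]))
    }
    utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Stratified train/validation/test split
#'
#' Within each class, items are shuffled deterministically and assigned
#' `floor(p * n)` to train, `floor(q * n)` to validation and the
#' remainder to test, where `p`, `q` are the normalised first two
#' ratios (default 7:1:2). A class with fewer items than split groups
#' goes entirely to train, with a warning.
#'
#' @param labels data.frame with a `class_id` column (one row per item).
#' @param ratios positive length-3 ratios, default `c(7, 1, 2)`.
#' @param seed integer seed for the within-class shuffle.
#' @return the labels data.frame with a `split` factor column
#'   (`train`/`val`/`test`).
#' @export
split_dataset <- function(labels, ratios = c(7, 1, 2), seed = 1L) {
  if (length(ratios) != 3L || any(ratios <= 0)) stop("need 3 positive ratios")
  pr <- ratios / sum(ratios)
  set.seed(as.integer(seed))
  split <- character(nrow(labels))
  for (k in sort(unique(labels$class_id))) {
    idx <- which(labels$class_id == k)
    n <- length(idx)
    idx <- idx[sample.int(n)]
    n_tr <- floor(pr[1L] * n)
    n_va <- floor(pr[2L] * n)
    if (n < 3L) {
      warning(sprintf("class %s has %d item(s); assigning all to train", k, n))
      split[idx] <- "train"
      next
    }
    split[idx[seq_len(n_tr)]] <- "train"
    split[idx[n_tr + seq_len(n_va)]] <- "val"
    split[idx[(n_tr + n_va + 1L):n]] <- "test"
  }
  labels$split <- factor(split, levels = c("train", "val", "test"))
  labels
}

#' Load an image folder into a batched tensor
#'
#' Reads the `labels.csv` table and the referenced PGM images, resizes
#' each to `image_size` (bilinear), scales intensities to `[0, 1]` and
#' replicates grayscale to 3 channels. Ordering is the labels-table
#' order, which itself is deterministic (filenames).
#'
#' @param path dataset directory containing `labels.csv`.
#' @param image_size target square side.
#' @return list with `x` array `(N, image_size, image_size, 3)` and
#'   `labels` data.frame.
#' @export
load_image_folder <- function(path, image_size = 256L) {
  lab_file <- file.path(path, "labels.csv")
  if (!file.exists(lab_file)) stop("missing labels table: ", lab_file)
  labels <- utils::read.csv(lab_file, stringsAsFactors = FALSE)
  labels <- labels[order(labels$filename), , drop = FALSE]
  rownames(labels) <- NULL
  n <- nrow(labels)
  x <- array(0, c(n, image_size, image_size, 3L))
  for (i in seq_len(n)) {
    f <- file.path(path, labels$filename[i])
    if (!file.exists(f)) stop("missing image file: ", f)
    img <- read_pgm(f)
    img <- resize_bilinear(img, image_size, image_size)
    x[i, , , ] <- array(img, c(dim(img), 3L))
  }
  list(x = x, labels = labels)
}

#' Materialise an in-memory synthetic dataset as model tensors
#'
#' Convenience route used by the training CLI when no folder is given:
#' generates, splits and packs the dataset without touching disk.
#'
#' @param spec a [synth_spec()].
#' @param ratios split ratios.
#' @param split_seed seed for the splitter (defaults to `spec$seed`).
#' @return list of `x`, `y`, `labels` per split (`train`, `val`, `test`).
#' @export
synth_tensors <- function(spec, ratios = c(7, 1, 2), split_seed = spec$seed) {
  ds <- generate_dataset(spec)
  labels <- split_dataset(ds$labels, ratios, seed = split_seed)
  s <- spec$image_size
  pack <- function(which) {
    idx <- which(labels$split == which)
    x <- array(0, c(length(idx), s, s, 3L))
    for (j in seq_along(idx)) {
      x[j, , , ] <- array(ds$images[[idx[j]]], c(s, s, 3L))
    }
    list(x = x, y = labels$class_id[idx], labels = labels[idx, , drop = FALSE])
  }
  list(train = pack("train"), val = pack("val"), test = pack("test"),
       labels = labels)
}
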