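test_that("generate_dataset honours count contracts and determinism", {
  spec <- synth_spec(n_classes = 3L, images_per_class = 10L, image_size = 32L,
                     noise_sd = 0.05, seed = 5L)
  d1 <- generate_dataset(spec)
  expect_equal(nrow(d1$labels), 30L)
  expect_length(d1$images, 30L)
  expect_equal(as.vector(table(d1$labels$class_id)), rep(10L, 3))

  d2 <- generate_dataset(spec)
  expect_identical(d1$images, d2$images)
  expect_identical(d1$labels, d2$labels)

  # on-disk route is byte-identical across runs with the same seed
  t1 <- file.path(tempdir(), "synthA"); t2 <- file.path(tempdir(), "synthB")
  generate_dataset(spec, dir = t1)
  generate_dataset(spec, dir = t2)
  f1 <- list.files(t1, full.names = TRUE)
  f2 <- list.files(t2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(t1, t2), recursive = TRUE)
})

test_that("noiseless blob images contain exactly k separated peaks", {
  spec <- synth_spec(n_classes = 3L, images_per_class = 4L, image_size = 48L,
                     family = "blob-count", noise_sd = 0, seed = 9L)
  ds <- generate_dataset(spec)
  count_blobs <- function(img, thr = 0.5) {
    # connected components (4-neighbour flood fill) of the bright set;
    # blobs sit on distinct grid cells, so components == blob count
    mask <- img > thr
    lab <- matrix(0L, nrow(img), ncol(img))
    n <- 0L
    for (i0 in seq_len(nrow(img))) for (j0 in seq_len(ncol(img))) {
      if (!mask[i0, j0] || lab[i0, j0] > 0L) next
      n <- n + 1L
      queue <- list(c(i0, j0)); lab[i0, j0] <- n
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(img) && q[2] >= 1 && q[2] <= ncol(img) &&
              mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- n
            queue[[length(queue) + 1]] <- q
          }
        }
      }
    }
    n
  }
  for (r in seq_len(nrow(ds$labels))) {
    expect_equal(count_blobs(ds$images[[r]]), ds$labels$class_id[r])
  }
})

test_that("imbalance weights shape per-class counts", {
  spec <- synth_spec(n_classes = 3L, images_per_class = 12L, image_size = 16L,
                     imbalance = c(1, 0.5, 0.25), seed = 2L)
  expect_equal(spec$counts, c(12L, 6L, 3L))
  expect_error(synth_spec(n_classes = 2L, imbalance = c(1, -1)), "positive")
})

test_that("split_dataset follows the floor-then-remainder 7:1:2 rule", {
  lab <- data.frame(class_id = rep(1L, 100L))
  sp <- split_dataset(lab, seed = 3L)
  expect_equal(as.vector(table(sp$split)), c(70L, 10L, 20L))

  # one class of 662 items: 463 / 66 / 133 under the stated rule
  lab2 <- data.frame(class_id = rep(1L, 662L))
  sp2 <- split_dataset(lab2, seed = 3L)
  expect_equal(as.vector(table(sp2$split)), c(463L, 66L, 133L))

  # stratification: per-class deviation from 7:1:2 below one item
  lab3 <- data.frame(class_id = rep(1:3, times = c(143L, 143L, 143L)))
  sp3 <- split_dataset(lab3, seed = 4L)
  tab <- table(sp3$class_id, sp3$split)
  for (k in 1:3) {
    expect_lt(abs(tab[k, "train"] - 0.7 * 143), 1)
    expect_lt(abs(tab[k, "val"] - 0.1 * 143), 1)
  }
  # partition: union = original set, no overlaps
  expect_equal(sum(tab), 429L)
  expect_identical(split_dataset(lab3, seed = 4L)$split, sp3$split)
  expect_false(identical(split_dataset(lab3, seed = 5L)$split, sp3$split))

  expect_warning(split_dataset(data.frame(class_id = c(1L, 1L, 2L, 2L, 2L))),
                 "all to train")
  expect_error(split_dataset(lab, ratios = c(1, 2)), "positive ratios")
})

test_that("load_image_folder round-trips, scales and orders deterministically", {
  spec <- synth_spec(n_classes = 2L, images_per_class = 3L, image_size = 24L,
                     seed = 6L)
  dir <- file.path(tempdir(), "synthload")
  ds <- generate_dataset(spec, dir = dir)
  got <- load_image_folder(dir, image_size = 24L)
  expect_identical(dim(got$x), c(6L, 24L, 24L, 3L))
  expect_true(all(got$x >= 0 & got$x <= 1))
  # identity resize: pixels unchanged, and the three channels replicate
  o <- order(ds$labels$filename)
  for (i in 1:6) {
    expect_equal(got$x[i, , , 1], ds$images[[o[i]]], tolerance = 1e-12)
    expect_equal(got$x[i, , , 1], got$x[i, , , 3])
  }
  expect_error(load_image_folder(file.path(tempdir(), "nope")), "labels table")
  unlink(dir, recursive = TRUE)
})

test_that("noiseless blob classes are separable by mean intensity alone", {
  spec <- synth_spec(n_classes = 3L, images_per_class = 8L, image_size = 32L,
                     family = "blob-count", noise_sd = 0, seed = 12L)
  ds <- generate_dataset(spec)
  means <- sapply(ds$images, mean)
  centroids <- tapply(means, ds$labels$class_id, mean)
  pred <- apply(abs(outer(means, centroids, `-`)), 1, which.min)
  expect_equal(unname(pred), ds$labels$class_id)
})
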