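test_that("configuration invariants are enforced", {
  expect_error(tsd_config(image_size = 50L), "divisible by 8")
  expect_error(tsd_config(image_size = 16L, widths = c(2L, 3L, 4L), d_fuse = 3L,
                          n_classes = 4L), "d_fuse")
  expect_error(tsd_config(thresholds = list(T1 = 0.3, T2 = 0.5, T3 = 0.5)),
               "configuration error")
  expect_error(tsd_config(knockout = c("f_cg", "f1", "f2", "f3")), "invalid-plan")
})

test_that("build_model is deterministic in its seed", {
  cfg <- tiny_cfg()
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$attn, m2$attn)
  expect_equal(count_params(m1), count_params(m2))
  m3 <- build_model(tiny_cfg(seed = 8L))
  expect_false(identical(m1$params$conv1$W, m3$params$conv1$W))
})

test_that("forward pass meets the probability and determinism contracts", {
  m <- build_model(tiny_cfg())
  x0 <- array(0, c(16, 16, 3))
  fw <- forward_sample(m, x0)
  expect_length(fw$probs, 3L)
  expect_equal(sum(fw$probs), 1, tolerance = 1e-6)
  expect_true(all(fw$probs >= 0 & fw$probs <= 1))

  set.seed(10)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(forward_sample(m, x)$probs, forward_sample(m, x)$probs)
})

test_that("cross-entropy gradients are finite and match finite differences", {
  m <- build_model(tiny_cfg())
  set.seed(11)
  m$params$dense_out$W[] <- rnorm(length(m$params$dense_out$W), sd = 0.05)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  fw <- forward_sample(m, x, keep_cache = TRUE)
  bw <- backward_sample(m, fw$cache, 2L)
  all_finite <- TRUE
  tsdnet:::param_map(bw$grads, function(g) { all_finite <<- all_finite && all(is.finite(g)); g })
  expect_true(all_finite)

  loss_at <- function(mm) -log(forward_sample(mm, x)$probs[2])
  eps <- 1e-6
  set.seed(12)
  layers <- sample(names(m$params), 5)
  for (nm in layers) {
    i <- sample(length(m$params[[nm]]$W), 1)
    m2 <- m; m2$params[[nm]]$W[i] <- m2$params[[nm]]$W[i] + eps
    m3 <- m; m3$params[[nm]]$W[i] <- m3$params[[nm]]$W[i] - eps
    num <- (loss_at(m2) - loss_at(m3)) / (2 * eps)
    expect_equal(bw$grads[[nm]]$W[i], num, tolerance = 1e-4)
  }
})

test_that("hard gating drops eliminated positions from forward and gradient", {
  m <- build_model(tiny_cfg())
  set.seed(13)
  x <- array(runif(16 * 16, 0.2, 1), c(16, 16, 1))
  x <- array(x, c(16, 16, 3))
  fw <- forward_sample(m, x, keep_cache = TRUE)
  cc <- fw$cache
  # forward: a zero mask position contributes exactly zero to the level map
  g <- cc$cf$masks$HV
  C <- dim(cc$f_x)[3]
  zero_pos <- which(g$m_imp == 0, arr.ind = TRUE)
  if (nrow(zero_pos) > 0) {
    i <- zero_pos[1, 1]; j <- zero_pos[1, 2]
    expect_true(all(cc$f1[i, j, seq_len(C)] == 0))
  }
  # gradient: the f_3 projection receives no gradient from gated-out inputs
  bw <- backward_sample(m, fw$cache, 1L)
  expect_true(all(is.finite(bw$grads$dense_f3$W)))
})

test_that("feature knockouts zero the pathway exactly", {
  base <- tiny_cfg()
  set.seed(14)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  for (ko in c("f_cg", "f1", "f2", "f3")) {
    cfg <- tiny_cfg(knockout = ko)
    m <- build_model(cfg)
    fw <- forward_sample(m, x, keep_cache = TRUE)
    field <- c(f_cg = "f_cg", f1 = "f1", f2 = "f2", f3 = "f3")[[ko]]
    expect_true(all(fw$cache[[field]] == 0))
    if (ko == "f2") expect_true(all(fw$cache$f_cg_deep == 0))
  }
})

test_that("per-sample predictions are batch-order invariant", {
  m <- build_model(tiny_cfg())
  set.seed(15)
  x <- array(runif(4 * 16 * 16 * 3), c(4, 16, 16, 3))
  p <- predict_probs(m, x)
  perm <- c(3, 1, 4, 2)
  xp <- x[perm, , , , drop = FALSE]
  expect_equal(predict_probs(m, xp), p[perm, ], tolerance = 1e-12)
})

test_that("one Adam step on a tiny batch decreases the batch loss", {
  m <- build_model(tiny_cfg())
  set.seed(16)
  x <- array(runif(6 * 16 * 16 * 3), c(6, 16, 16, 3))
  y <- rep(1:3, 2)
  batch_loss <- function(mm) {
    -mean(sapply(1:6, function(i) log(forward_sample(mm, bslice(x, i))$probs[y[i]])))
  }
  l0 <- batch_loss(m)
  fit <- train_model(m, list(x = x, y = y), epochs = 3L, batch_size = 6L, lr = 1e-2)
  expect_lt(batch_loss(fit$model), l0)
})
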