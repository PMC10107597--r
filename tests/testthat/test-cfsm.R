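test_that("pair_weights is the elementwise mean of its two directions", {
  ones <- array(1, c(2, 2, 2))
  w <- list(a_H = ones, a_V = ones, a_D = ones)
  p <- pair_weights(w)
  for (nm in names(p)) expect_equal(p[[nm]], ones)

  w$a_V <- ones * 0
  expect_equal(pair_weights(w)$a_HV, ones * 0.5)

  set.seed(31)
  for (rep in 1:100) {
    d <- c(sample(2:6, 1), sample(2:6, 1), sample(2:4, 1))
    w <- random_weights(d)
    p <- pair_weights(w)
    # elementwise loop oracle
    for (q in sample(prod(d), 5)) {
      expect_identical(p$a_HV[q], (w$a_H[q] + w$a_V[q]) / 2)
      expect_identical(p$a_HD[q], (w$a_H[q] + w$a_D[q]) / 2)
      expect_identical(p$a_VD[q], (w$a_V[q] + w$a_D[q]) / 2)
    }
    expect_true(all(p$a_HV >= 0 & p$a_HV <= 1))
  }

  w <- random_weights(c(2, 2, 2)); w$a_D <- array(0, c(2, 3, 2))
  expect_error(pair_weights(w), "shape mismatch")
})

test_that("cross_mean follows the printed crosswise pairing", {
  mk <- function(v) array(v, c(2, 2, 1))
  p <- list(a_HV = mk(0.4), a_HD = mk(0.4), a_VD = mk(0.4))
  for (b in c("HV", "HD", "VD")) expect_equal(cross_mean(p, b), mk(0.4))

  p2 <- list(a_HV = mk(0.6), a_HD = mk(0.2), a_VD = mk(0.9))
  expect_equal(cross_mean(p2, "HV"), mk(0.4))
  expect_equal(cross_mean(p2, "HD"), mk(0.55))
  expect_equal(cross_mean(p2, "VD"), mk(0.75))
  expect_equal(cross_mean(p2, "HV", rule = "self"), mk(0.6))
  expect_error(cross_mean(p2, "XX"), "unknown branch")

  set.seed(4)
  p3 <- list(a_HV = array(runif(12), c(2, 2, 3)),
             a_HD = array(runif(12), c(2, 2, 3)),
             a_VD = array(runif(12), c(2, 2, 3)))
  cm <- cross_mean(p3, "HD")
  for (q in seq_len(12)) expect_identical(cm[q], (p3$a_HD[q] + p3$a_VD[q]) / 2)
})

test_that("dual_gate_masks reproduces the worked example and tie rule", {
  m <- matrix(c(0.6, 0.4, 0.2, 0.5), 2, 2, byrow = TRUE)  # [[0.6,0.4],[0.2,0.5]]
  g <- dual_gate_masks(m, 0.5, 0.3)
  expect_equal(g$m_imp, matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
  expect_equal(g$m_sec, matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(g$m_red, matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE))

  expect_equal(dual_gate_masks(matrix(1, 2, 2), 0.5, 0.3)$m_imp, matrix(1, 2, 2))
  # closed-upper ties: mean == T1 -> important, mean == T2 -> secondary
  g2 <- dual_gate_masks(c(0.5, 0.3), 0.5, 0.3)
  expect_equal(g2$m_imp, c(1, 0))
  expect_equal(g2$m_sec, c(0, 1))
  expect_error(dual_gate_masks(m, 0.3, 0.5), "configuration error")
})

test_that("masks always partition: m_imp + m_sec + m_red == 1", {
  set.seed(77)
  for (rep in 1:100) {
    x <- array(runif(60, -0.2, 1.2), c(5, 4, 3))
    t2 <- runif(1, 0.05, 0.5); t1 <- runif(1, t2 + 0.05, 0.95)
    g <- dual_gate_masks(x, t1, t2)
    expect_true(all(g$m_imp + g$m_sec + g$m_red == 1))
    expect_true(all(g$m_imp %in% c(0, 1)))
  }
})

test_that("apply_masks gates elementwise and reconstructs the input", {
  set.seed(12)
  f <- array(rnorm(36), c(3, 4, 3))
  ones <- array(1, dim(f))
  expect_equal(apply_masks(f, list(m = ones))$m, f)
  expect_equal(apply_masks(f, list(m = ones * 0))$m, f * 0)

  for (rep in 1:20) {
    mean_map <- array(runif(36), dim(f))
    g <- dual_gate_masks(mean_map, 0.6, 0.3)
    parts <- apply_masks(f, g)
    # loop-oracle agreement and exact reconstruction
    for (q in sample(36, 6)) {
      expect_identical(parts$m_imp[q], f[q] * g$m_imp[q])
    }
    expect_equal(parts$m_imp + parts$m_sec + parts$m_red, f)
  }

  # spatial masks broadcast across channels
  gs <- dual_gate_masks(matrix(runif(12), 3, 4), 0.6, 0.3)
  parts <- apply_masks(f, gs)
  expect_equal(parts$m_imp[, , 2], f[, , 2] * gs$m_imp)
  expect_error(apply_masks(f, list(m = matrix(1, 2, 2))), "mask shape")
})

test_that("assemble_levels concatenates in branch order HV, HD, VD", {
  set.seed(3)
  mk <- function() array(rnorm(48), c(4, 4, 3))
  br <- list(HV = list(mk(), mk(), mk()), HD = list(mk(), mk(), mk()),
             VD = list(mk(), mk(), mk()))
  lv <- assemble_levels(br)
  expect_identical(dim(lv$f1), c(4L, 4L, 9L))
  expect_equal(lv$f1[, , 1:3], br$HV[[1]])
  expect_equal(lv$f2[, , 4:6], br$HD[[2]])
  expect_equal(lv$f3[, , 7:9], br$VD[[3]])
  expect_equal(sum(lv$f1), sum(br$HV[[1]]) + sum(br$HD[[1]]) + sum(br$VD[[1]]))

  br$HD[[1]] <- array(0, c(3, 4, 3))
  expect_error(assemble_levels(br), "inconsistent spatial shapes")
})

test_that("important counts fall in T1; redundant counts rise in T2", {
  set.seed(50)
  x <- array(runif(80), c(4, 5, 4))
  imp <- sapply(seq(0.05, 0.95, length.out = 11), function(t1) {
    sum(dual_gate_masks(x, t1, t1 / 2)$m_imp)
  })
  expect_true(all(diff(imp) <= 0))
  red <- sapply(seq(0.05, 0.95, length.out = 11), function(t2) {
    sum(dual_gate_masks(x, 0.99, t2)$m_red)
  })
  expect_true(all(diff(red) >= 0))
})

test_that("vectorised CFSM chain matches the per-element loop oracle", {
  set.seed(99)
  for (rep in 1:100) {
    d <- c(sample(2:6, 1), sample(2:6, 1), sample(2:4, 1))
    f <- array(rnorm(prod(d)), d)
    w <- random_weights(d)
    t2 <- runif(1, 0.1, 0.4); t1 <- runif(1, t2 + 0.1, 0.9)
    thr <- threshold_config(t1, t2, 0.5)

    got <- cfsm_chain(f, w, thr, per_pixel = FALSE)
    want <- oracle_cfsm_elementwise(f, w, t1, t2)
    expect_identical(got$f1, want$f1)
    expect_identical(got$f2, want$f2)
    expect_identical(got$f3, want$f3)

    gotp <- cfsm_chain(f, w, thr, per_pixel = TRUE)
    wantp <- oracle_cfsm_perpixel(f, w, t1, t2)
    expect_equal(gotp$f1, wantp$f1, tolerance = 1e-12)
    expect_equal(gotp$f2, wantp$f2, tolerance = 1e-12)
    expect_equal(gotp$f3, wantp$f3, tolerance = 1e-12)

    # reconstruction: the three levels sum back to the tripled input
    f3x <- cat_channels_oracle(f)
    expect_equal(got$f1 + got$f2 + got$f3, f3x)
  }
})
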