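# Independent loop-based oracles. These deliberately avoid the package's
# vectorised code paths: plain nested loops and scalar arithmetic only.

# softmax along one axis of a 3-D array, elementwise exp/sum loops
oracle_softmax_axis <- function(e, axis) {
  d <- dim(e)
  out <- array(NA_real_, d)
  if (axis == 2L) {
    for (i in seq_len(d[1])) for (c in seq_len(d[3])) {
      v <- exp(e[i, , c]); out[i, , c] <- v / sum(v)
    }
  } else if (axis == 1L) {
    for (j in seq_len(d[2])) for (c in seq_len(d[3])) {
      v <- exp(e[, j, c]); out[, j, c] <- v / sum(v)
    }
  } else {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      v <- exp(e[i, j, ]); out[i, j, ] <- v / sum(v)
    }
  }
  out
}

# per-element CFSM chain: pair -> cross mean -> gate -> apply, all scalar
oracle_cfsm_elementwise <- function(f, w, T1, T2) {
  d <- dim(f)
  f1 <- array(0, c(d[1], d[2], 3 * d[3]))
  f2 <- f1; f3 <- f1
  branches <- list(HV = c("a_H", "a_V"), HD = c("a_H", "a_D"), VD = c("a_V", "a_D"))
  pairval <- function(b, i, j, c) (w[[branches[[b]][1]]][i, j, c] + w[[branches[[b]][2]]][i, j, c]) / 2
  crossval <- function(b, i, j, c) {
    switch(b,
      HV = (pairval("HV", i, j, c) + pairval("HD", i, j, c)) / 2,
      HD = (pairval("HD", i, j, c) + pairval("VD", i, j, c)) / 2,
      VD = (pairval("VD", i, j, c) + pairval("HV", i, j, c)) / 2)
  }
  for (bi in seq_along(branches)) {
    b <- names(branches)[bi]
    off <- (bi - 1) * d[3]
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (c in seq_len(d[3])) {
      m <- crossval(b, i, j, c)
      v <- f[i, j, c]
      if (m >= T1) f1[i, j, off + c] <- v
      else if (m >= T2) f2[i, j, off + c] <- v
      else f3[i, j, off + c] <- v
    }
  }
  list(f1 = f1, f2 = f2, f3 = f3)
}

# per-pixel variant: channel-mean of the cross mean decides the gate
oracle_cfsm_perpixel <- function(f, w, T1, T2) {
  d <- dim(f)
  f1 <- array(0, c(d[1], d[2], 3 * d[3]))
  f2 <- f1; f3 <- f1
  branches <- list(HV = c("a_H", "a_V"), HD = c("a_H", "a_D"), VD = c("a_V", "a_D"))
  pairval <- function(b, i, j, c) (w[[branches[[b]][1]]][i, j, c] + w[[branches[[b]][2]]][i, j, c]) / 2
  crossval <- function(b, i, j, c) {
    switch(b,
      HV = (pairval("HV", i, j, c) + pairval("HD", i, j, c)) / 2,
      HD = (pairval("HD", i, j, c) + pairval("VD", i, j, c)) / 2,
      VD = (pairval("VD", i, j, c) + pairval("HV", i, j, c)) / 2)
  }
  for (bi in seq_along(branches)) {
    b <- names(branches)[bi]
    off <- (bi - 1) * d[3]
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      s <- 0
      for (c in seq_len(d[3])) s <- s + crossval(b, i, j, c)
      m <- s / d[3]
      for (c in seq_len(d[3])) {
        v <- f[i, j, c]
        if (m >= T1) f1[i, j, off + c] <- v
        else if (m >= T2) f2[i, j, off + c] <- v
        else f3[i, j, off + c] <- v
      }
    }
  }
  list(f1 = f1, f2 = f2, f3 = f3)
}

# per-element SGDM chain
oracle_sgdm_elementwise <- function(w, f_shallow, f_deep, T1, T3) {
  d <- dim(f_shallow)
  f_cg <- array(0, d)
  f_cg_deep <- array(0, dim(f_deep))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (c in seq_len(d[3])) {
    s <- sqrt(w$a_H[i, j, c]^2 + w$a_V[i, j, c]^2 + w$a_D[i, j, c]^2)
    if (s >= T1) f_cg[i, j, c] <- f_shallow[i, j, c]
  }
  dd <- dim(f_deep)
  for (i in seq_len(dd[1])) for (j in seq_len(dd[2])) for (c in seq_len(dd[3])) {
    s <- sqrt(w$a_H[i, j, c]^2 + w$a_V[i, j, c]^2 + w$a_D[i, j, c]^2)
    if (s >= T3) f_cg_deep[i, j, c] <- f_deep[i, j, c]
  }
  list(f_cg = f_cg, f_cg_deep = f_cg_deep)
}

# loop-based metrics
oracle_metrics <- function(cm) {
  s <- nrow(cm)
  tot <- 0; diag_sum <- 0; recalls <- numeric(s)
  nm <- 0; rowcol <- 0
  rows <- numeric(s); cols <- numeric(s)
  for (i in seq_len(s)) for (j in seq_len(s)) {
    tot <- tot + cm[i, j]
    rows[i] <- rows[i] + cm[i, j]
    cols[j] <- cols[j] + cm[i, j]
    if (i == j) diag_sum <- diag_sum + cm[i, j]
  }
  for (i in seq_len(s)) {
    recalls[i] <- cm[i, i] / rows[i]
    nm <- nm + cm[i, i] * rows[i]
    rowcol <- rowcol + rows[i] * cols[i]
  }
  oa <- diag_sum / tot
  pe_printed <- nm / (s * s)
  pe_std <- rowcol / tot^2
  list(OA = oa, AA = sum(recalls) / s,
       kappa_printed = (oa - pe_printed) / (1 - pe_printed),
       kappa_standard = (oa - pe_std) / (1 - pe_std))
}

# naive 2-D convolution (cross-correlation), stride/pad as in the package
oracle_conv2d <- function(x, W, b, kh, kw, stride, pad) {
  d <- dim(x)
  Hp <- d[1] + 2 * pad; Wp <- d[2] + 2 * pad
  xp <- array(0, c(Hp, Wp, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  Ho <- (Hp - kh) %/% stride + 1
  Wo <- (Wp - kw) %/% stride + 1
  Cout <- ncol(W)
  out <- array(0, c(Ho, Wo, Cout))
  for (o in seq_len(Cout)) for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    acc <- b[o]
    p <- 0
    for (c in seq_len(d[3])) for (dj in seq_len(kw)) for (di in seq_len(kh)) {
      p <- p + 1
      # weight row order must match the package: di fastest, then dj, then c
      wrow <- (c - 1) * kh * kw + (dj - 1) * kh + di
      acc <- acc + xp[(i - 1) * stride + di, (j - 1) * stride + dj, c] * W[wrow, o]
    }
    out[i, j, o] <- acc
  }
  out
}

# reference bilinear resize with the same pixel-centre convention
oracle_bilinear <- function(img, out_h, out_w) {
  in_h <- nrow(img); in_w <- ncol(img)
  out <- matrix(0, out_h, out_w)
  for (i in seq_len(out_h)) for (j in seq_len(out_w)) {
    si <- min(max((i - 0.5) * in_h / out_h + 0.5, 1), in_h)
    sj <- min(max((j - 0.5) * in_w / out_w + 0.5, 1), in_w)
    i0 <- min(floor(si), in_h - 1); if (in_h == 1) i0 <- 1
    j0 <- min(floor(sj), in_w - 1); if (in_w == 1) j0 <- 1
    fi <- si - i0; fj <- sj - j0
    i1 <- min(i0 + 1, in_h); j1 <- min(j0 + 1, in_w)
    out[i, j] <- img[i0, j0] * (1 - fi) * (1 - fj) + img[i1, j0] * fi * (1 - fj) +
      img[i0, j1] * (1 - fi) * fj + img[i1, j1] * fi * fj
  }
  out
}

# random directional-weight triple in [0, 1] with max 1 per map
random_weights <- function(dims) {
  r <- function() {
    a <- array(stats::runif(prod(dims)), dims)
    a / max(a)
  }
  list(a_H = r(), a_V = r(), a_D = r())
}

# f replicated three times along the channel axis (loop form)
cat_channels_oracle <- function(f) {
  d <- dim(f)
  out <- array(0, c(d[1], d[2], 3 * d[3]))
  for (b in 0:2) for (c in seq_len(d[3])) {
    out[, , b * d[3] + c] <- f[, , c]
  }
  out
}

bslice <- function(x, i) {
  d <- dim(x)
  y <- x[i, , , , drop = FALSE]
  dim(y) <- d[-1]
  y
}

tiny_cfg <- function(seed = 7L, ...) {
  tsd_config(image_size = 16L, widths = c(2L, 3L, 4L), d_fuse = 8L,
             n_classes = 3L, fy_filters = 4L, f1_filters = 4L, seed = seed, ...)
}
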