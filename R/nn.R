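# Minimal neural-network layer kit: im2col-based 2-D and 1-D
# convolutions, dense layers, ReLU, softmax cross-entropy and Adam, all
# with hand-written backward passes. Kept deliberately small — the model
# graph is fixed, so no general autodiff is needed. Convolution index
# plans are cached per shape so the inner loop is two BLAS matmuls.

.plan_cache <- new.env(parent = emptyenv())

conv2d_plan <- function(H, W, Cin, kh, kw, stride, pad) {
  key <- paste("c2", H, W, Cin, kh, kw, stride, pad, sep = "_")
  hit <- .plan_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - kh) %/% stride + 1L
  Wo <- (Wp - kw) %/% stride + 1L
  oi <- rep(seq_len(Ho), times = Wo)         # column-major over (Ho, Wo)
  oj <- rep(seq_len(Wo), each = Ho)
  base_i <- (oi - 1L) * stride
  base_j <- (oj - 1L) * stride
  di <- rep(seq_len(kh), times = kw * Cin)   # patch offsets: di fastest, then dj, then c
  dj <- rep(rep(seq_len(kw), each = kh), times = Cin)
  dc <- rep(seq_len(Cin), each = kh * kw)
  idx <- outer(base_i, di, `+`) +
    (outer(base_j, dj, `+`) - 1L) * Hp +
    matrix((dc - 1L) * Hp * Wp, nrow = Ho * Wo, ncol = kh * kw * Cin, byrow = TRUE)
  plan <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp,
               H = H, W = W, Cin = Cin, pad = pad)
  .plan_cache[[key]] <- plan
  plan
}

pad_hw <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1L] + 2L * pad, d[2L] + 2L * pad, d[3L]))
  xp[pad + seq_len(d[1L]), pad + seq_len(d[2L]), ] <- x
  xp
}

# W: (kh*kw*Cin) x Cout weight matrix; b: length-Cout bias
conv2d_forward <- function(x, W, b, kh = 3L, kw = 3L, stride = 1L, pad = 1L) {
  d <- dim(x)
  pl <- conv2d_plan(d[1L], d[2L], d[3L], kh, kw, stride, pad)
  xp <- pad_hw(x, pad)
  col <- xp[pl$idx]
  dim(col) <- dim(pl$idx)
  out <- col %*% W
  out <- sweep(out, 2L, b, `+`)
  Cout <- ncol(W)
  list(out = array(out, c(pl$Ho, pl$Wo, Cout)),
       cache = list(col = col, plan = pl, W = W))
}

conv2d_backward <- function(dout, cache) {
  pl <- cache$plan
  Cout <- dim(dout)[3L]
  dmat <- matrix(dout, nrow = pl$Ho * pl$Wo, ncol = Cout)
  dW <- crossprod(cache$col, dmat)
  db <- colSums(dmat)
  dcol <- dmat %*% t(cache$W)
  acc <- rowsum(as.vector(dcol), group = as.vector(pl$idx))
  dxp <- numeric(pl$Hp * pl$Wp * pl$Cin)
  dxp[as.integer(rownames(acc))] <- acc[, 1L]
  dxp <- array(dxp, c(pl$Hp, pl$Wp, pl$Cin))
  p <- pl$pad
  dx <- if (p > 0L) dxp[p + seq_len(pl$H), p + seq_len(pl$W), , drop = FALSE] else dxp
  dim(dx) <- c(pl$H, pl$W, pl$Cin)
  list(dx = dx, dW = dW, db = db)
}

conv1d_plan <- function(L, Cin, k, pad) {
  key <- paste("c1", L, Cin, k, pad, sep = "_")
  hit <- .plan_cache[[key]]
  if (!is.null(hit)) return(hit)
  Lp <- L + 2L * pad
  Lo <- Lp - k + 1L
  di <- rep(seq_len(k), times = Cin)
  dc <- rep(seq_len(Cin), each = k)
  idx <- outer(0L:(Lo - 1L), di, `+`) +
    matrix((dc - 1L) * Lp, nrow = Lo, ncol = k * Cin, byrow = TRUE)
  plan <- list(idx = idx, Lo = Lo, Lp = Lp, L = L, Cin = Cin, pad = pad)
  .plan_cache[[key]] <- plan
  plan
}

# x: (L, Cin) sequence; W: (k*Cin) x Cout; same padding when pad = (k-1)/2
conv1d_forward <- function(x, W, b, k = 3L, pad = 1L) {
  d <- dim(x)
  pl <- conv1d_plan(d[1L], d[2L], k, pad)
  xp <- matrix(0, pl$Lp, d[2L])
  xp[pad + seq_len(d[1L]), ] <- x
  col <- xp[pl$idx]
  dim(col) <- dim(pl$idx)
  out <- sweep(col %*% W, 2L, b, `+`)
  list(out = out, cache = list(col = col, plan = pl, W = W))
}

conv1d_backward <- function(dout, cache) {
  pl <- cache$plan
  dW <- crossprod(cache$col, dout)
  db <- colSums(dout)
  dcol <- dout %*% t(cache$W)
  acc <- rowsum(as.vector(dcol), group = as.vector(pl$idx))
  dxp <- numeric(pl$Lp * pl$Cin)
  dxp[as.integer(rownames(acc))] <- acc[, 1L]
  dxp <- matrix(dxp, pl$Lp, pl$Cin)
  p <- pl$pad
  dx <- if (p > 0L) dxp[p + seq_len(pl$L), , drop = FALSE] else dxp
  list(dx = dx, dW = dW, db = db)
}

dense_forward <- function(x, W, b) {
  list(out = as.vector(x %*% W) + b, cache = list(x = x, W = W))
}

dense_backward <- function(dout, cache) {
  list(dx = as.vector(cache$W %*% dout),
       dW = outer(cache$x, dout),
       db = dout)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_backward <- function(dout, x) {
  dout * (x > 0)
}

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# loss and gradient of mean cross-entropy for one sample
softmax_ce <- function(logits, y) {
  p <- softmax_vec(logits)
  dl <- p
  dl[y] <- dl[y] - 1
  list(loss = -log(max(p[y], 1e-12)), probs = p, dlogits = dl)
}

# ---- parameter-tree utilities ------------------------------------------

param_map <- function(p, f) {
  if (is.list(p)) return(lapply(p, param_map, f = f))
  f(p)
}

param_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- param_map2(a[[i]], b[[i]], f)
    return(out)
  }
  f(a, b)
}

zeros_like <- function(p) param_map(p, function(x) x * 0)

he_matrix <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- param_map(state$m, function(m) m / bc1)
  vhat <- param_map(state$v, function(v) v / bc2)
  upd <- param_map2(mhat, vhat, function(m, v) lr * m / (sqrt(v) + eps))
  params <- param_map2(params, upd, `-`)
  list(params = params, state = state)
}
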