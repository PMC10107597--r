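#' Model configuration
#'
#' Collects every architectural choice of the stereo spatial decoupling
#' network. The backbone is three 3x3 stride-2 convolution + ReLU blocks
#' (widths `widths`), so `image_size` must be divisible by 8; the
#' shallow map `f_x` has spatial side `image_size / 8` and `widths[3]`
#' channels. `d_fuse` is the width of the one-dimensional fusion space:
#' every fusion addend is flattened and affinely mapped to length
#' `d_fuse`, whatever the input shape. `head_filters` is the channel
#' count of the classifier's 1-D convolution. `sgdm_shallow` selects
#' which map the shallow SGDM screen gates (`"fx"`, the default, or
#' `"f1"`). `knockout` names feature pathways (`"f_cg"`, `"f1"`,
#' `"f2"`, `"f3"`) replaced by exact zeros, used by the ablation
#' harness.
#'
#' Note: at the full-scale defaults (256 px, widths 32/64/128) the
#' flatten-to-fuse affine maps are large (hundreds of MB); desk-scale
#' work should use a reduced configuration such as `image_size = 64`,
#' `widths = c(8, 16, 32)`, `d_fuse = 64`.
#'
#' @param image_size square input side in pixels (divisible by 8).
#' @param in_channels input image channels (grayscale is replicated to 3).
#' @param widths backbone channel widths, length 3.
#' @param d_fuse fusion vector width, at least `n_classes`.
#' @param n_classes number of classes S.
#' @param thresholds a [threshold_config()].
#' @param fy_filters channels of the deep local block applied to `f_2`.
#' @param f1_filters channels of the `f_1` convolution in the fusion head.
#' @param head_filters classifier 1-D convolution channels.
#' @param mean_rule CFSM cross-mean rule, see [cross_mean()].
#' @param sgdm_shallow `"fx"` or `"f1"`.
#' @param knockout character subset of `c("f_cg", "f1", "f2", "f3")`.
#' @param seed integer seed controlling every parameter draw.
#' @return list of class `tsd_config`.
#' @export
tsd_config <- function(image_size = 256L, in_channels = 3L,
                       widths = c(32L, 64L, 128L), d_fuse = 256L,
                       n_classes = 2L, thresholds = threshold_config(),
                       fy_filters = widths[3L], f1_filters = widths[3L],
                       head_filters = 4L,
                       mean_rule = c("printed", "self"),
                       sgdm_shallow = c("fx", "f1"),
                       knockout = character(0), seed = 1L) {
  mean_rule <- match.arg(mean_rule)
  sgdm_shallow <- match.arg(sgdm_shallow)
  if (image_size %% 8L != 0L) stop("configuration error: image_size must be divisible by 8")
  if (length(widths) != 3L || any(widths < 1L)) stop("configuration error: need 3 positive widths")
  if (d_fuse < n_classes) stop("configuration error: d_fuse must be >= n_classes")
  if (!inherits(thresholds, "threshold_config")) thresholds <- do.call(threshold_config, thresholds)
  bad <- setdiff(knockout, c("f_cg", "f1", "f2", "f3"))
  if (length(bad)) stop("unknown knockout pathway: ", paste(bad, collapse = ", "))
  if (setequal(knockout, c("f_cg", "f1", "f2", "f3"))) {
    stop("invalid-plan error: cannot knock out every pathway")
  }
  structure(list(
    image_size = as.integer(image_size), in_channels = as.integer(in_channels),
    widths = as.integer(widths), d_fuse = as.integer(d_fuse),
    n_classes = as.integer(n_classes), thresholds = thresholds,
    fy_filters = as.integer(fy_filters), f1_filters = as.integer(f1_filters),
    head_filters = as.integer(head_filters), mean_rule = mean_rule,
    sgdm_shallow = sgdm_shallow, knockout = knockout, seed = as.integer(seed)
  ), class = "tsd_config")
}

# derived shapes of the fixed graph
model_dims <- function(cfg) {
  side <- cfg$image_size %/% 8L
  C <- cfg$widths[3L]
  list(
    side = side, C = C, C3 = 3L * C,
    n_f3 = side * side * 3L * C,
    n_f1c = side * side * cfg$f1_filters,
    n_fcg = side * side * C,
    n_fhat = side * side * cfg$fy_filters,
    seq_len_fi = 2L * cfg$d_fuse + side * side * cfg$fy_filters
  )
}

#' Build the end-to-end model
#'
#' Wires backbone, directional attention, CFSM, SGDM and the fusion
#' head; parameters are drawn deterministically from `cfg$seed`. The
#' classifier's final affine starts at zero so that early training is
#' driven by the learned fusion features rather than initialisation
#' noise. Attention head parameters are fixed (screening masks are
#' constants under backpropagation, so no gradient reaches them).
#'
#' @param cfg a [tsd_config()].
#' @return list of class `tsd_model` with elements `cfg`, `params`
#'   (trainable) and `attn` (fixed attention parameters).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "tsd_config"))
  dm <- model_dims(cfg)
  w <- cfg$widths
  attn <- attention_init(dm$C, seed = cfg$seed + 1000003L)
  set.seed(cfg$seed)
  params <- list(
    conv1 = list(W = he_matrix(9L * cfg$in_channels, w[1L]), b = numeric(w[1L])),
    conv2 = list(W = he_matrix(9L * w[1L], w[2L]), b = numeric(w[2L])),
    conv3 = list(W = he_matrix(9L * w[2L], w[3L]), b = numeric(w[3L])),
    conv_fy = list(W = he_matrix(9L * dm$C3, cfg$fy_filters), b = numeric(cfg$fy_filters)),
    conv_f1 = list(W = he_matrix(9L * dm$C3, cfg$f1_filters), b = numeric(cfg$f1_filters)),
    dense_f3 = list(W = he_matrix(dm$n_f3, cfg$d_fuse), b = numeric(cfg$d_fuse)),
    dense_f1 = list(W = he_matrix(dm$n_f1c, cfg$d_fuse), b = numeric(cfg$d_fuse)),
    dense_fcg_mid = list(W = he_matrix(dm$n_fcg, cfg$d_fuse), b = numeric(cfg$d_fuse)),
    dense_fcg_deep = list(W = he_matrix(dm$n_fcg, cfg$d_fuse), b = numeric(cfg$d_fuse)),
    conv_m = list(W = he_matrix(3L, 1L), b = numeric(1L)),
    conv_head = list(W = he_matrix(3L, cfg$head_filters), b = numeric(cfg$head_filters)),
    dense_out = list(W = matrix(0, dm$seq_len_fi * cfg$head_filters, cfg$n_classes),
                     b = numeric(cfg$n_classes))
  )
  structure(list(cfg = cfg, params = params, attn = attn), class = "tsd_model")
}

ko_factor <- function(cfg, what) if (what %in% cfg$knockout) 0 else 1

#' Forward pass for a single sample
#'
#' @param model a `tsd_model`.
#' @param x input image array `(image_size, image_size, in_channels)`.
#' @param keep_cache keep intermediates for the backward pass /
#'   inspection.
#' @return list with `probs` (length-S probability vector, sums to 1)
#'   and, when `keep_cache`, the full `cache` of intermediates.
#' @export
forward_sample <- function(model, x, keep_cache = FALSE) {
  cfg <- model$cfg
  p <- model$params
  thr <- cfg$thresholds
  stopifnot(identical(dim(x)[1:2], rep(cfg$image_size, 2L)))

  b1 <- conv2d_forward(x, p$conv1$W, p$conv1$b, stride = 2L, pad = 1L)
  a1 <- relu(b1$out)
  b2 <- conv2d_forward(a1, p$conv2$W, p$conv2$b, stride = 2L, pad = 1L)
  a2 <- relu(b2$out)
  b3 <- conv2d_forward(a2, p$conv3$W, p$conv3$b, stride = 2L, pad = 1L)
  f_x <- relu(b3$out)

  w <- attention_weights(f_x, model$attn)
  cf <- cfsm_chain(f_x, w, thr, rule = cfg$mean_rule, per_pixel = TRUE)
  ko1 <- ko_factor(cfg, "f1"); ko2 <- ko_factor(cfg, "f2")
  ko3 <- ko_factor(cfg, "f3"); koc <- ko_factor(cfg, "f_cg")
  f1 <- cf$f1 * ko1
  f2 <- cf$f2 * ko2
  f3 <- cf$f3 * ko3

  by <- conv2d_forward(f2, p$conv_fy$W, p$conv_fy$b, stride = 1L, pad = 1L)
  f_y <- relu(by$out)
  shallow_src <- if (cfg$sgdm_shallow == "fx") f_x else f1
  sg <- sgdm_chain(w, shallow_src, f_y, thr, per_pixel = TRUE)
  f_cg <- sg$f_cg * koc
  f_cg_deep <- sg$f_cg_deep

  # fusion head: every addend flattened and affinely mapped to d_fuse
  d3 <- dense_forward(as.vector(f3), p$dense_f3$W, p$dense_f3$b)
  bf1 <- conv2d_forward(f1, p$conv_f1$W, p$conv_f1$b, stride = 1L, pad = 1L)
  f1c <- relu(bf1$out)
  d1 <- dense_forward(as.vector(f1c), p$dense_f1$W, p$dense_f1$b)
  dc <- dense_forward(as.vector(f_cg), p$dense_fcg_mid$W, p$dense_fcg_mid$b)
  f_m <- d3$out + d1$out + dc$out

  dd <- dense_forward(as.vector(f_cg), p$dense_fcg_deep$W, p$dense_fcg_deep$b)
  f_cg2 <- matrix(dd$out, ncol = 1L)                       # (d_fuse, 1)
  cm1 <- conv1d_forward(matrix(f_m, ncol = 1L), p$conv_m$W, p$conv_m$b)
  f_m1 <- cm1$out                                          # (d_fuse, 1)
  f_hat <- matrix(as.vector(f_cg_deep), ncol = 1L)
  f_i <- rbind(f_cg2, f_m1, f_hat)

  ch <- conv1d_forward(f_i, p$conv_head$W, p$conv_head$b)
  hc <- relu(ch$out)
  dout <- dense_forward(as.vector(hc), p$dense_out$W, p$dense_out$b)
  probs <- softmax_vec(dout$out)

  res <- list(probs = probs, logits = dout$out)
  if (keep_cache) {
    res$cache <- list(
      x = x, b1 = b1, a1 = a1, b2 = b2, a2 = a2, b3 = b3, f_x = f_x,
      w = w, cf = cf, f1 = f1, f2 = f2, f3 = f3,
      by = by, f_y = f_y, sg = sg, f_cg = f_cg, f_cg_deep = f_cg_deep,
      d3 = d3, bf1 = bf1, f1c = f1c, d1 = d1, dc = dc, f_m = f_m,
      dd = dd, cm1 = cm1, f_i = f_i, ch = ch, hc = hc, dout = dout,
      ko = c(f1 = ko1, f2 = ko2, f3 = ko3, f_cg = koc)
    )
  }
  res
}

#' Backward pass for a single sample
#'
#' Computes the cross-entropy loss and its gradient with respect to
#' every trainable parameter. Gate masks are constants under
#' backpropagation: eliminated positions contribute exactly zero
#' gradient, and no gradient reaches the attention heads (thresholding
#' is piecewise constant in them).
#'
#' @param model a `tsd_model`.
#' @param cache the `cache` of a [forward_sample()] call with
#'   `keep_cache = TRUE`.
#' @param y true class label in `1..n_classes`.
#' @return list with `grads` (parameter-shaped gradient tree) and
#'   `loss` (scalar cross-entropy).
#' @export
backward_sample <- function(model, cache, y) {
  cfg <- model$cfg
  p <- model$params
  dm <- model_dims(cfg)
  ko <- cache$ko
  g <- zeros_like(p)

  sc <- softmax_ce(cache$dout$out, y)
  dlog <- sc$dlogits
  bo <- dense_backward(dlog, cache$dout$cache)
  g$dense_out$W <- bo$dW; g$dense_out$b <- bo$db
  dhc <- array(bo$dx, dim = dim(cache$hc))
  dch <- relu_backward(dhc, cache$ch$out)
  bh <- conv1d_backward(dch, cache$ch$cache)
  g$conv_head$W <- bh$dW; g$conv_head$b <- bh$db
  dfi <- bh$dx

  n1 <- cfg$d_fuse; n2 <- cfg$d_fuse
  d_fcg2 <- dfi[seq_len(n1), , drop = FALSE]
  d_fm1 <- dfi[n1 + seq_len(n2), , drop = FALSE]
  d_fhat <- dfi[n1 + n2 + seq_len(dm$n_fhat), , drop = FALSE]

  # deep screened branch -> f_y conv -> f_2
  d_fcgdeep <- array(as.vector(d_fhat), dim = dim(cache$f_cg_deep))
  d_fy <- gate_multiply(d_fcgdeep, cache$sg$D_hat)
  d_by <- relu_backward(d_fy, cache$by$out)
  bb <- conv2d_backward(d_by, cache$by$cache)
  g$conv_fy$W <- bb$dW; g$conv_fy$b <- bb$db
  d_f2 <- bb$dx * ko[["f2"]]

  # f_m pathway
  bm <- conv1d_backward(d_fm1, cache$cm1$cache)
  g$conv_m$W <- bm$dW; g$conv_m$b <- bm$db
  d_fm <- as.vector(bm$dx)

  b3d <- dense_backward(d_fm, cache$d3$cache)
  g$dense_f3$W <- b3d$dW; g$dense_f3$b <- b3d$db
  d_f3 <- array(b3d$dx, dim = dim(cache$f3)) * ko[["f3"]]

  b1d <- dense_backward(d_fm, cache$d1$cache)
  g$dense_f1$W <- b1d$dW; g$dense_f1$b <- b1d$db
  d_f1c <- relu_backward(array(b1d$dx, dim = dim(cache$f1c)), cache$bf1$out)
  bf <- conv2d_backward(d_f1c, cache$bf1$cache)
  g$conv_f1$W <- bf$dW; g$conv_f1$b <- bf$db
  d_f1 <- bf$dx * ko[["f1"]]

  bcd <- dense_backward(d_fm, cache$dc$cache)
  g$dense_fcg_mid$W <- bcd$dW; g$dense_fcg_mid$b <- bcd$db
  d_fcg <- array(bcd$dx, dim = dim(cache$f_cg))

  bdd <- dense_backward(as.vector(d_fcg2), cache$dd$cache)
  g$dense_fcg_deep$W <- bdd$dW; g$dense_fcg_deep$b <- bdd$db
  d_fcg <- d_fcg + array(bdd$dx, dim = dim(cache$f_cg))
  d_fcg <- d_fcg * ko[["f_cg"]]
  d_shallow <- gate_multiply(d_fcg, cache$sg$S_hat)

  # CFSM: push level gradients back through the branch masks onto f_x
  C <- dm$C
  d_fx <- array(0, dim = dim(cache$f_x))
  blocks <- list(HV = seq_len(C), HD = C + seq_len(C), VD = 2L * C + seq_len(C))
  level_masks <- c("m_imp", "m_sec", "m_red")
  d_levels <- list(d_f1, d_f2, d_f3)
  for (b in names(blocks)) {
    for (k in 1:3) {
      dl <- d_levels[[k]][, , blocks[[b]], drop = FALSE]
      d_fx <- d_fx + gate_multiply(dl, cache$cf$masks[[b]][[level_masks[k]]])
    }
  }
  if (cfg$sgdm_shallow == "fx") {
    d_fx <- d_fx + d_shallow
  } else {
    # shallow screen gated f1: route through the important-level masks
    d1s <- d_shallow * ko[["f1"]]
    for (b in names(blocks)) {
      d_fx <- d_fx + gate_multiply(d1s[, , blocks[[b]], drop = FALSE],
                                   cache$cf$masks[[b]]$m_imp)
    }
  }

  # backbone
  d_b3 <- relu_backward(d_fx, cache$b3$out)
  bk3 <- conv2d_backward(d_b3, cache$b3$cache)
  g$conv3$W <- bk3$dW; g$conv3$b <- bk3$db
  d_a2 <- relu_backward(bk3$dx, cache$b2$out)
  bk2 <- conv2d_backward(d_a2, cache$b2$cache)
  g$conv2$W <- bk2$dW; g$conv2$b <- bk2$db
  d_a1 <- relu_backward(bk2$dx, cache$b1$out)
  bk1 <- conv2d_backward(d_a1, cache$b1$cache)
  g$conv1$W <- bk1$dW; g$conv1$b <- bk1$db

  list(grads = g, loss = sc$loss)
}

#' Parameter count of a model
#' @param model a `tsd_model`.
#' @param trainable_only count only trained parameters (default TRUE;
#'   otherwise the fixed attention heads are included).
#' @return integer.
#' @export
count_params <- function(model, trainable_only = TRUE) {
  n <- 0
  param_map(model$params, function(x) { n <<- n + length(x); x })
  if (!trainable_only) param_map(model$attn, function(x) { n <<- n + length(x); x })
  n
}

#' Predict class probabilities for a batch
#' @param model a `tsd_model`.
#' @param x array `(N, S, S, C)` or a single `(S, S, C)` image.
#' @return N x n_classes probability matrix.
#' @export
predict_probs <- function(model, x) {
  if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
  n <- dim(x)[1L]
  out <- matrix(0, n, model$cfg$n_classes)
  for (i in seq_len(n)) {
    out[i, ] <- forward_sample(model, batch_slice(x, i))$probs
  }
  out
}

#' Predict hard class labels for a batch
#' @inheritParams predict_probs
#' @return integer vector of class labels in `1..n_classes`.
#' @export
predict_classes <- function(model, x) {
  max.col(predict_probs(model, x), ties.method = "first")
}
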