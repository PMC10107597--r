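#' Tri-directional attention
#'
#' A shallow feature map `f_x` of shape (H, W, C) is scored by three
#' independent attention heads, one per spatial direction:
#' horizontal (weights normalised across the width axis), vertical
#' (across the height axis) and depth (across the channel axis).
#' Each head computes a hidden representation `h` by a learned 1x1
#' channel mixing of the input, scores it with a per-channel affine map
#' into logits `e`, applies a softmax along its direction's axis, and
#' finally rescales the whole weight map so its maximum equals 1. The
#' rescaling makes gate thresholds such as `T1 = 0.5` scale-free: a raw
#' axis softmax scales as `1/n` and would never clear them.
#'
#' @name directional_attention
NULL

DIRECTIONS <- c("H", "V", "D")

# axis each direction normalises over, in (H, W, C) index order
direction_axis <- function(direction, axes = c(H = 2L, V = 1L, D = 3L)) {
  if (!direction %in% names(axes)) {
    stop(sprintf("unknown direction tag '%s' (expected one of %s)",
                 direction, paste(names(axes), collapse = ", ")))
  }
  axes[[direction]]
}

#' Initialise directional attention parameters
#'
#' Each direction gets an independent head: a `C x C` mixing matrix with
#' zero bias and a per-channel affine score (`gamma`, `beta`). Mixing
#' weights are drawn N(0, 1/C); `gamma` starts at 1 and `beta` at 0 so
#' that a zero input yields zero logits.
#'
#' @param n_channels channel count `C` of the feature map to be scored.
#' @param seed integer seed; the draw is deterministic given it.
#' @return a named list with one parameter set per direction tag.
#' @export
attention_init <- function(n_channels, seed = 1L) {
  stopifnot(n_channels >= 1L)
  set.seed(as.integer(seed))
  one <- function() {
    list(
      W_mix = matrix(stats::rnorm(n_channels^2, sd = 1 / sqrt(n_channels)),
                     n_channels, n_channels),
      b_mix = numeric(n_channels),
      gamma = rep(1, n_channels),
      beta  = numeric(n_channels)
    )
  }
  out <- lapply(DIRECTIONS, function(d) one())
  names(out) <- DIRECTIONS
  out
}

#' Compute directional attention logits
#'
#' For each direction: `h = f . W_mix + b_mix` (1x1 channel mixing),
#' then `e = h * gamma + beta` channelwise. Logits keep the shape of the
#' input feature map.
#'
#' @param f feature map, (H,W,C) or (N,H,W,C).
#' @param params parameter list from [attention_init()].
#' @return named list of logit arrays, one per direction tag.
#' @export
compute_directional_logits <- function(f, params) {
  check_feature_map(f)
  if (has_batch(f)) return(map_batch(f, compute_directional_logits, params))
  d <- dim(f)
  C <- d[3L]
  if (!identical(dim(params$H$W_mix), c(C, C))) {
    stop(sprintf("configuration error: params built for %d channels, map has %d",
                 nrow(params$H$W_mix), C))
  }
  fm <- matrix(f, nrow = d[1L] * d[2L], ncol = C)
  out <- lapply(params, function(p) {
    h <- sweep(fm %*% p$W_mix, 2L, p$b_mix, `+`)
    e <- sweep(sweep(h, 2L, p$gamma, `*`), 2L, p$beta, `+`)
    array(e, dim = d)
  })
  names(out) <- names(params)
  out
}

#' Normalise logits into a directional weight map
#'
#' Applies a softmax along the direction's axis (H: width, V: height,
#' D: channels), then rescales the map by its global maximum so
#' `max(a) = 1`. Pre-rescale, entries along the designated axis sum to 1.
#'
#' @param e logit array, (H,W,C) or (N,H,W,C).
#' @param direction one of `"H"`, `"V"`, `"D"`.
#' @param rescale divide by the per-map maximum (default TRUE).
#' @param axes named axis binding, configurable.
#' @return weight array in `[0, 1]`, same shape as `e`.
#' @export
normalize_direction <- function(e, direction, rescale = TRUE,
                                axes = c(H = 2L, V = 1L, D = 3L)) {
  axis <- direction_axis(direction, axes)
  if (length(dim(e)) == 4L) {
    return(map_batch(e, normalize_direction, direction, rescale, axes))
  }
  a <- softmax_axis(e, axis)
  if (rescale) a <- a / max(a)
  a
}

#' Directional attention weights a_H, a_V, a_D
#'
#' Composition of [compute_directional_logits()] and
#' [normalize_direction()] for the three directions.
#'
#' @inheritParams compute_directional_logits
#' @param axes named axis binding (see [normalize_direction()]).
#' @return list with arrays `a_H`, `a_V`, `a_D`, each in `[0, 1]` with
#'   per-map maximum 1.
#' @export
attention_weights <- function(f, params, axes = c(H = 2L, V = 1L, D = 3L)) {
  check_feature_map(f)
  if (has_batch(f)) return(map_batch(f, attention_weights, params, axes))
  e <- compute_directional_logits(f, params)
  out <- list(
    a_H = normalize_direction(e$H, "H", axes = axes),
    a_V = normalize_direction(e$V, "V", axes = axes),
    a_D = normalize_direction(e$D, "D", axes = axes)
  )
  out
}
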