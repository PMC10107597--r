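# Internal array helpers shared by the attention / screening modules.
# Feature maps are plain numeric arrays of shape (H, W, C); every public
# operator also accepts a leading batch index (N, H, W, C) and applies
# itself per sample.

#' Validate a feature map array
#'
#' A feature map is a numeric array of shape `(H, W, C)` — height, width,
#' channels — or `(N, H, W, C)` with a leading batch index. All entries must
#' be finite and every extent at least 1.
#'
#' @param f numeric array.
#' @param arg name used in error messages.
#' @return `f`, invisibly, after validation.
#' @export
check_feature_map <- function(f, arg = "f") {
  if (!is.numeric(f)) stop(sprintf("`%s` must be numeric", arg))
  d <- dim(f)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop(sprintf("`%s` must be a 3-D (H,W,C) or 4-D (N,H,W,C) array", arg))
  }
  if (any(d < 1L)) stop(sprintf("`%s` has a zero extent", arg))
  if (!all(is.finite(f))) stop(sprintf("`%s` contains non-finite values", arg))
  invisible(f)
}

has_batch <- function(f) length(dim(f)) == 4L

# Apply `fun(sample_array, ...)` over the batch axis of a 4-D array,
# restacking results (which may be arrays or lists of arrays).
map_batch <- function(f, fun, ...) {
  if (!has_batch(f)) return(fun(f, ...))
  n <- dim(f)[1L]
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- fun(batch_slice(f, i), ...)
  restack(out)
}

batch_slice <- function(f, i) {
  d <- dim(f)
  x <- f[i, , , , drop = FALSE]
  dim(x) <- d[-1L]
  x
}

restack <- function(lst) {
  first <- lst[[1L]]
  if (is.list(first)) {
    out <- lapply(names(first), function(nm) restack(lapply(lst, `[[`, nm)))
    names(out) <- names(first)
    return(out)
  }
  d <- dim(first)
  out <- array(0, dim = c(length(lst), d))
  for (i in seq_along(lst)) out[i, , , ] <- lst[[i]]
  out
}

# Softmax along one axis of a 3-D array, numerically stabilised.
softmax_axis <- function(e, axis) {
  d <- dim(e)
  stopifnot(length(d) == 3L, axis %in% 1:3)
  perm <- c(setdiff(1:3, axis), axis)
  ep <- aperm(e, perm)
  m <- matrix(ep, ncol = d[axis])       # rows: all other positions
  m <- m - apply(m, 1L, max)
  m <- exp(m)
  m <- m / rowSums(m)
  ep <- array(m, dim = d[perm])
  aperm(ep, order(perm))
}

# Concatenate 3-D arrays along the channel (last) axis.
cat_channels <- function(...) {
  maps <- list(...)
  if (length(maps) == 1L && is.list(maps[[1L]])) maps <- maps[[1L]]
  d1 <- dim(maps[[1L]])[1:2]
  for (m in maps) {
    if (!identical(dim(m)[1:2], d1)) {
      stop("cat_channels: inconsistent spatial shapes")
    }
  }
  ctot <- sum(vapply(maps, function(m) dim(m)[3L], integer(1)))
  out <- array(0, dim = c(d1, ctot))
  at <- 0L
  for (m in maps) {
    c_m <- dim(m)[3L]
    out[, , at + seq_len(c_m)] <- m
    at <- at + c_m
  }
  out
}

# Mean over the channel axis: (H,W,C) -> (H,W).
channel_mean <- function(f) {
  d <- dim(f)
  matrix(rowMeans(matrix(f, nrow = d[1L] * d[2L], ncol = d[3L])), d[1L], d[2L])
}

# Multiply a feature map by a gate that is either an (H,W) spatial mask
# (broadcast across channels) or a mask of the map's own full shape.
gate_multiply <- function(f, mask) {
  d <- dim(f)
  md <- dim(mask)
  if (is.null(md)) md <- length(mask)
  if (identical(as.integer(md), as.integer(d))) return(f * as.numeric(mask))
  if (length(md) == 2L && all(md == d[1:2])) {
    return(f * as.numeric(array(mask, dim = d)))  # column-major: (H,W) recycles over C
  }
  stop("mask shape is neither the map's shape nor its spatial (H,W) shape")
}
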