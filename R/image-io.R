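# Plain-text PGM (P2) image I/O and bilinear resizing. PGM is used as
# the on-disk image format throughout: it is human-readable, diffable,
# byte-deterministic and needs no compression codec.

#' Write a grayscale image as plain-text PGM (P2)
#'
#' @param img numeric matrix in `[0, 1]` (rows = image rows).
#' @param path output file.
#' @param maxval intensity quantisation ceiling (default 255).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  stopifnot(is.matrix(img))
  q <- round(pmin(pmax(img, 0), 1) * maxval)
  con <- file(path, open = "wb")  # binary connection: fixed "\n", no CRLF drift
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  # one image row per line
  writeLines(apply(q, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read a plain-text PGM (P2) image
#'
#' @param path PGM file.
#' @return numeric matrix scaled to `[0, 1]`.
#' @export
read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1L] != "P2") stop("not a plain (P2) PGM file: ", path)
  w <- as.integer(tok[2L]); h <- as.integer(tok[3L])
  maxval <- as.numeric(tok[4L])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM payload: ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' Bilinear image resize
#'
#' Pixel-centre convention: output centre `(i - 0.5) * scale + 0.5` in
#' input coordinates, clamped at the borders. A 1:1 resize reproduces
#' the input exactly.
#'
#' @param img numeric matrix.
#' @param out_h,out_w target extent.
#' @return resized matrix.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  in_h <- nrow(img); in_w <- ncol(img)
  if (in_h == out_h && in_w == out_w) return(img)
  map_axis <- function(n_out, n_in) {
    src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    src <- pmin(pmax(src, 1), n_in)
    lo <- pmin(floor(src), n_in - 1L)
    if (n_in == 1L) lo <- rep(1L, n_out)
    list(lo = as.integer(lo), frac = src - lo)
  }
  mi <- map_axis(out_h, in_h)
  mj <- map_axis(out_w, in_w)
  hi_i <- pmin(mi$lo + 1L, in_h)
  hi_j <- pmin(mj$lo + 1L, in_w)
  a <- img[mi$lo, mj$lo, drop = FALSE]
  b <- img[hi_i, mj$lo, drop = FALSE]
  cc <- img[mi$lo, hi_j, drop = FALSE]
  d <- img[hi_i, hi_j, drop = FALSE]
  fi <- matrix(mi$frac, out_h, out_w)
  fj <- matrix(mj$frac, out_h, out_w, byrow = TRUE)
  a * (1 - fi) * (1 - fj) + b * fi * (1 - fj) + cc * (1 - fi) * fj + d * fi * fj
}
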