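#' Attention weight visualisation
#'
#' Renders the weighting process for one input image as a 3x3 panel of
#' nine tiles: (a) the original image, (b) the deep feature map
#' (channel mean of `f_x`), (c-e) the vertical, horizontal and depth
#' attention weights, (f-h) the three CFSM cross-mean maps (HV, HD, VD)
#' and (i) the SGDM combined weight magnitude. Every tile's numeric
#' grid is also dumped as CSV, and the assembled panel is written as a
#' plain-text PGM montage.
#'
#' @param model a `tsd_model`.
#' @param image input image: `(S,S,C)` array or `(S,S)` matrix.
#' @param out_dir output directory for `panel.pgm` and the per-tile
#'   CSV grids; `NULL` skips writing.
#' @param tile_px rendered tile side in the montage.
#' @return named list of the nine numeric tile matrices, invisibly
#'   when written.
#' @export
visualize_weights <- function(model, image, out_dir = NULL, tile_px = 80L) {
  if (is.matrix(image)) image <- array(image, c(dim(image), model$cfg$in_channels))
  fw <- forward_sample(model, image, keep_cache = TRUE)
  cc <- fw$cache
  cV <- channel_mean(cc$w$a_V)
  cH <- channel_mean(cc$w$a_H)
  cD <- channel_mean(cc$w$a_D)
  tiles <- list(
    a_original = channel_mean(image),
    b_deep_feature = channel_mean(cc$f_x),
    c_vertical = cV,
    d_horizontal = cH,
    e_depth = cD,
    f_cross_HV = as.matrix(cc$cf$cross_means$HV),
    g_cross_HD = as.matrix(cc$cf$cross_means$HD),
    h_cross_VD = as.matrix(cc$cf$cross_means$VD),
    # combined magnitude of the displayed (channel-mean) weight tiles,
    # so the panel is exactly reproducible from its own CSV dumps
    i_sgdm_combined = sqrt(cV^2 + cH^2 + cD^2)
  )
  if (is.null(out_dir)) return(tiles)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (nm in names(tiles)) {
    utils::write.table(tiles[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  write_pgm(montage_3x3(tiles, tile_px), file.path(out_dir, "panel.pgm"))
  invisible(tiles)
}

# nearest-neighbour upscale to a common tile size, unit-normalise,
# assemble with 1-px separators
montage_3x3 <- function(tiles, tile_px) {
  norm01 <- function(m) {
    r <- range(m)
    if (diff(r) == 0) return(m * 0)
    (m - r[1L]) / diff(r)
  }
  nn <- function(m) {
    ri <- pmin(pmax(ceiling(seq_len(tile_px) * nrow(m) / tile_px), 1L), nrow(m))
    cj <- pmin(pmax(ceiling(seq_len(tile_px) * ncol(m) / tile_px), 1L), ncol(m))
    m[ri, cj, drop = FALSE]
  }
  rend <- lapply(tiles, function(t) nn(norm01(t)))
  side <- 3L * tile_px + 2L
  panel <- matrix(1, side, side)
  for (q in seq_along(rend)) {
    r0 <- ((q - 1L) %/% 3L) * (tile_px + 1L)
    c0 <- ((q - 1L) %% 3L) * (tile_px + 1L)
    panel[r0 + seq_len(tile_px), c0 + seq_len(tile_px)] <- rend[[q]]
  }
  panel
}
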