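#' Semantic guided decoupling module (SGDM)
#'
#' Combines the three directional weight maps into a single magnitude
#' map — the elementwise Euclidean norm `sqrt(a_H^2 + a_V^2 + a_D^2)`,
#' bounded by `sqrt(3)` — and thresholds it twice: at `T1` to screen the
#' shallow global features `f_x` into `f_cg`, and at `T3` to screen the
#' deep local features `f_y` into `f'_cg`. Because
#' `sqrt(a^2 + ...) >= a`, any point whose weight in a single direction
#' already exceeds the threshold survives the screen.
#'
#' @name sgdm
NULL

#' Combined directional weight magnitude
#'
#' Elementwise Euclidean norm of the three directional weights. The
#' shallow (`S_HVD`) and deep (`D_HVD`) maps are defined by the same
#' formula and returned as two names for the one quantity; they differ
#' only in the threshold later applied to them.
#'
#' @param w list with `a_H`, `a_V`, `a_D`.
#' @return list with `S_HVD` and `D_HVD`, entries in `[0, sqrt(3)]`.
#' @export
combined_magnitude <- function(w) {
  if (!identical(dim(w$a_H), dim(w$a_V)) || !identical(dim(w$a_H), dim(w$a_D))) {
    stop("combined_magnitude: shape mismatch among a_H, a_V, a_D")
  }
  s <- sqrt(w$a_H^2 + w$a_V^2 + w$a_D^2)
  list(S_HVD = s, D_HVD = s)
}

#' Threshold a combined-weight map into a binary screen mask
#'
#' 1 where the map is `>= T`, else 0 (equality retained, mirroring the
#' CFSM tie rule).
#'
#' @param c_map real array.
#' @param T_gate finite threshold.
#' @return binary array of the same shape.
#' @export
threshold_mask <- function(c_map, T_gate) {
  if (!is.finite(T_gate)) stop("threshold must be finite")
  (c_map >= T_gate) * 1
}

#' Screen a feature map with a binary mask
#'
#' Elementwise (Hadamard) gating; an `(H, W)` spatial mask broadcasts
#' across channels. Used for `f_cg = S_hat * f_x` and
#' `f'_cg = D_hat * f_y`.
#'
#' @param mask binary array.
#' @param f feature map (H,W,C).
#' @return gated feature map, same shape as `f`.
#' @export
screen_features <- function(mask, f) {
  gate_multiply(f, mask)
}

#' Full SGDM chain
#'
#' Computes the combined magnitude of the directional weights, reduces
#' it per spatial position when `per_pixel` (model default), thresholds
#' at `T1` (shallow) and `T3` (deep), and gates the shallow and deep
#' feature maps.
#'
#' @param w directional weights.
#' @param f_shallow shallow features to screen at `T1` (`f_x`, or `f_1`
#'   under the alternative gating choice).
#' @param f_deep deep features to screen at `T3` (`f_y`).
#' @param thr a [threshold_config()].
#' @param per_pixel logical; reduce the magnitude over channels first.
#' @return list with `f_cg`, `f_cg_deep`, the two masks and the
#'   magnitude map used.
#' @export
sgdm_chain <- function(w, f_shallow, f_deep, thr = threshold_config(),
                       per_pixel = TRUE) {
  cmb <- combined_magnitude(w)
  s <- cmb$S_HVD
  if (per_pixel) s <- channel_mean(s)
  S_hat <- threshold_mask(s, thr$T1)
  D_hat <- threshold_mask(s, thr$T3)
  list(
    f_cg = screen_features(S_hat, f_shallow),
    f_cg_deep = screen_features(D_hat, f_deep),
    S_hat = S_hat, D_hat = D_hat, magnitude = s
  )
}
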