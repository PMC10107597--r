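#' Cross feature screening module (CFSM)
#'
#' Pairs the three directional weight maps, averages the paired maps
#' crosswise, and splits every feature point into one of three levels by
#' a dual gate threshold: important (mean >= T1), secondary
#' (T2 <= mean < T1) and redundant (mean < T2). Each level's binary mask
#' gates the shallow feature map; the three gated branches (HV, HD, VD)
#' are concatenated channelwise into the level features `f_1`, `f_2`,
#' `f_3`.
#'
#' @name cfsm
NULL

#' Threshold configuration
#'
#' The gate thresholds: `T1` and `T2` bound the CFSM dual gate
#' (`0 < T2 < T1 < 1`), `T3` gates the SGDM deep screen
#' (`0 < T3 < sqrt(3)`, the upper bound of the combined magnitude).
#' Defaults are the best-performing configuration of the threshold
#' ablation grid.
#'
#' @param T1,T2,T3 numeric gate thresholds.
#' @return validated list of class `threshold_config`.
#' @export
threshold_config <- function(T1 = 0.5, T2 = 0.3, T3 = 0.5) {
  if (!(is.finite(T1) && is.finite(T2) && is.finite(T3))) {
    stop("thresholds must be finite")
  }
  if (!(T2 > 0 && T2 < T1 && T1 < 1)) {
    stop("configuration error: need 0 < T2 < T1 < 1")
  }
  if (!(T3 > 0 && T3 < sqrt(3))) {
    stop("configuration error: need 0 < T3 < sqrt(3)")
  }
  structure(list(T1 = T1, T2 = T2, T3 = T3), class = "threshold_config")
}

#' Pair directional weights
#'
#' `a_XY = (a_X + a_Y) / 2` elementwise, for the pairs HV, HD, VD. The
#' arithmetic mean keeps the paired maps in `[0, 1]`.
#'
#' @param w list with `a_H`, `a_V`, `a_D` (equal shapes).
#' @return list with `a_HV`, `a_HD`, `a_VD`.
#' @export
pair_weights <- function(w) {
  if (!identical(dim(w$a_H), dim(w$a_V)) || !identical(dim(w$a_H), dim(w$a_D))) {
    stop("pair_weights: shape mismatch among a_H, a_V, a_D")
  }
  list(
    a_HV = (w$a_H + w$a_V) / 2,
    a_HD = (w$a_H + w$a_D) / 2,
    a_VD = (w$a_V + w$a_D) / 2
  )
}

#' Cross-mean of paired weights
#'
#' Averages the paired maps crosswise, branch by branch:
#' HV uses `(a_HV + a_HD)/2`, HD uses `(a_HD + a_VD)/2`, VD uses
#' `(a_VD + a_HV)/2`. With `rule = "self"` each branch instead gates on
#' its own paired map `a_XY` (the alternative reading of the screening
#' text; the crosswise rule is the default, as printed).
#'
#' @param p list from [pair_weights()].
#' @param branch one of `"HV"`, `"HD"`, `"VD"`.
#' @param rule `"printed"` (crosswise, default) or `"self"`.
#' @return real array, same shape as the paired maps.
#' @export
cross_mean <- function(p, branch, rule = c("printed", "self")) {
  rule <- match.arg(rule)
  if (!branch %in% c("HV", "HD", "VD")) {
    stop(sprintf("unknown branch '%s'", branch))
  }
  if (rule == "self") {
    return(switch(branch, HV = p$a_HV, HD = p$a_HD, VD = p$a_VD))
  }
  switch(branch,
    HV = (p$a_HV + p$a_HD) / 2,
    HD = (p$a_HD + p$a_VD) / 2,
    VD = (p$a_VD + p$a_HV) / 2
  )
}

#' Dual-gate masks
#'
#' Splits a mean weight array into three binary masks that partition
#' every position: important (`mean >= T1`), secondary
#' (`T2 <= mean < T1`) and redundant (`mean < T2`). Equality goes to the
#' upper level (closed-upper tie rule), which keeps the partition exact.
#'
#' @param mean_map real array (any shape).
#' @param T1,T2 gate thresholds with `T2 < T1`.
#' @return list of binary arrays `m_imp`, `m_sec`, `m_red` summing to 1
#'   at every position.
#' @export
dual_gate_masks <- function(mean_map, T1, T2) {
  if (!(T2 < T1)) stop("configuration error: need T2 < T1")
  m_imp <- (mean_map >= T1) * 1
  m_sec <- (mean_map >= T2 & mean_map < T1) * 1
  m_red <- (mean_map < T2) * 1
  list(m_imp = m_imp, m_sec = m_sec, m_red = m_red)
}

#' Apply gate masks to a feature map
#'
#' Elementwise (Hadamard) gating: zero where the mask is 0, unchanged
#' where it is 1. Spatial `(H, W)` masks broadcast across channels.
#'
#' @param f feature map (H,W,C).
#' @param g mask triple from [dual_gate_masks()].
#' @return list of three gated maps, in mask order.
#' @export
apply_masks <- function(f, g) {
  lapply(g, function(m) gate_multiply(f, m))
}

#' Assemble level features f_1, f_2, f_3
#'
#' Channel-axis concatenation of the three branch outputs per level, in
#' branch order HV, HD, VD; the channel count triples.
#'
#' @param branches named list with `HV`, `HD`, `VD`, each a list of
#'   three gated maps (important, secondary, redundant).
#' @return list with `f1`, `f2`, `f3`.
#' @export
assemble_levels <- function(branches) {
  lev <- function(k) cat_channels(branches$HV[[k]], branches$HD[[k]], branches$VD[[k]])
  list(f1 = lev(1L), f2 = lev(2L), f3 = lev(3L))
}

#' Full CFSM chain
#'
#' pair -> cross-mean -> dual gate -> apply -> concatenate. With
#' `per_pixel = TRUE` (the model default) the cross-mean is reduced over
#' channels before gating, so masks are per spatial position and
#' broadcast across channels; with `FALSE` the gate acts elementwise on
#' the full (H,W,C) cross-mean.
#'
#' @param f shallow feature map (H,W,C).
#' @param w directional weights from [attention_weights()].
#' @param thr a [threshold_config()].
#' @param rule cross-mean rule, see [cross_mean()].
#' @param per_pixel logical; reduce masks to spatial positions.
#' @return list with level features `f1`, `f2`, `f3`, the per-branch
#'   `masks`, and the `cross_means` used for gating.
#' @export
cfsm_chain <- function(f, w, thr = threshold_config(), rule = "printed",
                       per_pixel = TRUE) {
  p <- pair_weights(w)
  branches <- list()
  cms <- list()
  for (b in c("HV", "HD", "VD")) {
    cm <- cross_mean(p, b, rule)
    if (per_pixel) cm <- channel_mean(cm)
    g <- dual_gate_masks(cm, thr$T1, thr$T2)
    branches[[b]] <- apply_masks(f, g)
    cms[[b]] <- cm
    attr(branches[[b]], "masks") <- g
  }
  out <- assemble_levels(branches)
  out$masks <- lapply(branches, attr, "masks")
  out$cross_means <- cms
  out
}
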