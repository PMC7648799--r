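#' Smoothed Dice overlap score
#'
#' `(2 TP + eps) / (2 TP + FP + FN + eps)` with `eps = 1e-5`, computed on
#' the full 3-d masks. The smoothing makes the score well-defined (and
#' equal to 1) when both masks are empty. Symmetric in its arguments.
#'
#' @param pred,ref logical/0-1 arrays of identical geometry.
#' @param eps smoothing constant.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(pred, ref, eps = 1e-5) {
  if (!identical(dim(pred), dim(ref))) stop("geometry mismatch")
  pred <- as.logical(pred); ref <- as.logical(ref)
  tp <- sum(pred & ref)
  fp <- sum(pred & !ref)
  fn <- sum(!pred & ref)
  if (tp == length(pred)) return(1)  # identical full masks: eps cancels
  (2 * tp + eps) / (2 * tp + fp + fn + eps)
}

#' Percentile Hausdorff surface distance
#'
#' The p-th percentile of the set of minimum distances from each surface
#' voxel of the reference mask to the surface of the predicted mask
#' (directed variant, the default), in physical units. Surface voxels are
#' mask voxels with at least one face-adjacent (6-connected) background
#' neighbour. `p = 50` is the median surface distance; `p = 95` a robust
#' near-maximum. With `symmetric = TRUE` the distance sets of both
#' directions are pooled before taking the percentile.
#'
#' @param pred,ref nonempty logical/0-1 arrays of identical geometry.
#' @param p percentile in `[0, 100]` (may be a vector).
#' @param spacing micrometers per voxel per axis.
#' @param symmetric pool both directed distance sets?
#' @return Distance(s) in micrometers, `NA` with a `reason` attribute if
#'   either mask is empty.
#' @export
hausdorff_percentile <- function(pred, ref, p = c(50, 95),
                                 spacing = c(1, 1, 1), symmetric = FALSE) {
  if (!identical(dim(pred), dim(ref))) stop("geometry mismatch")
  pred <- array(as.logical(pred), dim(pred))
  ref <- array(as.logical(ref), dim(ref))
  if (!any(pred) || !any(ref)) {
    out <- rep(NA_real_, length(p))
    attr(out, "reason") <- if (!any(pred)) "empty prediction" else
      "empty reference"
    return(out)
  }
  ps <- mask_coords(surface_mask(pred))
  rs <- mask_coords(surface_mask(ref))
  ps <- sweep(ps, 2, spacing, "*")
  rs <- sweep(rs, 2, spacing, "*")
  dists <- cpp_min_dists(rs, ps)
  if (symmetric) dists <- c(dists, cpp_min_dists(ps, rs))
  unname(stats::quantile(dists, p / 100, type = 7))
}

#' Center-of-mass displacement
#'
#' Euclidean distance between the voxel-center centroids of two masks, in
#' physical units.
#'
#' @param pred,ref nonempty logical/0-1 arrays of identical geometry.
#' @param spacing micrometers per voxel per axis.
#' @return Distance in micrometers, `NA` with a `reason` attribute if a
#'   mask is empty.
#' @export
com_displacement <- function(pred, ref, spacing = c(1, 1, 1)) {
  if (!identical(dim(pred), dim(ref))) stop("geometry mismatch")
  pred <- array(as.logical(pred), dim(pred))
  ref <- array(as.logical(ref), dim(ref))
  if (!any(pred) || !any(ref)) {
    out <- NA_real_
    attr(out, "reason") <- if (!any(pred)) "empty prediction" else
      "empty reference"
    return(out)
  }
  cp <- colMeans(mask_coords(pred)) * spacing
  cr <- colMeans(mask_coords(ref)) * spacing
  sqrt(sum((cp - cr)^2))
}

#' Dice against the union of two annotations
#'
#' Re-evaluation rule under which a predicted voxel is deemed correct if
#' it matches at least one of the two annotations: `TP = |pred & (a1 |
#' a2)|`, `FP = |pred & !(a1 | a2)|`, and a voxel is only a false negative
#' if both annotators marked it: `FN = |!pred & (a1 & a2)|`. Same
#' smoothing as [dice()].
#'
#' @param pred,a1,a2 logical/0-1 arrays of identical geometry.
#' @param eps smoothing constant.
#' @return Score in `[0, 1]`.
#' @export
union_reference_dice <- function(pred, a1, a2, eps = 1e-5) {
  if (!identical(dim(pred), dim(a1)) || !identical(dim(pred), dim(a2))) {
    stop("geometry mismatch")
  }
  pred <- as.logical(pred); a1 <- as.logical(a1); a2 <- as.logical(a2)
  tp <- sum(pred & (a1 | a2))
  fp <- sum(pred & !(a1 | a2))
  fn <- sum(!pred & a1 & a2)
  (2 * tp + eps) / (2 * tp + fp + fn + eps)
}

#' Dice between a binarized disagreement heatmap and actual disagreement
#'
#' Binarizes the predicted disagreement heatmap at 50% and scores it with
#' [dice()] against the actual inter-annotator disagreement (the XOR
#' region of the two annotations, as in [make_disagreement_targets()]).
#'
#' @param heatmap a [voxel_volume()] of disagreement probabilities, or a
#'   plain numeric array.
#' @param a1,a2 the two [label_volume()]s.
#' @param threshold binarization threshold (default 0.5).
#' @return Dice score in `[0, 1]`.
#' @export
disagreement_dice <- function(heatmap, a1, a2, threshold = 0.5) {
  h <- if (inherits(heatmap, "voxel_volume")) heatmap$data else heatmap
  if (!identical(dim(h), dim(a1$data))) stop("geometry mismatch")
  tg <- make_disagreement_targets(a1, a2)
  xor_mask <- tg$data[, , , dim(tg$data)[4]] > 0
  dice(h > threshold, xor_mask)
}

#' Per-organ evaluation report for one scan
#'
#' Computes, per organ, the Dice score, 50th and 95th percentile Hausdorff
#' surface distances, and center-of-mass displacement of a predicted
#' label volume against a reference annotation; with a second annotation,
#' also the union-reference Dice. Distances are reported in micrometers.
#' Organs with an empty predicted or reference mask get `NA` distances and
#' a `missing_reason`.
#'
#' @param pred predicted [label_volume()].
#' @param ref reference [label_volume()] (annotator 1).
#' @param ref2 optional second annotation.
#' @param heatmap optional disagreement heatmap; with `ref2`, adds a
#'   per-scan disagreement Dice as an attribute `disagreement_dice`.
#' @return Data frame with one row per organ: `organ, code, dice, hd50_um,
#'   hd95_um, com_um, union_dice, missing_reason`.
#' @export
evaluate_segmentation <- function(pred, ref, ref2 = NULL, heatmap = NULL) {
  stopifnot_same_geometry(pred, ref, "prediction and reference")
  ct <- ref$code_table
  rows <- lapply(seq_along(ct), function(k) {
    code <- unname(ct[k])
    pm <- pred$data == code
    rm_ <- ref$data == code
    hd <- hausdorff_percentile(pm, rm_, c(50, 95), ref$spacing)
    cm <- com_displacement(pm, rm_, ref$spacing)
    ud <- if (!is.null(ref2)) {
      union_reference_dice(pm, rm_, ref2$data == code)
    } else NA_real_
    data.frame(organ = names(ct)[k], code = code,
               dice = dice(pm, rm_),
               hd50_um = hd[1], hd95_um = hd[2], com_um = as.numeric(cm),
               union_dice = ud,
               missing_reason = attr(hd, "reason") %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(heatmap) && !is.null(ref2)) {
    attr(out, "disagreement_dice") <- disagreement_dice(heatmap, ref, ref2)
  }
  out
}
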