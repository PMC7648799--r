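#' Preprocessing configuration
#'
#' @param target_scale_um working resolution after resampling, micrometers
#'   per pixel; `NULL` keeps the native resolution. The pipeline default
#'   working resolution is 240 um/px and is robust over roughly
#'   120-1120 um/px.
#' @param rotation_deg augmentation: maximum in-plane rotation (degrees).
#' @param min_crop_area augmentation: minimum crop area as a fraction of
#'   the original image area.
#' @param normalize_scope `"slice"` (each coronal slice standardized on
#'   its own, the default) or `"volume"` (whole-scan statistics).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_scale_um = NULL, rotation_deg = 10,
                              min_crop_area = 0.8,
                              normalize_scope = c("slice", "volume")) {
  normalize_scope <- match.arg(normalize_scope)
  stopifnot(is.null(target_scale_um) || target_scale_um > 0,
            rotation_deg >= 0, min_crop_area > 0, min_crop_area <= 1)
  structure(list(target_scale_um = target_scale_um,
                 rotation_deg = rotation_deg,
                 min_crop_area = min_crop_area,
                 normalize_scope = normalize_scope),
            class = "preprocess_config")
}

new_slice_sample <- function(image, masks, source, scale, classes,
                             disagreement = FALSE) {
  structure(list(image = image, masks = masks, source = source,
                 scale = as.numeric(scale), classes = classes,
                 disagreement = disagreement),
            class = "slice_sample")
}

#' Slice a volume into coronal 2-d samples
#'
#' Produces one sample per index along the coronal axis (axis 1), in
#' order. When labels are given, each sample carries one-hot binary masks
#' per organ code (channels in code-table order).
#'
#' @param v a [voxel_volume()].
#' @param labels optional [label_volume()] with matching geometry.
#' @return List of `slice_sample` objects, each with `image` (matrix),
#'   `masks` (H x W x n_classes array, or `NULL`), `source`
#'   (mouse, scan, slice index; mouse/scan `NA` here) and `scale`
#'   (micrometers per pixel along the two slice axes).
#' @export
slice_coronal <- function(v, labels = NULL) {
  if (!is.null(labels)) stopifnot_same_geometry(v, labels, "image and labels")
  d <- dim(v$data)
  scale <- v$spacing[2:3]
  classes <- if (!is.null(labels)) names(labels$code_table) else NULL
  codes <- if (!is.null(labels)) unname(labels$code_table) else NULL
  out <- vector("list", d[1])
  for (i in seq_len(d[1])) {
    img <- v$data[i, , ]
    masks <- NULL
    if (!is.null(labels)) {
      lab <- labels$data[i, , ]
      masks <- array(0, c(d[2], d[3], length(codes)))
      for (k in seq_along(codes)) masks[, , k] <- (lab == codes[k]) * 1
    }
    out[[i]] <- new_slice_sample(img, masks, c(NA, NA, i), scale, classes)
  }
  out
}

#' Standardize image intensities
#'
#' Subtracts the mean and divides by the standard deviation, with a guard
#' `max(sd, 1e-6)` so constant images map to all zeros.
#'
#' @param image numeric matrix (or array).
#' @return Standardized array of the same shape.
#' @export
normalize_intensity <- function(image) {
  mu <- mean(image)
  s <- stats::sd(as.vector(image))
  if (!is.finite(s)) s <- 0
  (image - mu) / max(s, 1e-6)
}

#' Resample a slice sample to a target resolution
#'
#' The image is resampled with bilinear interpolation, masks with nearest
#' neighbour (so they stay binary); the new shape is
#' `round(old_shape * old_scale / target_scale)`.
#'
#' @param s a `slice_sample`.
#' @param target_scale target micrometers per pixel (applies to both slice
#'   axes).
#' @return The resampled `slice_sample`.
#' @export
resample_slice <- function(s, target_scale) {
  stopifnot(target_scale > 0)
  old_shape <- dim(s$image)
  new_shape <- as.integer(round(old_shape * s$scale / target_scale))
  if (any(new_shape < 8)) {
    stop("resampling to ", target_scale, " um/px gives shape ",
         paste(new_shape, collapse = "x"), "; need at least 8 px per axis")
  }
  if (identical(new_shape, as.integer(old_shape))) {
    s$scale <- rep(target_scale, 2)
    return(s)
  }
  img4 <- array(s$image, c(old_shape, 1L, 1L))
  s$image <- array(cpp_resize_bilinear(img4, new_shape[1], new_shape[2]),
                   new_shape)
  if (!is.null(s$masks)) {
    ii <- nn_index(old_shape[1], new_shape[1])
    jj <- nn_index(old_shape[2], new_shape[2])
    s$masks <- s$masks[ii, jj, , drop = FALSE]
  }
  s$scale <- rep(target_scale, 2)
  s
}

# nearest-neighbour source indices (1-based) for resizing n -> m, using the
# same half-pixel-center convention as the bilinear kernel
nn_index <- function(n, m) {
  pmin(pmax(round((seq_len(m) - 0.5) * n / m + 0.5), 1), n)
}

#' Keep only slices showing at least one organ voxel
#'
#' Training-time filter: keeps exactly the slices whose organ-mask union
#' is nonempty (the disagreement channel, if present, is not counted as an
#' organ). Order is preserved; at inference all slices of the volume are
#' presented and this filter is not applied.
#'
#' @param samples list of `slice_sample`s with masks.
#' @return The filtered list (possibly empty, with a warning).
#' @export
filter_training_slices <- function(samples) {
  keep <- vapply(samples, function(s) {
    if (is.null(s$masks)) stop("filter_training_slices needs masks")
    nc <- dim(s$masks)[3]
    organ_ch <- if (isTRUE(s$disagreement)) seq_len(nc - 1) else seq_len(nc)
    sum(s$masks[, , organ_ch]) > 0
  }, logical(1))
  if (!any(keep)) warning("no slice shows any organ voxel")
  samples[keep]
}

#' Randomly augment a training slice
#'
#' Applies one random in-plane rotation uniform in
#' `[-rotation_deg, +rotation_deg]` about the slice center (image
#' bilinear, masks nearest neighbour, out-of-bounds filled with 0, the
#' normalized background mean), followed by a random axis-aligned,
#' aspect-preserving crop with area uniform in `[min_crop_area, 1]` of the
#' original, resized back to the original shape. Deterministic given
#' `seed`.
#'
#' @param s a `slice_sample` with masks.
#' @param seed integer seed.
#' @param rotation_deg maximum rotation in degrees.
#' @param min_crop_area minimum crop area fraction.
#' @return The augmented `slice_sample` (same shape, masks still binary).
#' @export
augment <- function(s, seed, rotation_deg = 10, min_crop_area = 0.8) {
  if (is.null(s$masks)) stop("augment needs masks")
  with_seed(seed, {
    angle <- stats::runif(1, -rotation_deg, rotation_deg)
    area <- stats::runif(1, min_crop_area, 1)
    u_off <- stats::runif(2)
  })
  h <- dim(s$image)[1]; w <- dim(s$image)[2]
  if (angle != 0) {
    img3 <- array(s$image, c(h, w, 1L))
    s$image <- array(cpp_rotate2d(img3, angle, TRUE), c(h, w))
    s$masks <- array(cpp_rotate2d(s$masks, angle, FALSE), dim(s$masks))
  }
  if (area < 1) {
    side <- sqrt(area)
    ch <- max(8L, as.integer(round(h * side)))
    cw <- max(8L, as.integer(round(w * side)))
    oi <- as.integer(floor(u_off[1] * (h - ch + 1)))
    oj <- as.integer(floor(u_off[2] * (w - cw + 1)))
    img <- s$image[(oi + 1):(oi + ch), (oj + 1):(oj + cw)]
    s$image <- array(cpp_resize_bilinear(array(img, c(ch, cw, 1L, 1L)), h, w),
                     c(h, w))
    m <- s$masks[(oi + 1):(oi + ch), (oj + 1):(oj + cw), , drop = FALSE]
    s$masks <- m[nn_index(ch, h), nn_index(cw, w), , drop = FALSE]
  }
  s
}

# Zero-pad a (H, W) image at the bottom/right so both dims are multiples
# of m; returns the padded matrix and the original shape.
pad_to_multiple <- function(image, m) {
  d <- dim(image)
  target <- as.integer(ceiling(d / m) * m)
  if (identical(target, as.integer(d))) {
    return(list(image = image, orig = d))
  }
  out <- matrix(0, target[1], target[2])
  out[seq_len(d[1]), seq_len(d[2])] <- image
  list(image = out, orig = d)
}
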