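# Internal helpers: deterministic seed streams and small array utilities.

# Derive a 32-bit sub-seed from a base seed and a few small indices, so
# that every randomized component (phantom scan, annotator, augmentation
# step, weight init) has its own reproducible stream. All arithmetic stays
# well below 2^53 so the double-precision modulo is exact.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- (as.numeric(seed) %% 1000003) * 8191 + 1
  for (v in idx) h <- (h * 131071 + (as.numeric(v) %% 65521) * 257 + 97) %% 2147483629
  as.integer(h %% 2147483629) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# 6-connected binary shifts: TRUE where `mask` has a set voxel after a
# one-voxel shift along `axis` in direction `dir` (+1/-1).
shift_mask <- function(mask, axis, dir) {
  d <- dim(mask)
  out <- array(FALSE, d)
  idx_src <- idx_dst <- lapply(d, seq_len)
  if (dir > 0) {
    idx_dst[[axis]] <- 2:d[axis]
    idx_src[[axis]] <- 1:(d[axis] - 1)
  } else {
    idx_dst[[axis]] <- 1:(d[axis] - 1)
    idx_src[[axis]] <- 2:d[axis]
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    mask[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# One 6-connected morphological dilation / erosion step on a 3-d logical mask.
dilate6 <- function(mask) {
  out <- mask
  for (ax in 1:3) for (dir in c(-1, 1)) out <- out | shift_mask(mask, ax, dir)
  out
}

erode6 <- function(mask) {
  out <- mask
  for (ax in 1:3) for (dir in c(-1, 1)) out <- out & shift_mask(mask, ax, dir)
  out
}

# Voxels of `mask` with at least one face-adjacent background neighbour;
# voxels on the array border count as surface (out-of-grid is background).
surface_mask <- function(mask) {
  all_nb <- array(TRUE, dim(mask))
  for (ax in 1:3) for (dir in c(-1, 1)) all_nb <- all_nb & shift_mask(mask, ax, dir)
  mask & !all_nb
}

# 0-based voxel index coordinates (n x 3 matrix) of TRUE voxels.
mask_coords <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (is.null(dim(w))) w <- matrix(w, ncol = 3)
  w - 1
}
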