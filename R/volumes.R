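#' Volumetric intensity grid
#'
#' A `voxel_volume` is a 3-d scalar array together with its per-axis voxel
#' spacing in micrometers. The axis convention is fixed throughout the
#' package: axis 1 is dorsoventral (a "coronal slice" is one fixed index
#' along this axis), axis 2 and axis 3 span the coronal plane
#' (rostrocaudal and left-right). Voxel coordinates are 0-based array
#' indices; the physical position of a voxel center is `index * spacing`.
#'
#' @param data 3-d numeric array of intensities.
#' @param spacing numeric length-3, micrometers per voxel along each axis.
#' @return An object of class `voxel_volume` with elements `data` and
#'   `spacing`.
#' @export
voxel_volume <- function(data, spacing) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3-d array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive values (micrometers)")
  }
  if (any(!is.finite(data))) stop("volume contains non-finite values")
  structure(list(data = data, spacing = spacing), class = "voxel_volume")
}

#' Volumetric label grid
#'
#' A `label_volume` stores integer organ codes on the same grid convention
#' as [voxel_volume()]: 0 is background, positive codes are organ classes
#' named by `code_table`.
#'
#' @param data 3-d integer-valued array of label codes.
#' @param spacing micrometers per voxel along each axis.
#' @param code_table named integer vector mapping organ name -> code;
#'   all codes unique and > 0.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing, code_table) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3-d array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive values (micrometers)")
  }
  code_table <- validate_code_table(code_table)
  storage.mode(data) <- "integer"
  bad <- setdiff(unique(as.vector(data)), c(0L, unname(code_table)))
  if (length(bad) > 0) {
    stop("label volume contains codes not in the code table: ",
         paste(bad, collapse = ", "))
  }
  structure(list(data = data, spacing = spacing, code_table = code_table),
            class = "label_volume")
}

validate_code_table <- function(code_table) {
  nms <- names(code_table)
  code_table <- as.integer(code_table)
  if (length(code_table) == 0L) return(stats::setNames(code_table, character(0)))
  names(code_table) <- nms %||% paste0("class", code_table)
  if (any(code_table <= 0L)) stop("label codes must be > 0")
  if (anyDuplicated(code_table)) stop("label codes must be unique")
  if (anyDuplicated(names(code_table))) stop("organ names must be unique")
  code_table
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(x$spacing, collapse = "/"), " um\n", sep = "")
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(x$spacing, collapse = "/"), " um, ",
      length(x$code_table), " classes\n", sep = "")
  invisible(x)
}

#' Per-class probability maps
#'
#' Container for the network output reconstructed in 3-d: one channel per
#' prediction class, values in \[0, 1\] (independent per-class sigmoids;
#' channels need not sum to 1). The optional final channel is the
#' annotator-disagreement heatmap.
#'
#' @param data 4-d array `(d1, d2, d3, n_channels)` of probabilities.
#' @param spacing micrometers per voxel.
#' @param classes character vector of channel names in `code_table` order.
#' @param code_table named code table of the anatomical classes.
#' @param has_disagreement logical; is the last channel a disagreement
#'   heatmap rather than an anatomical class?
#' @return An object of class `prob_maps`.
#' @export
prob_maps <- function(data, spacing, classes, code_table,
                      has_disagreement = FALSE) {
  if (length(dim(data)) != 4L) stop("`data` must be a 4-d array")
  if (dim(data)[4] != length(classes)) stop("channel count != class count")
  if (min(data) < -1e-8 || max(data) > 1 + 1e-8) {
    stop("probabilities must lie in [0, 1]")
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 classes = classes,
                 code_table = validate_code_table(code_table),
                 has_disagreement = isTRUE(has_disagreement)),
            class = "prob_maps")
}

#' @export
print.prob_maps <- function(x, ...) {
  cat("<prob_maps> ", paste(dim(x$data)[1:3], collapse = " x "),
      " voxels, channels: ", paste(x$classes, collapse = ", "),
      if (x$has_disagreement) " (last = disagreement heatmap)", "\n", sep = "")
  invisible(x)
}

same_geometry <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-6))
}

stopifnot_same_geometry <- function(a, b, what = "volumes") {
  if (!same_geometry(a, b)) {
    stop("geometry mismatch between ", what, ": ",
         paste(dim(a$data), collapse = "x"), " / ",
         paste(a$spacing, collapse = ","), " um vs ",
         paste(dim(b$data), collapse = "x"), " / ",
         paste(b$spacing, collapse = ","), " um")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
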