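#' Volume of one organ in a label volume
#'
#' Voxel count times physical voxel volume.
#'
#' @param labels a [label_volume()].
#' @param organ organ code or name.
#' @return Volume in cubic millimeters.
#' @export
organ_volume <- function(labels, organ) {
  code <- resolve_organ(labels$code_table, organ)
  vox_mm3 <- prod(labels$spacing) / 1e9  # um^3 -> mm^3
  sum(labels$data == code) * vox_mm3
}

resolve_organ <- function(code_table, organ) {
  if (is.character(organ)) {
    if (!organ %in% names(code_table)) stop("unknown organ name: ", organ)
    return(unname(code_table[organ]))
  }
  organ <- as.integer(organ)
  if (!organ %in% code_table) stop("unknown organ code: ", organ)
  organ
}

#' Organ volume table of a cohort
#'
#' One row per (mouse, scan, annotator, organ) with the organ volume in
#' cubic millimeters; the long-format table consumed by the variability
#' decompositions.
#'
#' @param cohort a cohort (annotations), or supply `segmentations` to
#'   tabulate predicted label volumes instead.
#' @param segmentations optional named list `mouse -> list of scans ->`
#'   [label_volume()] replacing the annotations (annotator set to 0).
#' @return Data frame `mouse, scan, annotator, organ, code, volume_mm3`.
#' @export
cohort_volumes <- function(cohort, segmentations = NULL) {
  ct <- cohort$code_table
  rows <- list()
  add_row <- function(m, t, a, labels) {
    for (k in seq_along(ct)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        mouse = m, scan = t, annotator = a,
        organ = names(ct)[k], code = unname(ct[k]),
        volume_mm3 = organ_volume(labels, unname(ct[k])),
        stringsAsFactors = FALSE)
    }
  }
  for (s in cohort$subjects) {
    for (t in seq_along(s$scans)) {
      if (is.null(segmentations)) {
        for (a in seq_along(s$scans[[t]]$labels)) {
          add_row(s$id, t, a, s$scans[[t]]$labels[[a]])
        }
      } else {
        add_row(s$id, t, 0L, segmentations[[as.character(s$id)]][[t]])
      }
    }
  }
  do.call(rbind, rows)
}

# population standard deviation (divide by N under the root); with
# normalized = FALSE, the unnormalized root-sum-of-squares form
pop_sd <- function(x, normalized = TRUE) {
  ss <- sum((x - mean(x))^2)
  if (normalized) sqrt(ss / length(x)) else sqrt(ss)
}

#' Intersubject variability of organ volume
#'
#' Standard deviation, across mice, of the per-mouse scan-mean volume of
#' annotator 1. The relative form divides by the grand mean volume. By
#' default a population standard deviation (divide by the number of mice
#' under the root) is used; `normalized = FALSE` gives the unnormalized
#' root-sum-of-squares variant.
#'
#' @param tab a [cohort_volumes()] table.
#' @param organ organ name or code.
#' @param relative divide by the mean volume?
#' @param normalized population-sd normalization (see Details).
#' @return Nonnegative scalar (mm^3, or unitless fraction if relative).
#' @export
intersubject_variability <- function(tab, organ, relative = FALSE,
                                     normalized = TRUE) {
  x <- organ_rows(tab, organ)
  x <- x[x$annotator <= 1L, ]
  vbar <- tapply(x$volume_mm3, x$mouse, mean)
  if (length(vbar) < 2) stop("intersubject variability needs >= 2 mice")
  out <- pop_sd(as.numeric(vbar), normalized)
  if (relative) out <- out / mean(vbar)
  out
}

#' Interannotator variability of organ volume
#'
#' Mean over mice and scans of the per-scan standard deviation of organ
#' volume across annotators. Scans lacking a second annotation are
#' excluded with a warning.
#'
#' @inheritParams intersubject_variability
#' @return Nonnegative scalar.
#' @export
interannotator_variability <- function(tab, organ, relative = FALSE,
                                       normalized = TRUE) {
  x <- organ_rows(tab, organ)
  key <- interaction(x$mouse, x$scan, drop = TRUE)
  n_annot <- tapply(x$annotator, key, function(a) length(unique(a)))
  if (any(n_annot < 2)) {
    warning(sum(n_annot < 2), " scan(s) lack a second annotation; excluded")
  }
  keep <- key %in% names(n_annot)[n_annot >= 2]
  x <- x[keep, ]
  if (nrow(x) == 0) stop("no scan has >= 2 annotators")
  sds <- tapply(x$volume_mm3, droplevels(interaction(x$mouse, x$scan)),
                pop_sd, normalized = normalized)
  out <- mean(sds)
  if (relative) out <- out / mean_reference_volume(tab, organ)
  out
}

#' Intraannotator variability of organ volume
#'
#' Mean over mice of the standard deviation of annotator 1's volumes
#' across the repeat scans (timepoints) of each mouse.
#'
#' @inheritParams intersubject_variability
#' @return Nonnegative scalar.
#' @export
intraannotator_variability <- function(tab, organ, relative = FALSE,
                                       normalized = TRUE) {
  x <- organ_rows(tab, organ)
  x <- x[x$annotator <= 1L, ]
  n_scans <- tapply(x$scan, x$mouse, function(t) length(unique(t)))
  if (any(n_scans < 2)) stop("intraannotator variability needs >= 2 scans per mouse")
  sds <- tapply(x$volume_mm3, x$mouse, pop_sd, normalized = normalized)
  out <- mean(sds)
  if (relative) out <- out / mean_reference_volume(tab, organ)
  out
}

organ_rows <- function(tab, organ) {
  x <- if (is.character(organ)) tab[tab$organ == organ, ] else
    tab[tab$code == as.integer(organ), ]
  if (nrow(x) == 0) stop("organ not present in the volume table")
  x
}

# grand mean reference volume of an organ: mean over mice of the
# annotator-1 scan-mean volume
mean_reference_volume <- function(tab, organ) {
  x <- organ_rows(tab, organ)
  x <- x[x$annotator <= 1L, ]
  mean(tapply(x$volume_mm3, x$mouse, mean))
}

#' Per-organ variability report
#'
#' The three volumetry variability decompositions for every organ of a
#' cohort: intersubject (across mice), interannotator (across annotators
#' of one scan) and intraannotator (across repeat scans of one mouse),
#' absolute (mm^3) and relative to the mean organ volume.
#'
#' @param tab a [cohort_volumes()] table with two annotators.
#' @param normalized population-sd normalization.
#' @return Data frame, one row per organ: `organ, code, mean_volume_mm3,
#'   intersubject_mm3, interannotator_mm3, intraannotator_mm3,
#'   intersubject_rel, interannotator_rel, intraannotator_rel`.
#' @export
variability_report <- function(tab, normalized = TRUE) {
  organs <- unique(tab[, c("organ", "code")])
  rows <- lapply(seq_len(nrow(organs)), function(i) {
    o <- organs$organ[i]
    data.frame(
      organ = o, code = organs$code[i],
      mean_volume_mm3 = mean_reference_volume(tab, o),
      intersubject_mm3 = intersubject_variability(tab, o, FALSE, normalized),
      interannotator_mm3 = interannotator_variability(tab, o, FALSE,
                                                      normalized),
      intraannotator_mm3 = intraannotator_variability(tab, o, FALSE,
                                                      normalized),
      intersubject_rel = intersubject_variability(tab, o, TRUE, normalized),
      interannotator_rel = interannotator_variability(tab, o, TRUE,
                                                      normalized),
      intraannotator_rel = intraannotator_variability(tab, o, TRUE,
                                                      normalized),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Allocate metastasis points to organs of a segmentation
#'
#' Each point receives the label code of the voxel containing it (floor
#' of its 0-based coordinates; 0 = unallocated/background).
#'
#' @param points data frame with columns `x, y, z` (0-based voxel
#'   coordinates, fractions allowed) and optionally a truth column.
#' @param seg a [label_volume()].
#' @return `points` with an added `allocated` column.
#' @export
allocate_metastases <- function(points, seg) {
  d <- dim(seg$data)
  i <- floor(points$x); j <- floor(points$y); k <- floor(points$z)
  if (any(i < 0 | i >= d[1] | j < 0 | j >= d[2] | k < 0 | k >= d[3])) {
    bad <- which(i < 0 | i >= d[1] | j < 0 | j >= d[2] | k < 0 | k >= d[3])[1]
    stop("point ", bad, " lies outside the volume grid")
  }
  points$allocated <- seg$data[cbind(i + 1, j + 1, k + 1)]
  points
}

#' Metastasis count and relative count error for one organ
#'
#' @param alloc an [allocate_metastases()] result with a truth column.
#' @param organ organ code.
#' @param truth_col name of the column holding the true organ code.
#' @return List with `count` (points allocated to the organ),
#'   `true_count`, and `relative_error` = `|count - true| / true` (`NA`
#'   with reason when the true count is 0).
#' @export
metastasis_count_error <- function(alloc, organ, truth_col = "organ") {
  if (!truth_col %in% names(alloc)) stop("missing truth column: ", truth_col)
  organ <- as.integer(organ)
  count <- sum(alloc$allocated == organ)
  true_count <- sum(alloc[[truth_col]] == organ)
  rel <- if (true_count == 0) {
    structure(NA_real_, reason = "true count is zero")
  } else {
    abs(count - true_count) / true_count
  }
  list(count = count, true_count = true_count, relative_error = rel)
}

#' Mean-intensity projection along the dorsoventral axis
#'
#' Small visualization utility: the mean of the volume over axis 1.
#'
#' @param v a [voxel_volume()].
#' @return A matrix (axis 2 x axis 3).
#' @export
mean_intensity_projection <- function(v) {
  apply(v$data, c(2, 3), mean)
}
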