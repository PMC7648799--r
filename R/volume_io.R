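#' Read a volume from a NIfTI file
#'
#' Loads a 3-d NIfTI image as a [voxel_volume()] (or [label_volume()] when
#' a code table is supplied). Voxel spacing is taken from the file header
#' (NIfTI stores millimeters) and converted to micrometers. Intensities
#' are loaded as doubles regardless of on-disk dtype; non-finite values
#' are rejected.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param code_table if given, the image is interpreted as integer labels
#'   and returned as a [label_volume()].
#' @return A [voxel_volume()] or [label_volume()].
#' @export
read_volume <- function(path, code_table = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop("expected a 3-d image, got ", length(d), "-d: ", path)
  }
  spacing_um <- RNifti::pixdim(img) * 1000
  data <- array(as.numeric(img), d)
  if (is.null(code_table)) {
    voxel_volume(data, spacing_um)
  } else {
    label_volume(array(as.integer(round(data)), d), spacing_um, code_table)
  }
}

#' Write a volume to a NIfTI file
#'
#' Intensity volumes are stored as 32-bit floats, label volumes as 32-bit
#' integers (lossless for codes). Spacing is written to the header in
#' millimeters.
#'
#' @param v a [voxel_volume()] or [label_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  is_label <- inherits(v, "label_volume")
  if (!is_label && !inherits(v, "voxel_volume")) {
    stop("`v` must be a voxel_volume or label_volume")
  }
  img <- RNifti::asNifti(v$data)
  RNifti::`pixdim<-`(img, v$spacing / 1000) -> img
  RNifti::writeNifti(img, path,
                     datatype = if (is_label) "int32" else "float")
  invisible(path)
}

#' Index a cohort from a manifest file
#'
#' Reads a manifest CSV with columns `mouse, scan, annotator, image_path,
#' label_path` and assembles the cohort structure used by the training and
#' evaluation stages. The image of a scan is read once; each annotator row
#' contributes one label volume. Geometry agreement between every label
#' volume and its image is validated.
#'
#' @param manifest path to the manifest CSV. Relative paths are resolved
#'   against the manifest's directory.
#' @param code_table named integer vector organ name -> code.
#' @param spacing_tol relative tolerance for spacing agreement.
#' @return A `cohort` object (see [build_cohort()]); scans indexed by a
#'   cohort-wide code table. Subjects for which only one annotator exists
#'   simply carry one label volume.
#' @export
index_cohort <- function(manifest, code_table, spacing_tol = 1e-4) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("mouse", "scan", "annotator", "image_path", "label_path")
  miss <- setdiff(need, names(man))
  if (length(miss) > 0) {
    stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(man[, c("mouse", "scan", "annotator")])) {
    dup <- man[duplicated(man[, c("mouse", "scan", "annotator")]), ]
    stop("duplicate (mouse, scan, annotator) rows, e.g. mouse ",
         dup$mouse[1], " scan ", dup$scan[1], " annotator ", dup$annotator[1])
  }
  base <- dirname(normalizePath(manifest))
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  man$image_path <- resolve(man$image_path)
  man$label_path <- resolve(man$label_path)

  code_table <- validate_code_table(code_table)
  subjects <- list()
  for (m in sort(unique(man$mouse))) {
    rows_m <- man[man$mouse == m, ]
    scans <- list()
    for (t in sort(unique(rows_m$scan))) {
      rows_t <- rows_m[rows_m$scan == t, ]
      rows_t <- rows_t[order(rows_t$annotator), ]
      img <- read_volume(rows_t$image_path[1])
      labs <- list()
      for (i in seq_len(nrow(rows_t))) {
        lab <- read_volume(rows_t$label_path[i], code_table = code_table)
        if (!identical(dim(lab$data), dim(img$data)) ||
            max(abs(lab$spacing - img$spacing) / img$spacing) > spacing_tol) {
          stop("geometry mismatch for mouse ", m, " scan ", t,
               " annotator ", rows_t$annotator[i], ": image ",
               paste(dim(img$data), collapse = "x"), ", labels ",
               paste(dim(lab$data), collapse = "x"))
        }
        labs[[length(labs) + 1L]] <- lab
      }
      scans[[length(scans) + 1L]] <- list(image = img, labels = labs,
                                          metastases = NULL)
    }
    subjects[[length(subjects) + 1L]] <- list(id = m, scans = scans)
  }
  structure(list(subjects = subjects, code_table = code_table,
                 spacing = subjects[[1]]$scans[[1]]$image$spacing,
                 spec = NULL),
            class = "cohort")
}

#' Write a cohort to disk as NIfTI files plus manifest
#'
#' Writes `mouse{m}_scan{t}.nii.gz` volumes and
#' `mouse{m}_scan{t}_annot{a}.nii.gz` labels, a cohort manifest CSV
#' (`mouse, scan, annotator, image_path, label_path`) and, if present, a
#' metastasis table CSV (`mouse, scan, x, y, z, organ`; 0-based voxel
#' coordinates).
#'
#' @param cohort a cohort.
#' @param dir output directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  mets <- list()
  for (s in cohort$subjects) {
    for (t in seq_along(s$scans)) {
      sc <- s$scans[[t]]
      img_name <- sprintf("mouse%d_scan%d.nii.gz", s$id, t)
      write_volume(sc$image, file.path(dir, img_name))
      for (a in seq_along(sc$labels)) {
        lab_name <- sprintf("mouse%d_scan%d_annot%d.nii.gz", s$id, t, a)
        write_volume(sc$labels[[a]], file.path(dir, lab_name))
        rows[[length(rows) + 1L]] <- data.frame(
          mouse = s$id, scan = t, annotator = a,
          image_path = img_name, label_path = lab_name)
      }
      if (!is.null(sc$metastases) && nrow(sc$metastases) > 0) {
        mets[[length(mets) + 1L]] <-
          cbind(data.frame(mouse = s$id, scan = t), sc$metastases)
      }
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  codes <- data.frame(organ = names(cohort$code_table),
                      code = unname(cohort$code_table))
  utils::write.csv(codes, file.path(dir, "code_table.csv"), row.names = FALSE)
  if (length(mets) > 0) {
    utils::write.csv(do.call(rbind, mets), file.path(dir, "metastases.csv"),
                     row.names = FALSE)
  }
  invisible(manifest)
}
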