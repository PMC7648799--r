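#' Describe one ellipsoidal phantom organ
#'
#' Phantom organs are (optionally per-mouse rescaled) ellipsoids: the
#' simplest shape family whose voxelized volume and surface can be checked
#' against brute-force enumeration in tests.
#'
#' @param name organ name (unique within a spec).
#' @param code positive integer label code (unique within a spec).
#' @param center reference-pose center, 0-based voxel coordinates (length 3).
#' @param semiaxes ellipsoid semi-axes in voxels (length 3).
#' @param intensity mean image intensity inside the organ.
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   inside the organ.
#' @return A `phantom_organ` list.
#' @export
phantom_organ <- function(name, code, center, semiaxes, intensity,
                          noise_sd = 0.15) {
  stopifnot(length(center) == 3, length(semiaxes) == 3, all(semiaxes > 0),
            code > 0)
  structure(list(name = name, code = as.integer(code),
                 center = as.numeric(center), semiaxes = as.numeric(semiaxes),
                 intensity = as.numeric(intensity),
                 noise_sd = as.numeric(noise_sd)),
            class = "phantom_organ")
}

default_phantom_organs <- function() {
  list(
    phantom_organ("heart",  1L, c(32, 32, 20), c(10, 9, 8),  1.00),
    phantom_organ("liver",  2L, c(32, 30, 44), c(13, 13, 12), 0.70),
    phantom_organ("kidney", 3L, c(32, 42, 70), c(7, 6, 8),   0.85),
    # spleen analog: mean intensity close to background, so its contrast
    # is comparable to the noise floor
    phantom_organ("spleen", 4L, c(32, 18, 70), c(8, 5, 7),   0.12)
  )
}

#' Specify a synthetic phantom cohort
#'
#' Defines the study conditions for a cohort of synthetic "mice", each
#' scanned at several "timepoints". Organs of one mouse keep identical
#' shape parameters across its scans (per-mouse size factor), differing
#' only by a rigid posture jitter (shift plus in-plane rotation), so true
#' organ volumes are invariant across scans of a mouse. A second annotator
#' is emulated by a systematic per-organ boundary offset plus random
#' boundary flips; annotator 1 is the unperturbed truth by convention.
#'
#' @param grid_shape voxels per axis (length 3).
#' @param voxel_spacing micrometers per voxel per axis.
#' @param organs list of [phantom_organ()].
#' @param background_intensity mean background intensity.
#' @param background_noise_sd sd of background Gaussian noise.
#' @param n_mice number of subjects.
#' @param scans_per_mouse scans (timepoints) per subject.
#' @param subject_scale_sd sd of the per-mouse organ size factor
#'   (multiplies all semi-axes; 0 = identical mice).
#' @param jitter_shift_vx maximum rigid shift between scans of one mouse,
#'   voxels per axis (uniform in \[-max, max\]).
#' @param jitter_rot_deg maximum in-plane (coronal) rotation, degrees.
#' @param annotator2_bias named numeric vector (organ name -> signed
#'   boundary offset in voxels) or a single number for all organs;
#'   positive dilates, negative erodes.
#' @param annotator_noise_sd probability in \[0, 1\] that a boundary voxel
#'   of annotator 2 is flipped (random boundary perturbation scale).
#' @param metastases_per_organ simulated metastasis points sampled inside
#'   each organ, per scan.
#' @param background_metastases additional points sampled in background.
#' @param seed integer master seed; the same spec and seed give a
#'   bit-identical cohort.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 96),
                         voxel_spacing = c(240, 240, 240),
                         organs = default_phantom_organs(),
                         background_intensity = 0,
                         background_noise_sd = 0.15,
                         n_mice = 6L,
                         scans_per_mouse = 2L,
                         subject_scale_sd = 0.05,
                         jitter_shift_vx = 3,
                         jitter_rot_deg = 5,
                         annotator2_bias = c(spleen = 2),
                         annotator_noise_sd = 0.1,
                         metastases_per_organ = 4L,
                         background_metastases = 3L,
                         seed = 1L) {
  codes <- vapply(organs, function(o) o$code, integer(1))
  nms <- vapply(organs, function(o) o$name, character(1))
  if (anyDuplicated(codes) || any(codes <= 0L)) {
    stop("organ label codes must be unique and > 0")
  }
  if (anyDuplicated(nms)) stop("organ names must be unique")
  stopifnot(n_mice >= 1, scans_per_mouse >= 1, annotator_noise_sd >= 0,
            length(grid_shape) == 3, all(grid_shape >= 8))
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 organs = organs,
                 background_intensity = background_intensity,
                 background_noise_sd = background_noise_sd,
                 n_mice = as.integer(n_mice),
                 scans_per_mouse = as.integer(scans_per_mouse),
                 subject_scale_sd = subject_scale_sd,
                 jitter_shift_vx = jitter_shift_vx,
                 jitter_rot_deg = jitter_rot_deg,
                 annotator2_bias = annotator2_bias,
                 annotator_noise_sd = annotator_noise_sd,
                 metastases_per_organ = as.integer(metastases_per_organ),
                 background_metastases = as.integer(background_metastases),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Code table of a phantom spec
#' @param spec a [phantom_spec()].
#' @return Named integer vector organ name -> code.
#' @export
spec_code_table <- function(spec) {
  codes <- vapply(spec$organs, function(o) o$code, integer(1))
  names(codes) <- vapply(spec$organs, function(o) o$name, character(1))
  codes
}

# Per-mouse deterministic parameters: organ size factor.
mouse_params <- function(spec, mouse) {
  with_seed(derive_seed(spec$seed, 101, mouse), {
    scale <- max(0.5, 1 + stats::rnorm(1, 0, spec$subject_scale_sd))
  })
  list(scale = scale)
}

# Per-scan deterministic rigid posture: shift (3 axes) and in-plane angle.
scan_pose <- function(spec, mouse, scan) {
  with_seed(derive_seed(spec$seed, 202, mouse, scan), {
    shift <- stats::runif(3, -spec$jitter_shift_vx, spec$jitter_shift_vx)
    theta <- stats::runif(1, -spec$jitter_rot_deg, spec$jitter_rot_deg)
  })
  list(shift = shift, theta_deg = theta)
}

# Voxel-center coordinate columns (0-based) for a grid, as three n-vectors.
grid_coords <- function(d) {
  list(a1 = rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
       a2 = rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
       a3 = rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
}

# Inside-test of a posed ellipsoid, evaluated on pre-transformed body-frame
# coordinates u1, u2, u3 (same frame as organ reference centers).
ellipsoid_inside <- function(u1, u2, u3, center, semiaxes) {
  ((u1 - center[1]) / semiaxes[1])^2 +
    ((u2 - center[2]) / semiaxes[2])^2 +
    ((u3 - center[3]) / semiaxes[3])^2 <= 1
}

#' Generate one phantom scan
#'
#' Renders the intensity volume (organ means plus Gaussian noise) and the
#' ground-truth label volume for one (mouse, scan) pair. Deterministic
#' given `(spec$seed, mouse, scan)`.
#'
#' @param spec a [phantom_spec()].
#' @param mouse subject index in `1..n_mice`.
#' @param scan timepoint index in `1..scans_per_mouse`.
#' @return List with elements `volume` ([voxel_volume()]) and `labels`
#'   ([label_volume()]).
#' @export
generate_phantom <- function(spec, mouse, scan) {
  stopifnot(mouse >= 1, mouse <= spec$n_mice,
            scan >= 1, scan <= spec$scans_per_mouse)
  d <- spec$grid_shape
  mp <- mouse_params(spec, mouse)
  pose <- scan_pose(spec, mouse, scan)
  th <- pose$theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  g <- (d - 1) / 2

  # body-frame coordinates: invert the rigid pose (shift then rotation
  # about the grid center in the coronal plane, axes 2-3)
  co <- grid_coords(d)
  v1 <- co$a1 - pose$shift[1]
  v2 <- co$a2 - pose$shift[2] - g[2]
  v3 <- co$a3 - pose$shift[3] - g[3]
  u1 <- v1
  u2 <- ct * v2 + st * v3 + g[2]
  u3 <- -st * v2 + ct * v3 + g[3]

  labels <- integer(prod(d))
  organ_masks <- vector("list", length(spec$organs))
  for (k in seq_along(spec$organs)) {
    org <- spec$organs[[k]]
    ax <- org$semiaxes * mp$scale
    # fit check: bounding extent of the posed ellipsoid must stay in-grid
    cpos <- c(org$center[1] + pose$shift[1],
              ct * (org$center[2] - g[2]) - st * (org$center[3] - g[3]) +
                g[2] + pose$shift[2],
              st * (org$center[2] - g[2]) + ct * (org$center[3] - g[3]) +
                g[3] + pose$shift[3])
    ext <- c(ax[1],
             sqrt((ct * ax[2])^2 + (st * ax[3])^2),
             sqrt((st * ax[2])^2 + (ct * ax[3])^2))
    if (any(cpos - ext < 0) || any(cpos + ext > d - 1)) {
      stop("organ '", org$name, "' escapes the grid after posture jitter ",
           "(mouse ", mouse, ", scan ", scan, ")")
    }
    inside <- ellipsoid_inside(u1, u2, u3, org$center, ax)
    inside <- inside & labels == 0L  # first-painted organ keeps the voxel
    labels[inside] <- org$code
    organ_masks[[k]] <- inside
  }

  intens <- with_seed(derive_seed(spec$seed, 303, mouse, scan), {
    x <- spec$background_intensity +
      stats::rnorm(prod(d), 0, spec$background_noise_sd)
    for (k in seq_along(spec$organs)) {
      org <- spec$organs[[k]]
      n_in <- sum(organ_masks[[k]])
      if (n_in > 0) {
        x[organ_masks[[k]]] <- org$intensity +
          stats::rnorm(n_in, 0, org$noise_sd)
      }
    }
    x
  })

  list(volume = voxel_volume(array(intens, d), spec$voxel_spacing),
       labels = label_volume(array(labels, d), spec$voxel_spacing,
                             spec_code_table(spec)))
}

#' Simulate a second annotator
#'
#' Perturbs a ground-truth label volume the way an independent human
#' annotator's mask differs from the truth: a systematic per-organ
#' boundary offset (morphological dilation for positive, erosion for
#' negative values, 6-connectivity, one voxel per step) plus independent
#' random flips of boundary voxels. Dilation only claims background
#' voxels, so organ labels never overwrite each other.
#'
#' @param truth a [label_volume()].
#' @param bias_vx single number, or numeric vector named by organ name (or
#'   by code as character), of signed boundary offsets in voxels.
#' @param noise_sd probability in \[0, 1\] of flipping a boundary voxel.
#' @param seed integer seed; same seed gives identical output.
#' @return A [label_volume()] with the same geometry and code table.
#' @export
simulate_annotator <- function(truth, bias_vx = 0, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(truth, "label_volume"), noise_sd >= 0)
  ct <- truth$code_table
  bias_for <- function(name, code) {
    if (length(bias_vx) == 1L && is.null(names(bias_vx))) return(bias_vx[[1]])
    if (!is.null(names(bias_vx))) {
      if (name %in% names(bias_vx)) return(bias_vx[[name]])
      if (as.character(code) %in% names(bias_vx)) {
        return(bias_vx[[as.character(code)]])
      }
      return(0)
    }
    0
  }
  out <- array(0L, dim(truth$data))
  claimed <- array(FALSE, dim(truth$data))
  p <- min(1, noise_sd)
  with_seed(seed, {
    for (k in order(unname(ct))) {
      code <- unname(ct[k]); name <- names(ct)[k]
      m <- truth$data == code
      b <- round(bias_for(name, code))
      if (b > 0) {
        for (i in seq_len(b)) {
          grown <- dilate6(m)
          m <- m | (grown & truth$data == 0L & !claimed)
        }
      } else if (b < 0) {
        for (i in seq_len(-b)) m <- erode6(m)
      }
      if (p > 0 && any(m)) {
        inner <- surface_mask(m)
        outer <- dilate6(m) & !m & truth$data == 0L & !claimed
        flips_in <- which(inner)[stats::runif(sum(inner)) < p]
        flips_out <- which(outer)[stats::runif(sum(outer)) < p]
        m[flips_in] <- FALSE
        m[flips_out] <- TRUE
      }
      out[m] <- code
      claimed <- claimed | m
    }
  })
  label_volume(out, truth$spacing, ct)
}

# Sample metastasis points for one scan: points at the centers of voxels
# drawn uniformly inside each organ (truth labels) plus background points.
sample_metastases <- function(spec, labels, mouse, scan) {
  ct <- spec_code_table(spec)
  with_seed(derive_seed(spec$seed, 404, mouse, scan), {
    rows <- list()
    pick <- function(mask, n, code) {
      idx <- which(mask)
      if (length(idx) == 0 || n == 0) return(NULL)
      sel <- idx[sample.int(length(idx), min(n, length(idx)))]
      co <- arrayInd(sel, dim(labels$data)) - 1
      data.frame(x = co[, 1], y = co[, 2], z = co[, 3], organ = code)
    }
    for (code in unname(ct)) {
      rows[[length(rows) + 1L]] <-
        pick(labels$data == code, spec$metastases_per_organ, code)
    }
    rows[[length(rows) + 1L]] <-
      pick(labels$data == 0L, spec$background_metastases, 0L)
    do.call(rbind, rows)
  })
}

#' Build a synthetic cohort
#'
#' Generates all `n_mice * scans_per_mouse` scans of a phantom spec, with
#' annotator 1 equal to the ground truth and annotator 2 simulated by
#' [simulate_annotator()], plus per-scan simulated metastasis points.
#'
#' @param spec a [phantom_spec()].
#' @param two_annotators logical; generate the second annotator's labels?
#' @return A `cohort` object: `subjects[[m]]$scans[[t]]` holds `image`,
#'   `labels` (list, one [label_volume()] per annotator) and `metastases`
#'   (data frame x, y, z, organ in 0-based voxel coordinates); plus
#'   `code_table` and `spacing` metadata.
#' @export
build_cohort <- function(spec, two_annotators = TRUE) {
  subjects <- vector("list", spec$n_mice)
  for (m in seq_len(spec$n_mice)) {
    scans <- vector("list", spec$scans_per_mouse)
    for (t in seq_len(spec$scans_per_mouse)) {
      ph <- generate_phantom(spec, m, t)
      labs <- list(ph$labels)
      if (two_annotators) {
        labs[[2]] <- simulate_annotator(
          ph$labels, spec$annotator2_bias, spec$annotator_noise_sd,
          seed = derive_seed(spec$seed, 505, m, t))
      }
      scans[[t]] <- list(image = ph$volume, labels = labs,
                         metastases = sample_metastases(spec, ph$labels, m, t))
    }
    subjects[[m]] <- list(id = m, scans = scans)
  }
  structure(list(subjects = subjects,
                 code_table = spec_code_table(spec),
                 spacing = spec$voxel_spacing,
                 spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n_scans <- sum(vapply(x$subjects, function(s) length(s$scans), integer(1)))
  cat("<cohort> ", length(x$subjects), " subjects, ", n_scans, " scans, ",
      length(x$code_table), " organ classes\n", sep = "")
  invisible(x)
}

#' Number of annotators available for every scan of a cohort
#' @param cohort a cohort.
#' @return Integer, the minimum annotator count across scans.
#' @export
cohort_annotators <- function(cohort) {
  min(vapply(cohort$subjects, function(s) {
    min(vapply(s$scans, function(sc) length(sc$labels), integer(1)))
  }, integer(1)))
}
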