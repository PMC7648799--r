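test_that("organ volume is voxel count times physical voxel volume", {
  ct <- c(thing = 1L)
  lab <- array(0L, c(20, 20, 20))
  lab[sample(8000, 1000)] <- 1L
  l <- label_volume(lab, c(240, 240, 240), ct)
  # 1000 voxels at 240 um isotropic: 1000 * 0.013824 mm^3
  expect_equal(organ_volume(l, 1L), 13.824)
  expect_equal(organ_volume(l, "thing"), 13.824)
  l0 <- label_volume(array(0L, c(4, 4, 4)), c(240, 240, 240), ct)
  expect_equal(organ_volume(l0, 1L), 0)
  expect_error(organ_volume(l, 9L), "unknown")
})

test_that("voxelized ellipsoid volume approaches the analytic form", {
  spec <- phantom_spec(
    grid_shape = c(40, 40, 40), organs = list(
      phantom_organ("e", 1L, c(19, 19, 19), c(10, 8, 6), 1)),
    n_mice = 1, scans_per_mouse = 1, subject_scale_sd = 0,
    jitter_shift_vx = 0, jitter_rot_deg = 0, annotator2_bias = 0, seed = 1)
  ph <- generate_phantom(spec, 1, 1)
  vox_mm3 <- 0.24^3
  analytic <- 4 / 3 * pi * 10 * 8 * 6 * vox_mm3
  got <- organ_volume(ph$labels, 1L)
  # discretization error of a ~2000-voxel ellipsoid stays within a few %
  expect_lt(abs(got - analytic) / analytic, 0.05)
})

mk_tab <- function(rows) {
  do.call(rbind, lapply(rows, function(r) {
    data.frame(mouse = r[1], scan = r[2], annotator = r[3], organ = "o",
               code = 1L, volume_mm3 = r[4])
  }))
}

test_that("variability measures reproduce two-point hand computations", {
  # intersubject: mice with scan-means 10 and 14, population sd = 2
  tab <- mk_tab(list(c(1, 1, 1, 9), c(1, 2, 1, 11),
                     c(2, 1, 1, 13), c(2, 2, 1, 15)))
  expect_equal(intersubject_variability(tab, 1L), 2)
  expect_equal(intersubject_variability(tab, 1L, relative = TRUE), 2 / 12)
  # unnormalized (as-printed) form: sqrt(sum of squares) = sqrt(8)
  expect_equal(intersubject_variability(tab, 1L, normalized = FALSE),
               sqrt(8))

  # interannotator: single scan with volumes 8 and 12, per-scan sd = 2
  tab2 <- mk_tab(list(c(1, 1, 1, 8), c(1, 1, 2, 12)))
  expect_equal(interannotator_variability(tab2, 1L), 2)
  # permuting annotator labels changes nothing
  tab2p <- mk_tab(list(c(1, 1, 2, 8), c(1, 1, 1, 12)))
  expect_equal(interannotator_variability(tab2p, 1L), 2)

  # intraannotator: one mouse, volumes 9 and 11 across two scans, sd = 1
  tab3 <- mk_tab(list(c(1, 1, 1, 9), c(1, 2, 1, 11)))
  expect_equal(intraannotator_variability(tab3, 1L), 1)
})

test_that("variability invariances: translation, scaling, zero spread", {
  tab <- mk_tab(list(c(1, 1, 1, 9), c(1, 2, 1, 11),
                     c(2, 1, 1, 13), c(2, 2, 1, 15)))
  shifted <- tab; shifted$volume_mm3 <- shifted$volume_mm3 + 5
  expect_equal(intersubject_variability(shifted, 1L),
               intersubject_variability(tab, 1L))
  scaled <- tab; scaled$volume_mm3 <- scaled$volume_mm3 * 3
  expect_equal(intersubject_variability(scaled, 1L),
               3 * intersubject_variability(tab, 1L))
  expect_equal(intersubject_variability(scaled, 1L, relative = TRUE),
               intersubject_variability(tab, 1L, relative = TRUE))
  expect_equal(intraannotator_variability(scaled, 1L, relative = TRUE),
               intraannotator_variability(tab, 1L, relative = TRUE))
  # identical volumes everywhere: all three measures are 0
  flat <- mk_tab(list(c(1, 1, 1, 7), c(1, 1, 2, 7), c(1, 2, 1, 7),
                      c(1, 2, 2, 7), c(2, 1, 1, 7), c(2, 1, 2, 7),
                      c(2, 2, 1, 7), c(2, 2, 2, 7)))
  expect_equal(intersubject_variability(flat, 1L), 0)
  expect_equal(interannotator_variability(flat, 1L), 0)
  expect_equal(intraannotator_variability(flat, 1L), 0)
})

test_that("cohort volume table covers all indices and feeds the report", {
  cohort <- tiny_cohort()
  tab <- cohort_volumes(cohort)
  expect_equal(nrow(tab), 3 * 2 * 2 * 2)  # mice x scans x annotators x organs
  expect_true(all(tab$volume_mm3 > 0))
  rep <- variability_report(tab)
  expect_equal(rep$organ, c("blob", "pill"))
  expect_true(all(rep$intersubject_mm3 >= 0))
  # annotator-2 bias is on "blob" only: its interannotator variability
  # must exceed intraannotator; and exceed the unbiased organ's
  blob <- rep[rep$organ == "blob", ]
  expect_gt(blob$interannotator_rel, blob$intraannotator_rel)
})

test_that("a bias- and noise-free rigid cohort has near-zero variability", {
  spec <- tiny_spec(annotator2_bias = 0, annotator_noise_sd = 0,
                    jitter_shift_vx = 1, jitter_rot_deg = 2)
  spec$subject_scale_sd <- 0
  cohort <- build_cohort(spec)
  tab <- cohort_volumes(cohort)
  rep <- variability_report(tab)
  expect_equal(rep$interannotator_rel, c(0, 0))
  # intra/intersubject limited to rigid-resampling discretization
  expect_true(all(rep$intraannotator_rel < 0.05))
  expect_true(all(rep$intersubject_rel < 0.05))
})

test_that("metastasis allocation matches direct voxel lookup", {
  cohort <- tiny_cohort()
  sc <- cohort$subjects[[2]]$scans[[1]]
  alloc <- allocate_metastases(sc$metastases, sc$labels[[1]])
  for (r in seq_len(nrow(alloc))) {
    expect_equal(alloc$allocated[r],
                 sc$labels[[1]]$data[floor(alloc$x[r]) + 1,
                                     floor(alloc$y[r]) + 1,
                                     floor(alloc$z[r]) + 1])
  }
  # with the truth segmentation, allocation is perfect
  expect_equal(alloc$allocated, alloc$organ)
  err <- metastasis_count_error(alloc, 1L)
  expect_equal(err$relative_error, 0)
  # fractional coordinates use the containing voxel (floor)
  pts <- data.frame(x = alloc$x + 0.4, y = alloc$y + 0.4, z = alloc$z + 0.4,
                    organ = alloc$organ)
  expect_equal(allocate_metastases(pts, sc$labels[[1]])$allocated,
               alloc$allocated)
  # out-of-grid points error
  expect_error(allocate_metastases(data.frame(x = -1, y = 0, z = 0),
                                   sc$labels[[1]]), "outside")
})

test_that("count error arithmetic and dilation monotonicity", {
  alloc <- data.frame(organ = rep(1L, 10),
                      allocated = c(rep(1L, 9), 0L))
  err <- metastasis_count_error(alloc, 1L)
  expect_equal(err$count, 9)
  expect_equal(err$true_count, 10)
  expect_equal(err$relative_error, 0.1)  # 9 allocated vs 10 true
  none <- metastasis_count_error(alloc, 5L)
  expect_true(is.na(none$relative_error))
  expect_match(attr(none$relative_error, "reason"), "zero")

  # counts from a dilated segmentation can only grow for interior points
  sc <- tiny_cohort()$subjects[[1]]$scans[[1]]
  seg_dil <- simulate_annotator(sc$labels[[1]], 2, 0, seed = 1)
  a_true <- allocate_metastases(sc$metastases, sc$labels[[1]])
  a_dil <- allocate_metastases(sc$metastases, seg_dil)
  for (code in 1:2) {
    expect_gte(metastasis_count_error(a_dil, code)$count,
               metastasis_count_error(a_true, code)$count)
  }
})
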