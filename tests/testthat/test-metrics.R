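test_that("dice matches the confusion-count oracle on random masks", {
  set.seed(31)
  for (rep in 1:20) {
    d <- c(sample(4:12, 1), sample(4:12, 1), sample(4:12, 1))
    a <- random_mask(d, runif(1, 0.1, 0.5))
    b <- random_mask(d, runif(1, 0.1, 0.5))
    expect_equal(dice(a, b), oracle_confusion_dice(a, b), tolerance = 1e-12)
    expect_equal(dice(a, b), dice(b, a))  # symmetric
  }
})

test_that("dice edge cases follow the eps-smoothed definition", {
  a <- array(FALSE, c(4, 4, 4)); a[2:3, 2:3, 2:3] <- TRUE
  expect_identical(dice(a, a), 1)           # identical nonempty: exactly 1
  e <- array(FALSE, c(4, 4, 4))
  expect_equal(dice(e, e), 1)               # both empty: eps/eps
  expect_lt(dice(a, e), 1e-4)               # one empty: ~0
  # |pred| = 4, |ref| = 4, overlap 2: (4 + 1e-5)/(8 + 1e-5)
  p <- array(FALSE, c(4, 4, 1)); p[1:4, 1, 1] <- TRUE
  r <- array(FALSE, c(4, 4, 1)); r[3:4, 1, 1] <- TRUE; r[1:2, 2, 1] <- TRUE
  expect_equal(dice(p, r), (4 + 1e-5) / (8 + 1e-5), tolerance = 1e-12)
  expect_error(dice(p, array(FALSE, c(4, 4, 2))), "geometry")
})

test_that("dice strictly decreases as overlap voxels are removed", {
  set.seed(32)
  ref <- array(FALSE, c(8, 8, 8)); ref[2:7, 2:7, 2:7] <- TRUE
  pred <- ref
  on_idx <- sample(which(pred))
  prev <- dice(pred, ref)
  for (i in on_idx[1:20]) {
    pred[i] <- FALSE
    cur <- dice(pred, ref)
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("percentile Hausdorff matches the all-pairs brute-force oracle", {
  set.seed(33)
  spacing <- c(240, 240, 480)
  for (rep in 1:15) {
    d <- c(sample(5:10, 1), sample(5:10, 1), sample(5:10, 1))
    a <- random_mask(d, 0.3); b <- random_mask(d, 0.3)
    if (!any(a) || !any(b)) next
    got <- hausdorff_percentile(a, b, c(50, 95), spacing)
    want <- oracle_hausdorff(a, b, c(50, 95), spacing)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("Hausdorff special values and ordering hold", {
  a <- array(FALSE, c(8, 8, 8)); a[3:5, 3:5, 3:5] <- TRUE
  expect_equal(hausdorff_percentile(a, a, c(50, 95, 100), c(240, 240, 240)),
               c(0, 0, 0))
  # two single voxels 3 voxels apart at 240 um: 720 um at any percentile
  p1 <- array(FALSE, c(8, 8, 8)); p1[2, 4, 4] <- TRUE
  p2 <- array(FALSE, c(8, 8, 8)); p2[5, 4, 4] <- TRUE
  expect_equal(hausdorff_percentile(p1, p2, c(5, 50, 95), c(240, 240, 240)),
               rep(720, 3))
  # percentiles are monotone in p
  set.seed(34)
  x <- random_mask(c(8, 8, 8), 0.2); y <- random_mask(c(8, 8, 8), 0.2)
  h <- hausdorff_percentile(x, y, c(50, 95, 100), c(100, 100, 100))
  expect_true(h[1] <= h[2] && h[2] <= h[3])
  # empty mask: missing value with a reason
  e <- array(FALSE, c(8, 8, 8))
  he <- hausdorff_percentile(e, a, 50, c(240, 240, 240))
  expect_true(is.na(he))
  expect_match(attr(he, "reason"), "empty prediction")
})

test_that("center-of-mass displacement is exact and translation-aware", {
  set.seed(35)
  a <- random_mask(c(10, 10, 10), 0.3)
  b <- random_mask(c(10, 10, 10), 0.3)
  sp <- c(240, 240, 120)
  expect_equal(com_displacement(a, b, sp), oracle_com(a, b, sp),
               tolerance = 1e-12)
  expect_equal(com_displacement(a, a, sp), 0)
  # pure translation by 3 voxels along axis 1 at 240 um: 720 um
  m <- array(FALSE, c(12, 8, 8)); m[2:4, 3:5, 3:5] <- TRUE
  mt <- array(FALSE, c(12, 8, 8)); mt[5:7, 3:5, 3:5] <- TRUE
  expect_equal(com_displacement(mt, m, c(240, 240, 240)), 720)
  # collinear second translation: displacement follows the offset change
  mt2 <- array(FALSE, c(12, 8, 8)); mt2[7:9, 3:5, 3:5] <- TRUE
  expect_equal(com_displacement(mt2, m, c(240, 240, 240)), 1200)
})

test_that("union-reference dice follows its set algebra", {
  set.seed(36)
  # pred = a1 = a2: perfect
  a <- random_mask(c(8, 8, 8), 0.3)
  expect_equal(union_reference_dice(a, a, a), 1, tolerance = 1e-6)
  # pred = a1 and a2 a superset: still perfect (no FP inside a2, no FN
  # outside the intersection)
  a2 <- a | random_mask(c(8, 8, 8), 0.2)
  expect_equal(union_reference_dice(a, a, a2), 1, tolerance = 1e-6)
  # brute-force oracle on random triples; never worse than plain dice
  # against either annotation alone when the other contains it
  for (rep in 1:10) {
    p <- random_mask(c(8, 8, 8), 0.3)
    x1 <- random_mask(c(8, 8, 8), 0.3)
    x2 <- x1 | random_mask(c(8, 8, 8), 0.2)  # x2 contains x1
    tp <- sum(p & (x1 | x2)); fp <- sum(p & !(x1 | x2))
    fn <- sum(!p & (x1 & x2))
    expect_equal(union_reference_dice(p, x1, x2),
                 (2 * tp + 1e-5) / (2 * tp + fp + fn + 1e-5),
                 tolerance = 1e-12)
    expect_gte(union_reference_dice(p, x1, x2), dice(p, x1) - 1e-12)
  }
})

test_that("disagreement dice scores a binarized heatmap against true XOR", {
  spec <- tiny_spec(annotator_noise_sd = 0)
  ph <- generate_phantom(spec, 1, 1)
  a1 <- ph$labels
  a2 <- simulate_annotator(a1, c(blob = 1), 0, seed = 2)
  tg <- make_disagreement_targets(a1, a2)
  xor_mask <- tg$data[, , , 3] > 0
  # heatmap equal to the exact indicator: 1
  heat <- voxel_volume(xor_mask * 1, a1$spacing)
  expect_equal(disagreement_dice(heat, a1, a2), 1, tolerance = 1e-6)
  # all-zero heatmap with nonempty disagreement: ~0
  expect_lt(disagreement_dice(voxel_volume(array(0, dim(a1$data)),
                                           a1$spacing), a1, a2), 1e-4)
  # heatmap covering about half the XOR region matches the count oracle
  half <- xor_mask
  half[which(half)[seq(1, sum(half), by = 2)]] <- FALSE
  expect_equal(disagreement_dice(voxel_volume(half * 1, a1$spacing), a1, a2),
               oracle_confusion_dice(half, xor_mask), tolerance = 1e-12)
})

test_that("human-vs-human scoring with dice is symmetric", {
  cohort <- tiny_cohort()
  sc <- cohort$subjects[[1]]$scans[[1]]
  for (k in 1:2) {
    m1 <- sc$labels[[1]]$data == k
    m2 <- sc$labels[[2]]$data == k
    expect_identical(dice(m1, m2), dice(m2, m1))
  }
})

test_that("evaluation report has per-organ rows with sane values", {
  cohort <- tiny_cohort()
  sc <- cohort$subjects[[1]]$scans[[1]]
  rep <- evaluate_segmentation(sc$labels[[2]], sc$labels[[1]],
                               ref2 = sc$labels[[2]])
  expect_equal(rep$organ, c("blob", "pill"))
  expect_true(all(rep$dice >= 0 & rep$dice <= 1))
  expect_true(all(rep$hd50_um >= 0))
  expect_true(all(rep$union_dice >= rep$dice - 1e-12))
})
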