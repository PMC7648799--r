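test_that("leave-one-mouse-out splits partition subjects without leakage", {
  cohort <- build_cohort(tiny_spec(n_mice = 5, scans_per_mouse = 1))
  tests <- numeric(0)
  for (fold in 1:5) {
    sp <- split_cv(cohort, fold, seed = 3, ensemble_size = 2)
    tests <- c(tests, sp$test_mice)
    expect_length(sp$test_mice, 1)
    for (m in sp$members) {
      expect_false(sp$test_mice %in% m$training_mice)
      expect_false(sp$test_mice %in% m$validation_mice)
      expect_false(m$validation_mice %in% m$training_mice)
      # member's sets plus the test mouse partition the cohort
      expect_setequal(c(sp$test_mice, m$validation_mice, m$training_mice),
                      sp$all_mice)
    }
  }
  # the folds' test sets tile all mice, pairwise disjoint
  expect_setequal(tests, 1:5)
  expect_equal(anyDuplicated(tests), 0)
  expect_error(split_cv(build_cohort(tiny_spec(n_mice = 2)), 1), "at least 3")
})

test_that("disagreement targets encode agreement plus XOR union", {
  spec <- tiny_spec(annotator2_bias = 0, annotator_noise_sd = 0)
  ph <- generate_phantom(spec, 1, 1)
  a1 <- ph$labels
  # identical annotations: organ channels one-hot, empty disagreement
  tg <- make_disagreement_targets(a1, a1)
  expect_equal(sum(tg$data[, , , 3]), 0)
  for (k in 1:2) expect_equal(tg$data[, , , k], (a1$data == k) * 1)

  # a2 = a1 with one organ dilated by 1 voxel: disagreement = the shell
  a2 <- simulate_annotator(a1, c(blob = 1), 0, seed = 1)
  tg2 <- make_disagreement_targets(a1, a2)
  shell <- (a2$data == 1L) & (a1$data != 1L)
  expect_equal(tg2$data[, , , 3] > 0, shell)
  # agreement channel is the intersection
  expect_equal(tg2$data[, , , 1], ((a1$data == 1L) & (a2$data == 1L)) * 1)

  # random labels: disagreement = union(OR) minus union(AND), per identity
  set.seed(8)
  r1 <- label_volume(array(sample(0:2, 4096, TRUE), c(16, 16, 16)),
                     c(240, 240, 240), c(a = 1L, b = 2L))
  r2 <- label_volume(array(sample(0:2, 4096, TRUE), c(16, 16, 16)),
                     c(240, 240, 240), c(a = 1L, b = 2L))
  tg3 <- make_disagreement_targets(r1, r2)
  or_u <- and_u <- array(FALSE, c(16, 16, 16))
  for (k in 1:2) {
    or_u <- or_u | (r1$data == k) | (r2$data == k)
    and_u <- and_u | ((r1$data == k) & (r2$data == k))
  }
  expect_equal(tg3$data[, , , 3] > 0, or_u & !and_u)
})

test_that("plateau scheduler reduces the rate once per stagnation window", {
  step <- plateau_scheduler(1e-3, factor = 0.1, patience = 5)
  lrs <- vapply(rep(0.5, 12), step, numeric(1))
  # constant metric: first call sets the best, reductions after every 5
  # further stagnating calls
  expect_equal(lrs, c(rep(1e-3, 5), rep(1e-4, 5), rep(1e-5, 2)))
  # improvement resets the counter
  step2 <- plateau_scheduler(1e-3, factor = 0.5, patience = 3)
  met <- c(0.1, 0.2, 0.2, 0.2, 0.25, 0.25, 0.25, 0.25)
  lrs2 <- vapply(met, step2, numeric(1))
  expect_equal(lrs2, c(1e-3, 1e-3, 1e-3, 1e-3, 1e-3, 1e-3, 1e-3, 5e-4))
})

test_that("short training descends and is seed-reproducible", {
  cohort <- tiny_cohort()
  net_cfg <- net_config(names(cohort$code_table), levels = 2,
                        base_channels = 4)
  train_cfg <- train_config(epochs = 2, initial_lr = 1e-2,
                            ensemble_size = 1, seed = 19)
  split <- split_cv(cohort, 1, seed = 19)
  fit1 <- train_model(cohort, split, net_cfg, train_cfg)
  expect_lt(fit1$history$train_loss[2], fit1$history$train_loss[1])
  expect_equal(nrow(fit1$history), 2)
  fit2 <- train_model(cohort, split, net_cfg, train_cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$net$params, fit2$net$params)
})

test_that("volume prediction honours the output contract", {
  cohort <- tiny_cohort()
  net <- build_network(net_config(names(cohort$code_table), levels = 2,
                                  base_channels = 4), seed = 7)
  v <- cohort$subjects[[1]]$scans[[1]]$image
  maps <- predict_volume(net, v, code_table = cohort$code_table)
  expect_s3_class(maps, "prob_maps")
  expect_equal(dim(maps$data), c(dim(v$data), 2))
  expect_true(all(maps$data >= 0 & maps$data <= 1))
  # ensemble of one identical member: exactly the single-model maps
  maps2 <- predict_volume(list(net), v, code_table = cohort$code_table)
  expect_identical(maps$data, maps2$data)
  med <- ensemble_median(list(maps, maps, maps))
  expect_equal(med$data, maps$data)
})

test_that("prediction pads and resamples odd-shaped volumes transparently", {
  net <- build_network(net_config(c("a"), levels = 3, base_channels = 2),
                       seed = 1)
  v <- voxel_volume(array(rnorm(10 * 18 * 22), c(10, 18, 22)),
                    c(200, 200, 200))
  maps <- predict_volume(net, v, preprocess_config(target_scale_um = 400),
                         code_table = c(a = 1L))
  expect_equal(dim(maps$data), c(10, 18, 22, 1))
  expect_true(all(maps$data >= 0 & maps$data <= 1))
})

test_that("ensemble median equals the sort-and-pick-middle oracle", {
  set.seed(21)
  ct <- c(a = 1L)
  mk <- function() prob_maps(array(runif(4 * 4 * 4 * 1), c(4, 4, 4, 1)),
                             c(1, 1, 1), "a", ct)
  maps <- list(mk(), mk(), mk(), mk(), mk())
  med <- ensemble_median(maps)
  for (v in sample(64, 10)) {
    idx <- arrayInd(v, c(4, 4, 4))
    vals <- vapply(maps, function(m) {
      m$data[idx[1], idx[2], idx[3], 1]
    }, numeric(1))
    expect_equal(med$data[idx[1], idx[2], idx[3], 1],
                 sort(vals)[3])
  }
  # a literal median triple
  m3 <- lapply(c(0.1, 0.9, 0.9), function(p) {
    prob_maps(array(p, c(2, 2, 2, 1)), c(1, 1, 1), "a", ct)
  })
  expect_equal(ensemble_median(m3)$data[1, 1, 1, 1], 0.9)
})

test_that("softmax binarization assigns arg-max classes with stable ties", {
  ct <- c(a = 1L, b = 2L)
  arr <- array(0, c(1, 1, 4, 2))
  arr[1, 1, 1, ] <- c(0.99, 0.01)  # clear organ a
  arr[1, 1, 2, ] <- c(0.01, 0.99)  # clear organ b
  arr[1, 1, 3, ] <- c(0.40, 0.30)  # all <= 0.5: background
  arr[1, 1, 4, ] <- c(0.70, 0.70)  # organ tie: lowest class index wins
  maps <- prob_maps(arr, c(1, 1, 1), c("a", "b"), ct)
  out <- binarize_softmax(maps)
  expect_equal(as.vector(out$labels$data), c(1L, 2L, 0L, 1L))
  expect_null(out$heatmap)
  # threshold rule agrees on these cases
  out2 <- binarize_softmax(maps, rule = "threshold")
  expect_equal(as.vector(out2$labels$data), c(1L, 2L, 0L, 1L))
  # exact 0.5 everywhere: background wins the tie against an organ
  half <- prob_maps(array(0.5, c(1, 1, 1, 2)), c(1, 1, 1), c("a", "b"), ct)
  expect_equal(as.vector(binarize_softmax(half)$labels$data), 0L)
  # disagreement channel passes through as a heatmap, untouched
  arrd <- array(runif(2 * 2 * 2 * 3), c(2, 2, 2, 3))
  mapsd <- prob_maps(arrd, c(1, 1, 1), c("a", "b", ".disagreement"), ct,
                     has_disagreement = TRUE)
  outd <- binarize_softmax(mapsd)
  expect_equal(outd$heatmap$data, arrd[, , , 3])
})

test_that("slice then reconstruct is the identity on label volumes", {
  ph <- generate_phantom(tiny_spec(), 2, 1)
  sl <- slice_coronal(ph$volume, ph$labels)
  maps <- reconstruct_3d(lapply(sl, function(s) s$masks),
                         spacing = ph$labels$spacing,
                         classes = names(ph$labels$code_table),
                         code_table = ph$labels$code_table)
  expect_equal(dim(maps$data), c(dim(ph$labels$data), 2))
  back <- binarize_softmax(maps)
  expect_identical(back$labels$data, ph$labels$data)
  # missing slice raises
  broken <- lapply(sl, function(s) s$masks)
  broken[5] <- list(NULL)
  expect_error(reconstruct_3d(broken, ph$labels$spacing, c("blob", "pill"),
                              ph$labels$code_table), "index 5")
})
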