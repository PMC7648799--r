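# Shared fixtures. Heavy objects (cohorts, trained models) are built once
# per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# A small, fast phantom spec for unit tests: 3 mice x 2 scans, two organs
# on a 32 x 32 x 48 grid.
tiny_spec <- function(n_mice = 3L, scans_per_mouse = 2L, seed = 42L,
                      annotator2_bias = c(blob = 1), annotator_noise_sd = 0.05,
                      jitter_shift_vx = 2, jitter_rot_deg = 4, ...) {
  phantom_spec(
    grid_shape = c(32, 32, 48),
    voxel_spacing = c(240, 240, 240),
    organs = list(
      phantom_organ("blob", 1L, c(16, 16, 14), c(6, 5, 6), 1.0),
      phantom_organ("pill", 2L, c(16, 16, 34), c(4, 7, 5), 0.6)
    ),
    n_mice = n_mice, scans_per_mouse = scans_per_mouse,
    subject_scale_sd = 0.04,
    jitter_shift_vx = jitter_shift_vx, jitter_rot_deg = jitter_rot_deg,
    annotator2_bias = annotator2_bias,
    annotator_noise_sd = annotator_noise_sd,
    metastases_per_organ = 3L, background_metastases = 2L,
    seed = seed, ...)
}

tiny_cohort <- function() fixture("tiny_cohort", function() {
  build_cohort(tiny_spec())
})

# The full-size study cohort (6 mice x 2 scans, 64 x 64 x 96, 4 organs,
# one low-contrast, annotator-2 bias on the spleen boundary).
study_cohort <- function() fixture("study_cohort", function() {
  build_cohort(phantom_spec(seed = 20260926L))
})

# Training configuration for the desk-scale studies: tiny network
# (3 levels, 8 base channels), 12 epochs at lr 1e-2, one model per fold.
study_net_cfg <- function(disagreement = FALSE) {
  net_config(names(study_cohort()$code_table), levels = 3L,
             base_channels = 8L, disagreement_head = disagreement)
}

study_train_cfg <- function(seed = 73L) {
  train_config(epochs = 12L, initial_lr = 1e-2, ensemble_size = 1L,
               seed = seed)
}

# Leave-one-mouse-out training over all folds of the study cohort, with
# per-fold predictions and evaluation reports on the held-out mouse.
study_lomo <- function() fixture("study_lomo", function() {
  cohort <- study_cohort()
  M <- length(cohort$subjects)
  ids <- vapply(cohort$subjects, function(s) s$id, numeric(1))
  lapply(seq_len(M), function(fold) {
    split <- split_cv(cohort, fold, seed = 73L)
    fit <- train_model(cohort, split, study_net_cfg(), study_train_cfg())
    subj <- cohort$subjects[[which(ids == split$test_mice)]]
    scans <- lapply(subj$scans, function(sc) {
      maps <- predict_volume(fit$net, sc$image,
                             code_table = cohort$code_table)
      bin <- binarize_softmax(maps)
      list(maps = maps, labels = bin$labels,
           report = evaluate_segmentation(bin$labels, sc$labels[[1]],
                                          ref2 = sc$labels[[2]]))
    })
    list(fit = fit, split = split, scans = scans)
  })
})

# One disagreement-head model trained on the study cohort (fold 1).
study_disagreement <- function() fixture("study_disagreement", function() {
  cohort <- study_cohort()
  split <- split_cv(cohort, 1, seed = 73L)
  fit <- train_model(cohort, split, study_net_cfg(disagreement = TRUE),
                     study_train_cfg(seed = 74L))
  list(fit = fit, split = split)
})

# Random small binary mask for metric oracle tests.
random_mask <- function(d, p = 0.2) {
  array(stats::runif(prod(d)) < p, d)
}

# Independent brute-force metric oracles (straight from the definitions,
# no shared code with the package internals).
oracle_confusion_dice <- function(pred, ref, eps = 1e-5) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] && ref[i]) tp <- tp + 1
    else if (pred[i]) fp <- fp + 1
    else if (ref[i]) fn <- fn + 1
  }
  (2 * tp + eps) / (2 * tp + fp + fn + eps)
}

oracle_surface <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (!mask[i, j, k]) next
    nb <- c(
      if (i > 1) mask[i - 1, j, k] else FALSE,
      if (i < d[1]) mask[i + 1, j, k] else FALSE,
      if (j > 1) mask[i, j - 1, k] else FALSE,
      if (j < d[2]) mask[i, j + 1, k] else FALSE,
      if (k > 1) mask[i, j, k - 1] else FALSE,
      if (k < d[3]) mask[i, j, k + 1] else FALSE)
    if (any(!nb)) out[i, j, k] <- TRUE
  }
  out
}

oracle_hausdorff <- function(pred, ref, p, spacing) {
  ps <- which(oracle_surface(pred), arr.ind = TRUE)
  rs <- which(oracle_surface(ref), arr.ind = TRUE)
  ps <- sweep(ps, 2, spacing, "*")
  rs <- sweep(rs, 2, spacing, "*")
  dists <- apply(rs, 1, function(s) {
    min(sqrt(colSums((t(ps) - s)^2)))
  })
  unname(stats::quantile(dists, p / 100, type = 7))
}

oracle_com <- function(pred, ref, spacing) {
  cp <- colMeans(which(pred, arr.ind = TRUE)) * spacing
  cr <- colMeans(which(ref, arr.ind = TRUE)) * spacing
  sqrt(sum((cp - cr)^2))
}

# End-to-end CLI pipeline (simulate -> train -> predict -> evaluate) on a
# small 4-mouse phantom, executed twice with the same seed into separate
# directories; used by the smoke and determinism checks.
cli_runs <- function() fixture("cli_runs", function() {
  run_once <- function(root) {
    sim_dir <- file.path(root, "sim")
    run_command("simulate", run_config("simulate", overrides = list(
      n_mice = 4L, scans_per_mouse = 1L, seed = 5L, out = sim_dir)))
    train_dir <- file.path(root, "train")
    run_command("train", run_config("train", overrides = list(
      manifest = file.path(sim_dir, "manifest.csv"),
      code_table = file.path(sim_dir, "code_table.csv"),
      fold = 1L, levels = 2L, base_channels = 4L, epochs = 1L,
      initial_lr = 1e-2, seed = 5L, out = train_dir)))
    pred_dir <- file.path(root, "pred")
    run_command("predict", run_config("predict", overrides = list(
      models = train_dir, image = file.path(sim_dir, "mouse1_scan1.nii.gz"),
      seed = 5L, out = pred_dir)))
    eval_dir <- file.path(root, "eval")
    run_command("evaluate", run_config("evaluate", overrides = list(
      pred = file.path(pred_dir, "seg.nii.gz"),
      ref = file.path(sim_dir, "mouse1_scan1_annot1.nii.gz"),
      ref2 = file.path(sim_dir, "mouse1_scan1_annot2.nii.gz"),
      code_table = file.path(sim_dir, "code_table.csv"),
      seed = 5L, out = eval_dir)))
    root
  }
  base <- file.path(tempdir(), "moseg_cli_fixture")
  unlink(base, recursive = TRUE)
  dir.create(base, recursive = TRUE)
  suppressMessages({
    run_once(file.path(base, "run1"))
    run_once(file.path(base, "run2"))
  })
  base
})
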