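#' Training configuration
#'
#' @param epochs training epochs (default 30).
#' @param initial_lr initial Adam learning rate (default 1e-3).
#' @param plateau_patience epochs of stagnating validation performance
#'   before the learning rate is reduced (default 5).
#' @param lr_factor multiplicative learning-rate reduction (default 0.1).
#' @param batch_size slices per optimization step.
#' @param ensemble_size independently trained models per
#'   training/validation set (default 10); members differ by validation
#'   mouse and by seed.
#' @param seed master seed for weight init, shuffling and augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 30L, initial_lr = 1e-3,
                         plateau_patience = 5L, lr_factor = 0.1,
                         batch_size = 8L, ensemble_size = 10L, seed = 1L) {
  stopifnot(epochs >= 1, initial_lr > 0, lr_factor > 0, lr_factor < 1,
            plateau_patience >= 1, batch_size >= 1, ensemble_size >= 1)
  structure(list(epochs = as.integer(epochs), initial_lr = initial_lr,
                 plateau_patience = as.integer(plateau_patience),
                 lr_factor = lr_factor, batch_size = as.integer(batch_size),
                 ensemble_size = as.integer(ensemble_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Subject-level cross-validation split
#'
#' Leave-one-mouse-out: fold `i`'s subject is the test set (`k` equals the
#' number of mice); the remaining subjects are partitioned, per ensemble
#' member, into one validation subject and the training subjects. No scan
#' of the test mouse ever appears in training or validation.
#'
#' @param cohort a cohort with at least 3 subjects.
#' @param fold fold index in `1..n_subjects`.
#' @param seed seed for the validation-mouse assignment.
#' @param ensemble_size number of members; each gets its own validation
#'   mouse (recycled if there are fewer non-test mice than members, in
#'   which case members differ by seed only).
#' @return A `cv_split` with `test_mice` and `members`, where
#'   `members[[j]]` has `validation_mice` and `training_mice`.
#' @export
split_cv <- function(cohort, fold, seed = 1L, ensemble_size = 1L) {
  ids <- vapply(cohort$subjects, function(s) s$id, numeric(1))
  M <- length(ids)
  if (M < 3) stop("subject-level cross-validation needs at least 3 mice")
  stopifnot(fold >= 1, fold <= M)
  test <- ids[fold]
  rest <- ids[-fold]
  perm <- with_seed(derive_seed(seed, 21, fold), sample(rest))
  members <- lapply(seq_len(ensemble_size), function(j) {
    val <- perm[((j - 1) %% length(perm)) + 1]
    list(validation_mice = val, training_mice = setdiff(rest, val))
  })
  structure(list(fold = fold, test_mice = test, members = members,
                 all_mice = ids),
            class = "cv_split")
}

#' Build training targets encoding annotator agreement and disagreement
#'
#' For the disagreement-prediction mode: each organ channel is the voxels
#' both annotators assign to that organ (their agreement); the extra
#' disagreement channel is the union over organs of the XOR of the two
#' annotators' masks, i.e. every voxel the two annotators label
#' differently.
#'
#' @param a1,a2 two [label_volume()]s with identical geometry and code
#'   table.
#' @param organ_targets `"agreement"` (default): organ channels are the
#'   annotator intersection; `"annotator1"`: organ channels follow
#'   annotator 1, with the disagreement channel as an auxiliary class.
#' @return A [prob_maps()] of binary masks with `has_disagreement = TRUE`.
#' @export
make_disagreement_targets <- function(a1, a2,
                                      organ_targets = c("agreement",
                                                        "annotator1")) {
  organ_targets <- match.arg(organ_targets)
  stopifnot_same_geometry(a1, a2, "annotations")
  if (!identical(a1$code_table, a2$code_table)) {
    stop("annotations have different code tables")
  }
  ct <- a1$code_table
  d <- dim(a1$data)
  out <- array(0, c(d, length(ct) + 1L))
  dis <- array(FALSE, d)
  for (k in seq_along(ct)) {
    m1 <- a1$data == ct[k]
    m2 <- a2$data == ct[k]
    out[, , , k] <- if (organ_targets == "agreement") (m1 & m2) * 1 else
      m1 * 1
    dis <- dis | xor(m1, m2)
  }
  out[, , , length(ct) + 1L] <- dis * 1
  prob_maps(out, a1$spacing, c(names(ct), ".disagreement"), ct,
            has_disagreement = TRUE)
}

# One-hot organ masks of a label volume as binary prob_maps.
label_to_masks <- function(labels) {
  ct <- labels$code_table
  d <- dim(labels$data)
  out <- array(0, c(d, length(ct)))
  for (k in seq_along(ct)) out[, , , k] <- (labels$data == ct[k]) * 1
  prob_maps(out, labels$spacing, names(ct), ct)
}

#' Plateau learning-rate scheduler
#'
#' Reduces the learning rate by `factor` whenever the monitored metric
#' (higher is better) has not improved for `patience` consecutive steps;
#' the stagnation counter resets after each reduction.
#'
#' @param initial_lr starting learning rate.
#' @param factor multiplicative reduction in `(0, 1)`.
#' @param patience steps without improvement before reducing.
#' @param min_lr lower bound on the learning rate.
#' @return A function `step(metric)` returning the learning rate to use
#'   after observing `metric`.
#' @export
plateau_scheduler <- function(initial_lr, factor = 0.1, patience = 5L,
                              min_lr = 1e-7) {
  lr <- initial_lr
  best <- -Inf
  wait <- 0L
  function(metric) {
    if (metric > best) {
      best <<- metric
      wait <<- 0L
    } else {
      wait <<- wait + 1L
      if (wait >= patience) {
        lr <<- max(lr * factor, min_lr)
        wait <<- 0L
      }
    }
    lr
  }
}

# Slice one scan into normalized (optionally resampled) training samples
# with per-class mask channels taken from `targets` (a prob_maps of
# binary masks).
scan_to_samples <- function(image, targets, pre_cfg, mouse = NA, scan = NA) {
  d <- dim(image$data)
  nc <- dim(targets$data)[4]
  vol_norm <- if (pre_cfg$normalize_scope == "volume") {
    normalize_intensity(image$data)
  } else image$data
  out <- vector("list", d[1])
  for (i in seq_len(d[1])) {
    img <- vol_norm[i, , ]
    if (pre_cfg$normalize_scope == "slice") img <- normalize_intensity(img)
    masks <- array(targets$data[i, , , ], c(d[2], d[3], nc))
    s <- new_slice_sample(img, masks, c(mouse, scan, i), image$spacing[2:3],
                          targets$classes,
                          disagreement = targets$has_disagreement)
    if (!is.null(pre_cfg$target_scale_um)) {
      s <- resample_slice(s, pre_cfg$target_scale_um)
    }
    out[[i]] <- s
  }
  out
}

scan_targets <- function(scan, disagreement) {
  if (disagreement) {
    if (length(scan$labels) < 2) {
      stop("disagreement mode needs two annotators per scan")
    }
    make_disagreement_targets(scan$labels[[1]], scan$labels[[2]])
  } else {
    label_to_masks(scan$labels[[1]])
  }
}

gather_slices <- function(cohort, mice, pre_cfg, disagreement,
                          filter = TRUE) {
  ids <- vapply(cohort$subjects, function(s) s$id, numeric(1))
  out <- list()
  for (m in mice) {
    subj <- cohort$subjects[[which(ids == m)]]
    for (t in seq_along(subj$scans)) {
      sc <- subj$scans[[t]]
      targets <- scan_targets(sc, disagreement)
      out <- c(out, scan_to_samples(sc$image, targets, pre_cfg, m, t))
    }
  }
  if (filter) out <- filter_training_slices(out)
  out
}

stack_batch <- function(samples) {
  h <- dim(samples[[1]]$image)[1]
  w <- dim(samples[[1]]$image)[2]
  nc <- dim(samples[[1]]$masks)[3]
  B <- length(samples)
  x <- array(0, c(h, w, 1L, B))
  tg <- array(0, c(h, w, nc, B))
  for (b in seq_len(B)) {
    x[, , 1, b] <- samples[[b]]$image
    tg[, , , b] <- samples[[b]]$masks
  }
  list(x = x, targets = tg)
}

# Aggregated per-class soft-Dice over a slice set (evaluation mode).
eval_soft_dice <- function(net, samples, batch_size = 16L, eps = 1e-5) {
  nc <- net$cfg$n_classes
  inter <- sp <- st <- numeric(nc)
  i <- 1L
  while (i <= length(samples)) {
    idx <- i:min(i + batch_size - 1L, length(samples))
    bt <- stack_batch(samples[idx])
    probs <- net_forward(net, bt$x, training = FALSE)
    inter <- inter + channel_sums(probs * bt$targets)
    sp <- sp + channel_sums(probs)
    st <- st + channel_sums(bt$targets)
    i <- i + batch_size
  }
  mean((2 * inter + eps) / (sp + st + eps))
}

#' Train one network on a cross-validation split
#'
#' Adam optimization of the soft-Dice loss on the filtered, augmented
#' training slices of the member's training mice. After each epoch the
#' mean soft-Dice on the validation mouse's slices is evaluated and drives
#' the plateau learning-rate scheduler. Deterministic given the seeds in
#' `train_cfg`.
#'
#' @param cohort a cohort.
#' @param split a [split_cv()] result.
#' @param net_cfg a [net_config()]; with `disagreement_head = TRUE` the
#'   targets come from [make_disagreement_targets()], otherwise they are
#'   the one-hot masks of annotator 1.
#' @param train_cfg a [train_config()].
#' @param pre_cfg a [preprocess_config()].
#' @param member ensemble member index into `split$members`.
#' @param verbose print per-epoch progress?
#' @return List with `net` (trained `segnet`), `history` (data frame:
#'   epoch, train_loss, val_dice, lr) and `trained_on` bookkeeping.
#' @export
train_model <- function(cohort, split, net_cfg, train_cfg,
                        pre_cfg = preprocess_config(), member = 1L,
                        verbose = FALSE) {
  ms <- split$members[[member]]
  disagreement <- net_cfg$disagreement_head
  train_slices <- gather_slices(cohort, ms$training_mice, pre_cfg,
                                disagreement)
  if (length(train_slices) == 0) stop("empty training slice set")
  val_slices <- gather_slices(cohort, ms$validation_mice, pre_cfg,
                              disagreement)
  # leakage guard: training/validation samples must not come from test mice
  src_mice <- vapply(c(train_slices, val_slices),
                     function(s) s$source[1], numeric(1))
  if (any(src_mice %in% split$test_mice)) {
    stop("data leakage: test-mouse slices in the training/validation set")
  }

  net <- build_network(net_cfg,
                       seed = derive_seed(train_cfg$seed, 31, split$fold,
                                          member))
  ad <- adam_init(net$params)
  sched <- plateau_scheduler(train_cfg$initial_lr, train_cfg$lr_factor,
                             train_cfg$plateau_patience)
  lr <- train_cfg$initial_lr
  n <- length(train_slices)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_dice = numeric(), lr = numeric())
  step_counter <- 0L
  for (epoch in seq_len(train_cfg$epochs)) {
    ord <- with_seed(derive_seed(train_cfg$seed, 41, split$fold, member,
                                 epoch),
                     sample.int(n))
    losses <- numeric(0)
    i <- 1L
    while (i <= n) {
      idx <- ord[i:min(i + train_cfg$batch_size - 1L, n)]
      batch <- lapply(seq_along(idx), function(j) {
        augment(train_slices[[idx[j]]],
                seed = derive_seed(train_cfg$seed, 51, split$fold, member,
                                   epoch, idx[j]),
                rotation_deg = pre_cfg$rotation_deg,
                min_crop_area = pre_cfg$min_crop_area)
      })
      bt <- stack_batch(batch)
      fwd <- net_forward(net, bt$x, training = TRUE)
      net$state <- fwd$env$state
      loss <- soft_dice_loss(fwd$probs, bt$targets)
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", epoch, ", step ",
             step_counter, " (lr = ", lr, ")")
      }
      losses <- c(losses, loss)
      dprobs <- soft_dice_loss_grad(fwd$probs, bt$targets)
      grads <- net_backward(net, fwd$env, dprobs)
      upd <- adam_step(net$params, grads, ad, lr)
      net$params <- upd$params
      ad <- upd$st
      step_counter <- step_counter + 1L
      i <- i + train_cfg$batch_size
    }
    val_dice <- if (length(val_slices) > 0) {
      eval_soft_dice(net, val_slices)
    } else NA_real_
    if (is.finite(val_dice)) lr <- sched(val_dice)
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = mean(losses),
                                val_dice = val_dice, lr = lr))
    if (verbose) {
      message(sprintf("epoch %d: train loss %.4f, val dice %.4f, lr %g",
                      epoch, mean(losses), val_dice, lr))
    }
  }
  list(net = net, history = history,
       trained_on = list(fold = split$fold, member = member,
                         training_mice = ms$training_mice,
                         validation_mice = ms$validation_mice,
                         test_mice = split$test_mice))
}

#' Train the full ensemble for one split
#'
#' @inheritParams train_model
#' @return List of [train_model()] results, one per ensemble member.
#' @export
train_ensemble <- function(cohort, split, net_cfg, train_cfg,
                           pre_cfg = preprocess_config(), verbose = FALSE) {
  lapply(seq_along(split$members), function(j) {
    train_model(cohort, split, net_cfg, train_cfg, pre_cfg, member = j,
                verbose = verbose)
  })
}

#' Predict per-class probability maps for a whole volume
#'
#' Every coronal slice of the volume (no filtering, no augmentation) is
#' normalized, optionally resampled to the working resolution, padded so
#' the network's pooling chain divides the shape, forwarded, cropped and
#' resampled back to the native grid, and stacked into per-class 3-d
#' probability maps. With several networks, the voxel-wise channel-wise
#' median of the members' maps is returned.
#'
#' @param networks a trained `segnet` or a list of them (identical class
#'   lists required).
#' @param v a [voxel_volume()].
#' @param pre_cfg a [preprocess_config()] (must match training).
#' @param code_table named code table of the anatomical classes.
#' @param batch_size slices per forward pass.
#' @return A [prob_maps()] on the native grid of `v`.
#' @export
predict_volume <- function(networks, v, pre_cfg = preprocess_config(),
                           code_table = NULL, batch_size = 16L) {
  if (inherits(networks, "segnet")) networks <- list(networks)
  cls <- lapply(networks, function(n) n$cfg$classes)
  if (length(unique(vapply(cls, paste, character(1), collapse = ","))) != 1) {
    stop("ensemble members have different class lists")
  }
  cfg <- networks[[1]]$cfg
  if (is.null(code_table)) {
    code_table <- stats::setNames(seq_along(cfg$classes), cfg$classes)
  }
  maps <- lapply(networks, function(net) {
    predict_volume_single(net, v, pre_cfg, batch_size)
  })
  out <- if (length(maps) == 1) maps[[1]] else ensemble_median_array(maps)
  prob_maps(out, v$spacing, net_channels(cfg), code_table,
            has_disagreement = cfg$disagreement_head)
}

predict_volume_single <- function(net, v, pre_cfg, batch_size = 16L) {
  d <- dim(v$data)
  nc <- net$cfg$n_classes
  div <- 2^(net$cfg$levels - 1)
  vol_norm <- if (pre_cfg$normalize_scope == "volume") {
    normalize_intensity(v$data)
  } else v$data
  # prepare all slices (normalized, resampled)
  slices <- vector("list", d[1])
  for (i in seq_len(d[1])) {
    img <- vol_norm[i, , ]
    if (pre_cfg$normalize_scope == "slice") img <- normalize_intensity(img)
    if (!is.null(pre_cfg$target_scale_um)) {
      s <- new_slice_sample(img, NULL, c(NA, NA, i), v$spacing[2:3], NULL)
      s <- resample_slice(s, pre_cfg$target_scale_um)
      img <- s$image
    }
    slices[[i]] <- img
  }
  work_dim <- dim(slices[[1]])
  out <- array(0, c(d, nc))
  i <- 1L
  while (i <= d[1]) {
    idx <- i:min(i + batch_size - 1L, d[1])
    padded <- lapply(slices[idx], pad_to_multiple, m = div)
    ph <- dim(padded[[1]]$image)
    x <- array(0, c(ph[1], ph[2], 1L, length(idx)))
    for (b in seq_along(idx)) x[, , 1, b] <- padded[[b]]$image
    probs <- net_forward(net, x, training = FALSE)
    probs <- probs[seq_len(work_dim[1]), seq_len(work_dim[2]), , ,
                   drop = FALSE]
    if (!identical(as.integer(work_dim), as.integer(d[2:3]))) {
      probs <- cpp_resize_bilinear(probs, d[2], d[3])
    }
    for (b in seq_along(idx)) out[idx[b], , , ] <- probs[, , , b]
    i <- i + batch_size
  }
  out
}

ensemble_median_array <- function(arrs) {
  k <- length(arrs)
  m <- matrix(0, length(arrs[[1]]), k)
  for (j in seq_len(k)) m[, j] <- as.vector(arrs[[j]])
  array(cpp_row_median(m), dim(arrs[[1]]))
}

#' Voxel-wise median of an ensemble's probability maps
#'
#' @param maps list of [prob_maps()] with identical geometry and classes.
#' @return A [prob_maps()] of the channel-wise, voxel-wise medians.
#' @export
ensemble_median <- function(maps) {
  stopifnot(length(maps) >= 1)
  ref <- maps[[1]]
  for (m in maps[-1]) {
    stopifnot_same_geometry(ref, m, "probability maps")
    if (!identical(ref$classes, m$classes)) stop("class list mismatch")
  }
  if (length(maps) == 1) return(ref)
  out <- ensemble_median_array(lapply(maps, function(m) m$data))
  prob_maps(out, ref$spacing, ref$classes, ref$code_table,
            ref$has_disagreement)
}

#' Binarize probability maps into a label volume
#'
#' The anatomical channels, together with a synthetic background score
#' `1 - max(anatomical probabilities)`, are passed through a per-voxel
#' softmax and each voxel is assigned the arg-max class (background
#' allowed; ties break toward the lowest class index, with background
#' first). The disagreement channel, if present, is excluded from the
#' softmax and returned unchanged as a heatmap. No further postprocessing
#' (filtering, morphology) is applied. With `rule = "threshold"`, a voxel
#' is background whenever all anatomical probabilities are <= 0.5 and
#' arg-max otherwise.
#'
#' @param maps a [prob_maps()].
#' @param rule `"softmax"` (default) or `"threshold"`.
#' @return List with `labels` (a [label_volume()]) and `heatmap` (a
#'   [voxel_volume()] of disagreement probabilities, or `NULL`).
#' @export
binarize_softmax <- function(maps, rule = c("softmax", "threshold")) {
  rule <- match.arg(rule)
  nc <- length(maps$classes)
  n_anat <- nc - maps$has_disagreement
  d <- dim(maps$data)[1:3]
  A <- matrix(maps$data[, , , seq_len(n_anat)], ncol = n_anat)
  mx <- do.call(pmax, lapply(seq_len(n_anat), function(j) A[, j]))
  S <- cbind(1 - mx, A)
  if (rule == "softmax") {
    E <- exp(S - mx)  # shift for stability; monotone per voxel
    S <- E / rowSums(E)
  } else {
    S[, 1] <- 0.5  # background wins unless some organ exceeds 0.5
  }
  idx <- max.col(S, ties.method = "first")
  codes <- c(0L, unname(maps$code_table))
  lab <- array(codes[idx], d)
  heat <- NULL
  if (maps$has_disagreement) {
    heat <- voxel_volume(array(maps$data[, , , nc], d), maps$spacing)
  }
  list(labels = label_volume(lab, maps$spacing, maps$code_table),
       heatmap = heat)
}

#' Stack per-slice maps back into a volume
#'
#' Inverse of coronal slicing: given one per-slice map per coronal index,
#' in order, stacks them on the native grid.
#'
#' @param slice_outputs list of `(H, W, C)` arrays (or `(H, W)` matrices),
#'   one per coronal index.
#' @param spacing micrometers per voxel of the reconstructed volume.
#' @param classes channel names.
#' @param code_table anatomical code table.
#' @param has_disagreement is the last channel a disagreement heatmap?
#' @return A [prob_maps()] of shape `(n_slices, H, W, C)`.
#' @export
reconstruct_3d <- function(slice_outputs, spacing, classes, code_table,
                           has_disagreement = FALSE) {
  n <- length(slice_outputs)
  if (n == 0) stop("no slices to reconstruct")
  if (any(vapply(slice_outputs, is.null, logical(1)))) {
    stop("missing slice output at index ",
         which(vapply(slice_outputs, is.null, logical(1)))[1])
  }
  first <- slice_outputs[[1]]
  if (is.matrix(first)) {
    slice_outputs <- lapply(slice_outputs, function(s) {
      array(s, c(dim(s), 1L))
    })
    first <- slice_outputs[[1]]
  }
  dd <- dim(first)
  out <- array(0, c(n, dd[1], dd[2], dd[3]))
  for (i in seq_len(n)) {
    if (!identical(dim(slice_outputs[[i]]), dd)) {
      stop("inconsistent slice shape at index ", i)
    }
    out[i, , , ] <- slice_outputs[[i]]
  }
  prob_maps(out, spacing, classes, code_table, has_disagreement)
}
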