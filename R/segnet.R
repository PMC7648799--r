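#' Encoder-decoder network configuration
#'
#' The backbone is a U-Net-style fully convolutional network operating on
#' single-channel 2-d coronal slices. Each encoding unit applies two 3x3
#' convolutions (padding 1, stride 1), each followed by batch
#' normalization and a rectified linear activation; units are separated by
#' 2x2 max-pooling (stride 2), and the deepest unit is the bottleneck.
#' Channels double per level: level `l` has `base_channels * 2^(l-1)`
#' feature channels (32, 64, ..., 1024 at the defaults). Each decoding
#' unit bilinearly upsamples the coarser output, concatenates the skip
#' connection from the same level, and applies three such convolutions.
#' A final 1x1 convolution maps to the prediction classes, and a per-class
#' sigmoid yields probability maps (channels are independent and do not
#' sum to 1).
#'
#' @param classes character vector of anatomical class names, in
#'   code-table order.
#' @param levels number of encoder/decoder levels (default 6).
#' @param base_channels channels of the first encoding unit (default 32).
#' @param disagreement_head append one extra output channel trained on the
#'   annotator-disagreement mask and returned as a heatmap?
#' @return A `net_config` list; `n_classes` counts all output channels
#'   including the disagreement channel.
#' @export
net_config <- function(classes, levels = 6L, base_channels = 32L,
                       disagreement_head = FALSE) {
  stopifnot(levels >= 1, base_channels >= 1, length(classes) >= 1)
  channels <- as.integer(base_channels * 2^(seq_len(levels) - 1))
  structure(list(classes = as.character(classes),
                 levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 channels = channels,
                 disagreement_head = isTRUE(disagreement_head),
                 n_classes = length(classes) + isTRUE(disagreement_head)),
            class = "net_config")
}

#' Output channel names of a network configuration
#' @param cfg a [net_config()].
#' @return Character vector; the disagreement channel, if present, is last
#'   and named `".disagreement"`.
#' @export
net_channels <- function(cfg) {
  c(cfg$classes, if (cfg$disagreement_head) ".disagreement")
}

he_init <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

#' Build (initialize) an encoder-decoder network
#'
#' @param cfg a [net_config()].
#' @param seed integer seed for the weight initialization (He-normal).
#' @return A `segnet` object holding the configuration, a flat named list
#'   of trainable parameters, and batch-normalization running statistics.
#' @export
build_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "net_config"))
  L <- cfg$levels
  ch <- cfg$channels
  params <- list()
  state <- list()
  with_seed(seed, {
    add_conv <- function(tag, cin, cout, k = 3L) {
      params[[paste0(tag, ".w")]] <<- he_init(k, cin, cout)
      params[[paste0(tag, ".b")]] <<- numeric(cout)
    }
    add_bn <- function(tag, c) {
      params[[paste0(tag, ".g")]] <<- rep(1, c)
      params[[paste0(tag, ".be")]] <<- numeric(c)
      state[[paste0(tag, ".rm")]] <<- numeric(c)
      state[[paste0(tag, ".rv")]] <<- rep(1, c)
    }
    for (l in seq_len(L)) {
      cin <- if (l == 1) 1L else ch[l - 1]
      add_conv(sprintf("e%d.c1", l), cin, ch[l])
      add_bn(sprintf("e%d.bn1", l), ch[l])
      add_conv(sprintf("e%d.c2", l), ch[l], ch[l])
      add_bn(sprintf("e%d.bn2", l), ch[l])
    }
    for (l in rev(seq_len(L - 1))) {
      add_conv(sprintf("d%d.c1", l), ch[l + 1] + ch[l], ch[l])
      add_bn(sprintf("d%d.bn1", l), ch[l])
      for (j in 2:3) {
        add_conv(sprintf("d%d.c%d", l, j), ch[l], ch[l])
        add_bn(sprintf("d%d.bn%d", l, j), ch[l])
      }
    }
    add_conv("out", ch[1], cfg$n_classes, k = 1L)
  })
  structure(list(cfg = cfg, params = params, state = state),
            class = "segnet")
}

#' @export
print.segnet <- function(x, ...) {
  cat("<segnet> ", x$cfg$levels, " levels, channels ",
      paste(x$cfg$channels, collapse = "-"), ", ", x$cfg$n_classes,
      " output classes, ", format(net_parameter_count(x), big.mark = ","),
      " parameters\n", sep = "")
  invisible(x)
}

#' Number of trainable parameters of a network
#' @param net a `segnet`.
#' @return Integer count.
#' @export
net_parameter_count <- function(net) {
  sum(vapply(net$params, length, numeric(1)))
}

# ---- internal layers ---------------------------------------------------

bn_eps <- 1e-5

# per-class (channel) sums of a (H, W, C, B) array, aggregated over
# spatial positions and batch
channel_sums <- function(a4) {
  d <- dim(a4)
  rowSums(matrix(colSums(matrix(a4, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# conv -> batchnorm -> relu, updating caches/state environments in place
cbr_forward <- function(env, tag, x, training, momentum = 0.1) {
  p <- env$params
  y <- cpp_conv2d_forward(x, p[[paste0(tag, ".w")]], p[[paste0(tag, ".b")]])
  bn_tag <- sub("\\.c", ".bn", tag)
  if (training) {
    mv <- cpp_channel_mean_var(y)
    mu <- mv$mean; v <- mv$var
    env$state[[paste0(bn_tag, ".rm")]] <-
      (1 - momentum) * env$state[[paste0(bn_tag, ".rm")]] + momentum * mu
    env$state[[paste0(bn_tag, ".rv")]] <-
      (1 - momentum) * env$state[[paste0(bn_tag, ".rv")]] + momentum * v
  } else {
    mu <- env$state[[paste0(bn_tag, ".rm")]]
    v <- env$state[[paste0(bn_tag, ".rv")]]
  }
  istd <- 1 / sqrt(v + bn_eps)
  bn <- cpp_bnrelu_forward(y, mu, istd, p[[paste0(bn_tag, ".g")]],
                           p[[paste0(bn_tag, ".be")]], training)
  if (training) {
    env$cache[[tag]] <- list(conv_in = x, xhat = bn$xhat, istd = istd,
                             relu_out = bn$y)
  }
  bn$y
}

cbr_backward <- function(env, tag, dy) {
  cc <- env$cache[[tag]]
  bn_tag <- sub("\\.c", ".bn", tag)
  bnb <- cpp_bnrelu_backward(dy, cc$relu_out, cc$xhat,
                             env$params[[paste0(bn_tag, ".g")]], cc$istd)
  env$grads[[paste0(bn_tag, ".g")]] <- bnb$dg
  env$grads[[paste0(bn_tag, ".be")]] <- bnb$dbe
  cb <- cpp_conv2d_backward(cc$conv_in, env$params[[paste0(tag, ".w")]],
                            bnb$dx)
  env$grads[[paste0(tag, ".w")]] <- cb$dw
  env$grads[[paste0(tag, ".b")]] <- cb$db
  cb$dx
}

# ---- forward / backward -------------------------------------------------

#' Forward pass of the network
#'
#' Maps a batch of normalized 1-channel images to per-class probability
#' maps of identical spatial shape. In evaluation mode (the default) batch
#' normalization uses frozen running statistics, so repeated passes are
#' bit-identical.
#'
#' @param net a `segnet` from [build_network()].
#' @param x numeric array `(H, W, 1, B)` (a single `(H, W)` matrix is
#'   promoted to a batch of one). `H` and `W` must be divisible by
#'   `2^(levels - 1)`.
#' @param training logical; use batch statistics and record caches for
#'   the backward pass.
#' @return In evaluation mode, a `(H, W, n_classes, B)` probability array.
#'   In training mode, a list `(probs, env)` where `env` carries the
#'   layer caches consumed by the internal backward pass.
#' @export
net_forward <- function(net, x, training = FALSE) {
  cfg <- net$cfg
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  d <- dim(x)
  if (length(d) != 4L || d[3] != 1L) stop("input must be (H, W, 1, B)")
  div <- 2^(cfg$levels - 1)
  if (d[1] %% div != 0 || d[2] %% div != 0) {
    stop("spatial dims ", d[1], "x", d[2], " not divisible by 2^(levels-1) = ",
         div, "; pad the input (see pad_to_multiple)")
  }
  env <- new.env(parent = emptyenv())
  env$params <- net$params
  env$state <- net$state
  env$cache <- if (training) list() else NULL
  L <- cfg$levels
  skips <- vector("list", L)
  h <- x
  for (l in seq_len(L)) {
    if (l > 1) {
      mp <- cpp_maxpool_forward(h)
      if (training) env$cache[[sprintf("pool%d", l)]] <-
          list(arg = mp$argmax, h = dim(h)[1], w = dim(h)[2])
      h <- mp$y
    }
    h <- cbr_forward(env, sprintf("e%d.c1", l), h, training)
    h <- cbr_forward(env, sprintf("e%d.c2", l), h, training)
    if (l < L) skips[[l]] <- h
  }
  for (l in rev(seq_len(L - 1))) {
    sk <- skips[[l]]
    up <- cpp_resize_bilinear(h, dim(sk)[1], dim(sk)[2])
    if (training) env$cache[[sprintf("up%d", l)]] <-
        list(h = dim(h)[1], w = dim(h)[2], c_up = dim(h)[3])
    h <- concat_channels(up, sk)
    h <- cbr_forward(env, sprintf("d%d.c1", l), h, training)
    h <- cbr_forward(env, sprintf("d%d.c2", l), h, training)
    h <- cbr_forward(env, sprintf("d%d.c3", l), h, training)
  }
  logits <- cpp_conv2d_forward(h, net$params[["out.w"]], net$params[["out.b"]])
  probs <- 1 / (1 + exp(-logits))
  if (training) {
    env$cache[["out"]] <- list(conv_in = h)
    env$cache[["probs"]] <- probs
    env$state_out <- env$state
    list(probs = probs, env = env)
  } else {
    probs
  }
}

# Backward pass from dL/d(probs); returns flat named gradient list.
net_backward <- function(net, env, dprobs) {
  cfg <- net$cfg
  probs <- env$cache[["probs"]]
  dlogits <- dprobs * probs * (1 - probs)
  env$grads <- list()
  cb <- cpp_conv2d_backward(env$cache[["out"]]$conv_in, net$params[["out.w"]],
                            dlogits)
  env$grads[["out.w"]] <- cb$dw
  env$grads[["out.b"]] <- cb$db
  dh <- cb$dx
  L <- cfg$levels
  dskips <- vector("list", L)
  for (l in seq_len(L - 1)) {
    dh <- cbr_backward(env, sprintf("d%d.c3", l), dh)
    dh <- cbr_backward(env, sprintf("d%d.c2", l), dh)
    dh <- cbr_backward(env, sprintf("d%d.c1", l), dh)
    up <- env$cache[[sprintf("up%d", l)]]
    c_up <- up$c_up
    dup <- dh[, , seq_len(c_up), , drop = FALSE]
    dskips[[l]] <- dh[, , c_up + seq_len(dim(dh)[3] - c_up), , drop = FALSE]
    dh <- cpp_resize_bilinear_backward(dup, up$h, up$w)
  }
  for (l in rev(seq_len(L))) {
    if (l < L) dh <- dh + dskips[[l]]
    dh <- cbr_backward(env, sprintf("e%d.c2", l), dh)
    dh <- cbr_backward(env, sprintf("e%d.c1", l), dh)
    if (l > 1) {
      pl <- env$cache[[sprintf("pool%d", l)]]
      dh <- cpp_maxpool_backward(dh, pl$arg, pl$h, pl$w)
    }
  }
  env$grads
}

# ---- loss ---------------------------------------------------------------

#' Soft-Dice loss
#'
#' `1 - mean over classes of (2 * sum(p * t) + eps) / (sum p + sum t + eps)`
#' with `eps = 1e-5`, the same smoothing constant as the evaluation Dice.
#' Sums run over all spatial positions and the batch; classes are averaged
#' with equal weights.
#'
#' @param probs probability array `(H, W, C)` or `(H, W, C, B)`.
#' @param targets binary target masks, same shape.
#' @param eps smoothing constant.
#' @return Scalar loss in `[0, 1)`.
#' @export
soft_dice_loss <- function(probs, targets, eps = 1e-5) {
  1 - mean(soft_dice_per_class(probs, targets, eps))
}

soft_dice_per_class <- function(probs, targets, eps = 1e-5) {
  d <- dim(probs)
  if (!identical(d, dim(targets))) stop("shape mismatch")
  if (length(d) == 3L) {
    dim(probs) <- c(d[1], d[2], d[3], 1L)
    dim(targets) <- dim(probs)
  }
  inter <- channel_sums(probs * targets)
  (2 * inter + eps) / (channel_sums(probs) + channel_sums(targets) + eps)
}

# dL/dprobs for the soft-Dice loss (same conventions as soft_dice_loss)
soft_dice_loss_grad <- function(probs, targets, eps = 1e-5) {
  d <- dim(probs)
  C <- d[3]; B <- d[4]; hw <- d[1] * d[2]
  inter <- channel_sums(probs * targets)
  denom <- channel_sums(probs) + channel_sums(targets) + eps
  # d dice_c / d p = 2 t / denom - (2 inter + eps) / denom^2
  two_over_d <- rep(rep(2 / denom, times = B), each = hw)
  kc <- rep(rep((2 * inter + eps) / denom^2, times = B), each = hw)
  g <- -(as.vector(targets) * two_over_d - kc) / C
  array(g, d)
}

# ---- optimizer ----------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, st = st)
}
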