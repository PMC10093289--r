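# Network builders: a fully convolutional encoder-decoder generator with
# densely connected blocks, and a six-layer multi-scale feature-extraction
# discriminator. Both are pure architecture definitions with strict
# shape/channel contracts; training lives in train.R.

#' Dense block specification
#'
#' A densely connected block applies `n_layers` units, each
#' batch-normalization -> ReLU -> 3x3 convolution emitting `growth` channels,
#' and concatenates every unit's output onto its input along the channel axis,
#' so the block output carries `in_channels + n_layers * growth` channels.
#'
#' @param n_layers number of convolutional units in the block.
#' @param growth channels added by each unit.
#' @return a `dense_block_spec` list.
#' @export
dense_block_spec <- function(n_layers = 4L, growth = 3L) {
  stopifnot(n_layers >= 0, growth >= 1)
  structure(list(n_layers = as.integer(n_layers), growth = as.integer(growth)),
            class = "dense_block_spec")
}

dense_block_out_channels <- function(spec, in_channels) {
  in_channels + spec$n_layers * spec$growth
}

build_dense_block <- function(in_channels, spec) {
  layers <- vector("list", spec$n_layers)
  cin <- in_channels
  for (j in seq_len(spec$n_layers)) {
    layers[[j]] <- list(
      bn = layer_bn(cin),
      conv = layer_conv(cin, spec$growth, kernel = 3L))
    cin <- cin + spec$growth
  }
  e <- new.env(parent = emptyenv())
  e$type <- "dense_block"
  e$layers <- layers
  e$in_channels <- as.integer(in_channels)
  e$growth <- spec$growth
  e$out_channels <- as.integer(cin)
  class(e) <- c("dense_block", "nn_module")
  e
}

# Forward/backward run through fused kernels covering the whole block
# (per-unit BN -> ReLU -> 3x3 conv, concatenated); the per-unit layer
# environments remain the owners of parameters and running statistics.
#' @export
nn_forward.dense_block <- function(layer, x, training = FALSE) {
  ls <- layer$layers
  if (length(ls) == 0L) return(list(y = x, cache = NULL))
  r <- .dense_forward(x,
    lapply(ls, function(l) l$bn$gamma),
    lapply(ls, function(l) l$bn$beta),
    lapply(ls, function(l) l$bn$running_mean),
    lapply(ls, function(l) l$bn$running_var),
    lapply(ls, function(l) l$conv$W),
    lapply(ls, function(l) l$conv$b),
    ls[[1]]$bn$eps, training)
  if (training) {
    for (j in seq_along(ls)) {
      bn <- ls[[j]]$bn
      bn$running_mean <- (1 - bn$momentum) * bn$running_mean +
        bn$momentum * r$mu[[j]]
      bn$running_var <- (1 - bn$momentum) * bn$running_var +
        bn$momentum * r$var[[j]]
    }
  }
  list(y = r$y, cache = list(xhat = r$xhat, act = r$act, istd = r$istd,
                             training = training))
}

#' @export
nn_backward.dense_block <- function(layer, cache, dy, want_params = TRUE) {
  ls <- layer$layers
  if (length(ls) == 0L) return(list(dx = dy, grads = list()))
  r <- .dense_backward(dy, cache$xhat, cache$act, cache$istd,
                       lapply(ls, function(l) l$bn$gamma),
                       lapply(ls, function(l) l$conv$W),
                       cache$training, want_params)
  grads <- list()
  if (want_params) {
    for (j in seq_along(ls)) {
      grads[[sprintf("l%d.conv.W", j)]] <- r$dw[[j]]
      grads[[sprintf("l%d.conv.b", j)]] <- r$db[[j]]
      grads[[sprintf("l%d.bn.gamma", j)]] <- r$dgamma[[j]]
      grads[[sprintf("l%d.bn.beta", j)]] <- r$dbeta[[j]]
    }
  }
  list(dx = r$dx, grads = grads)
}

#' @export
nn_param_refs.dense_block <- function(module) {
  refs <- list()
  for (j in seq_along(module$layers)) {
    lj <- module$layers[[j]]
    refs <- c(refs,
      refs_prefix(nn_param_refs(lj$bn), sprintf("l%d.bn", j)),
      refs_prefix(nn_param_refs(lj$conv), sprintf("l%d.conv", j)))
  }
  refs
}

# ---- generator -------------------------------------------------------------

#' Generator configuration
#'
#' The generator is an end-to-end segmentation network with a U-Net-like
#' encoder-decoder topology: a 3x3 stem convolution, then three stages of
#' dense block -> 1x1 transition -> 2x2 max pool on the way down, and three
#' stages of 2x2 transposed convolution -> skip concatenation -> dense block
#' -> 1x1 transition on the way up, closed by a 1x1 convolution and a sigmoid
#' so the output is a per-pixel foreground probability in [0, 1].
#'
#' @param in_channels input channels (1 for grayscale CT slices).
#' @param base_channels channels emitted by the stem convolution.
#' @param dense a [dense_block_spec()] shared by all blocks.
#' @param n_scales number of pool/up-sample stages (3: input sizes must be
#'   divisible by 8).
#' @param compression channel fraction kept by the 1x1 encoder transitions
#'   (DenseNet-style compression keeping channel growth bounded).
#' @param dec_channels channel width of the decoder transitions and
#'   transposed convolutions.
#' @return a `generator_config` list.
#' @export
generator_config <- function(in_channels = 1L, base_channels = 6L,
                             dense = dense_block_spec(),
                             n_scales = 3L, compression = 0.5,
                             dec_channels = 2L * base_channels) {
  stopifnot(in_channels >= 1, base_channels >= 1,
            inherits(dense, "dense_block_spec"),
            n_scales == 3L, compression > 0, compression <= 1,
            dec_channels >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 dense = dense, n_scales = 3L,
                 compression = compression,
                 dec_channels = as.integer(dec_channels)),
            class = "generator_config")
}

#' Build the segmentation generator
#'
#' @param config a [generator_config()].
#' @return a `seg_generator` module. Apply it with [predict_slices()] or the
#'   lower-level `gen_forward()`.
#' @export
build_generator <- function(config = generator_config()) {
  g <- new.env(parent = emptyenv())
  g$config <- config
  g$stem <- layer_conv(config$in_channels, config$base_channels, kernel = 3L)
  cin <- config$base_channels
  g$enc <- vector("list", 3L)
  skip_channels <- integer(3L)
  for (s in 1:3) {
    db <- build_dense_block(cin, config$dense)
    tout <- max(1L, as.integer(floor(db$out_channels * config$compression)))
    trans <- layer_conv(db$out_channels, tout, kernel = 1L, pad = 0L)
    g$enc[[s]] <- list(db = db, trans = trans)
    skip_channels[s] <- tout
    cin <- tout
  }
  g$skip_channels <- skip_channels
  g$dec <- vector("list", 3L)
  up_in <- cin                      # bottom channels
  for (s in 3:1) {
    up <- layer_convt(up_in, config$dec_channels, kernel = 2L, stride = 2L)
    db <- build_dense_block(config$dec_channels + skip_channels[s], config$dense)
    trans <- layer_conv(db$out_channels, config$dec_channels, kernel = 1L, pad = 0L)
    g$dec[[s]] <- list(up = up, db = db, trans = trans)
    up_in <- config$dec_channels
  }
  g$head <- layer_conv(config$dec_channels, 1L, kernel = 1L, pad = 0L)
  g$out_act <- layer_act("sigmoid")
  class(g) <- c("seg_generator", "nn_module")
  g
}

#' @export
print.seg_generator <- function(x, ...) {
  cat("<seg_generator>",
      sprintf("base %d, growth %d x %d layers/block, decoder width %d",
              x$config$base_channels, x$config$dense$growth,
              x$config$dense$n_layers, x$config$dec_channels),
      sprintf("trainable parameters: %d", as.integer(count_parameters(x))),
      sep = "\n")
  invisible(x)
}

#' Generator forward pass
#'
#' Low-level forward pass over an `(H, W, C, N)` batch; spatial sizes must be
#' divisible by 8. Returns the probability maps plus the tape of caches that
#' [gen_backward()] consumes.
#'
#' @param g a [build_generator()] network.
#' @param x input tensor `(H, W, C, N)`.
#' @param training `TRUE` for batch-statistics mode (updates running stats).
#' @return list with `y` (probability maps, same spatial size, one channel)
#'   and `tape`.
#' @export
gen_forward <- function(g, x, training = FALSE) {
  d <- dim(x)
  if (length(d) != 4L || d[3] != g$config$in_channels) {
    abort("generator input must be an (H, W, C, N) array with matching channels")
  }
  check_divisible(d[1], d[2], 8L)
  tape <- list()
  st <- nn_forward(g$stem, x, training)
  tape$stem <- st$cache
  h <- st$y
  skips <- vector("list", 3L)
  tape$enc <- vector("list", 3L)
  for (s in 1:3) {
    db <- nn_forward(g$enc[[s]]$db, h, training)
    tr <- nn_forward(g$enc[[s]]$trans, db$y, training)
    pl <- maxpool_forward(tr$y, 2L)
    tape$enc[[s]] <- list(db = db$cache, trans = tr$cache, pool_idx = pl$idx,
                          pre_pool_dim = dim(tr$y))
    skips[[s]] <- tr$y
    h <- pl$y
  }
  tape$dec <- vector("list", 3L)
  for (s in 3:1) {
    up <- nn_forward(g$dec[[s]]$up, h, training)
    cat_in <- ccat(up$y, skips[[s]])
    db <- nn_forward(g$dec[[s]]$db, cat_in, training)
    tr <- nn_forward(g$dec[[s]]$trans, db$y, training)
    tape$dec[[s]] <- list(up = up$cache, db = db$cache, trans = tr$cache,
                          up_channels = dim(up$y)[3])
    h <- tr$y
  }
  hd <- nn_forward(g$head, h, training)
  act <- nn_forward(g$out_act, hd$y, training)
  tape$head <- hd$cache
  tape$out_act <- act$cache
  list(y = act$y, tape = tape)
}

#' Generator backward pass
#'
#' @param g a [build_generator()] network.
#' @param tape the tape from [gen_forward()].
#' @param dy gradient of the loss with respect to the output maps.
#' @param want_params also compute parameter gradients.
#' @return list with `dx` and flat named `grads`.
#' @export
gen_backward <- function(g, tape, dy, want_params = TRUE) {
  grads <- list()
  b <- nn_backward(g$out_act, tape$out_act, dy, want_params)
  b <- nn_backward(g$head, tape$head, b$dx, want_params)
  if (want_params) grads <- grad_merge(grads, grad_prefix(b$grads, "head"))
  dh <- b$dx
  d_skips <- vector("list", 3L)
  for (s in 1:3) {     # decoder stages were applied s = 3, 2, 1; reverse order
    tp <- tape$dec[[s]]
    bt <- nn_backward(g$dec[[s]]$trans, tp$trans, dh, want_params)
    bd <- nn_backward(g$dec[[s]]$db, tp$db, bt$dx, want_params)
    cu <- tp$up_channels
    d_up <- channel_slice(bd$dx, seq_len(cu))
    d_skips[[s]] <- channel_slice(bd$dx, cu + seq_len(dim(bd$dx)[3] - cu))
    bu <- nn_backward(g$dec[[s]]$up, tp$up, d_up, want_params)
    if (want_params) {
      pre <- sprintf("dec%d", s)
      grads <- grad_merge(grads, grad_prefix(bt$grads, paste0(pre, ".trans")))
      grads <- grad_merge(grads, grad_prefix(bd$grads, paste0(pre, ".db")))
      grads <- grad_merge(grads, grad_prefix(bu$grads, paste0(pre, ".up")))
    }
    dh <- bu$dx
  }
  for (s in 3:1) {     # encoder stages in reverse
    tp <- tape$enc[[s]]
    d_pre <- maxpool_backward(dh, tp$pool_idx, tp$pre_pool_dim[1], tp$pre_pool_dim[2])
    d_pre <- d_pre + d_skips[[s]]
    bt <- nn_backward(g$enc[[s]]$trans, tp$trans, d_pre, want_params)
    bd <- nn_backward(g$enc[[s]]$db, tp$db, bt$dx, want_params)
    if (want_params) {
      pre <- sprintf("enc%d", s)
      grads <- grad_merge(grads, grad_prefix(bt$grads, paste0(pre, ".trans")))
      grads <- grad_merge(grads, grad_prefix(bd$grads, paste0(pre, ".db")))
    }
    dh <- bd$dx
  }
  b <- nn_backward(g$stem, tape$stem, dh, want_params)
  if (want_params) grads <- grad_merge(grads, grad_prefix(b$grads, "stem"))
  list(dx = b$dx, grads = grads)
}

#' @export
nn_param_refs.seg_generator <- function(module) {
  refs <- refs_prefix(nn_param_refs(module$stem), "stem")
  for (s in 1:3) {
    refs <- c(refs,
      refs_prefix(nn_param_refs(module$enc[[s]]$db), sprintf("enc%d.db", s)),
      refs_prefix(nn_param_refs(module$enc[[s]]$trans), sprintf("enc%d.trans", s)))
  }
  for (s in 1:3) {
    refs <- c(refs,
      refs_prefix(nn_param_refs(module$dec[[s]]$up), sprintf("dec%d.up", s)),
      refs_prefix(nn_param_refs(module$dec[[s]]$db), sprintf("dec%d.db", s)),
      refs_prefix(nn_param_refs(module$dec[[s]]$trans), sprintf("dec%d.trans", s)))
  }
  c(refs, refs_prefix(nn_param_refs(module$head), "head"))
}

# ---- discriminator ---------------------------------------------------------

#' Discriminator configuration
#'
#' A six-layer multi-scale feature extractor. Every layer is convolution ->
#' batch-normalization -> leaky ReLU; the kernel-size schedule draws on
#' {7, 5, 4, 3}. The network consumes the channel-concatenation of an image
#' and a mask (it judges a mask in the context of its image) and returns the
#' ordered per-layer feature maps plus a scalar real/fake score per item from
#' a global-average-pool head.
#'
#' @param in_channels input channels after image/mask concatenation.
#' @param kernel_sizes per-layer spatial kernel sizes; must draw on {7,5,4,3}.
#' @param strides per-layer strides.
#' @param channels per-layer output channels.
#' @param leaky_slope negative slope of the leaky ReLU.
#' @return a `discriminator_config` list.
#' @export
discriminator_config <- function(in_channels = 2L,
                                 kernel_sizes = c(7L, 5L, 4L, 4L, 3L, 3L),
                                 strides = c(2L, 2L, 2L, 2L, 1L, 1L),
                                 channels = c(8L, 16L, 32L, 32L, 32L, 32L),
                                 leaky_slope = 0.2) {
  n <- length(kernel_sizes)
  stopifnot(n == 6L, length(strides) == n, length(channels) == n,
            all(kernel_sizes %in% c(7L, 5L, 4L, 3L)),
            all(strides >= 1L), all(channels >= 1L),
            leaky_slope > 0, leaky_slope < 1)
  structure(list(in_channels = as.integer(in_channels),
                 kernel_sizes = as.integer(kernel_sizes),
                 strides = as.integer(strides),
                 channels = as.integer(channels),
                 leaky_slope = leaky_slope),
            class = "discriminator_config")
}

#' Build the multi-scale feature discriminator
#'
#' @param config a [discriminator_config()].
#' @return a `seg_discriminator` module.
#' @export
build_discriminator <- function(config = discriminator_config()) {
  d <- new.env(parent = emptyenv())
  d$config <- config
  cin <- config$in_channels
  d$layers <- vector("list", 6L)
  for (i in 1:6) {
    k <- config$kernel_sizes[i]
    pad <- if (k %% 2L == 1L) k %/% 2L else (k - config$strides[i]) %/% 2L
    d$layers[[i]] <- list(
      conv = layer_conv(cin, config$channels[i], kernel = k,
                        stride = config$strides[i], pad = pad),
      bn = layer_bn(config$channels[i]),
      act = layer_act("lrelu", slope = config$leaky_slope))
    cin <- config$channels[i]
  }
  d$head_w <- matrix(rnorm(cin, sd = sqrt(1 / cin)), nrow = cin)
  d$head_b <- 0
  class(d) <- c("seg_discriminator", "nn_module")
  d
}

#' @export
print.seg_discriminator <- function(x, ...) {
  cat("<seg_discriminator>",
      sprintf("kernels [%s], strides [%s], channels [%s]",
              paste(x$config$kernel_sizes, collapse = ","),
              paste(x$config$strides, collapse = ","),
              paste(x$config$channels, collapse = ",")),
      sprintf("trainable parameters: %d", as.integer(count_parameters(x))),
      sep = "\n")
  invisible(x)
}

#' Discriminator forward pass
#'
#' Concatenates image and mask on the channel axis (the discriminator judges
#' a mask in the context of its image) and extracts the six-level feature
#' pyramid plus a scalar real/fake score per item.
#'
#' @param d a [build_discriminator()] network.
#' @param image,mask `(H, W, 1, N)` tensors of equal spatial/batch size.
#' @param training `TRUE` for batch-statistics mode.
#' @return list with `feats` (ordered per-layer feature maps), `score`
#'   (length-N), and `tape`.
#' @export
disc_forward <- function(d, image, mask, training = FALSE) {
  if (!identical(dim(image)[c(1, 2, 4)], dim(mask)[c(1, 2, 4)])) {
    abort("image and mask batches must share spatial size and batch size")
  }
  x <- ccat(image, mask)
  if (dim(x)[3] != d$config$in_channels) {
    abort("image + mask channel count does not match discriminator input channels")
  }
  feats <- vector("list", 6L)
  tape <- vector("list", 6L)
  h <- x
  for (i in 1:6) {
    li <- d$layers[[i]]
    cv <- nn_forward(li$conv, h, training)
    bn <- nn_forward(li$bn, cv$y, training)
    ac <- nn_forward(li$act, bn$y, training)
    tape[[i]] <- list(conv = cv$cache, bn = bn$cache, act = ac$cache)
    feats[[i]] <- ac$y
    h <- ac$y
  }
  # decision head: global average pool -> linear
  dl <- dim(h)
  hm <- matrix(h, nrow = dl[1] * dl[2])           # (H*W, C*N)
  pooled <- matrix(colMeans(hm), nrow = dl[3])    # (C, N)
  score <- as.numeric(crossprod(d$head_w, pooled)) + d$head_b
  list(feats = feats, score = score,
       tape = list(layers = tape, pooled = pooled, feat_dim = dl))
}

#' Discriminator backward pass
#'
#' @param d a [build_discriminator()] network.
#' @param tape the tape from [disc_forward()].
#' @param dfeats list of per-level feature gradients (`NULL` entries allowed).
#' @param dscore gradient on the scalar scores, or `NULL`.
#' @param want_params also compute parameter gradients.
#' @return list with `dx` (gradient on the concatenated input: channel 1 the
#'   image, channel 2 the mask) and flat named `grads`.
#' @export
disc_backward <- function(d, tape, dfeats = NULL, dscore = NULL,
                          want_params = TRUE) {
  grads <- list()
  dl <- tape$feat_dim
  dh <- NULL
  if (!is.null(dscore)) {
    dpooled <- d$head_w %*% matrix(dscore, nrow = 1)      # (C, N)
    dh <- array(rep(as.numeric(dpooled), each = dl[1] * dl[2]) / (dl[1] * dl[2]),
                dim = dl)
    if (want_params) {
      grads$head.W <- tape$pooled %*% matrix(dscore, ncol = 1)
      grads$head.b <- sum(dscore)
    }
  }
  for (i in 6:1) {
    if (!is.null(dfeats) && !is.null(dfeats[[i]])) dh <- gadd(dh, dfeats[[i]])
    if (is.null(dh)) next
    li <- d$layers[[i]]
    tp <- tape$layers[[i]]
    b <- nn_backward(li$act, tp$act, dh, want_params)
    b2 <- nn_backward(li$bn, tp$bn, b$dx, want_params)
    b3 <- nn_backward(li$conv, tp$conv, b2$dx, want_params)
    if (want_params) {
      grads <- grad_merge(grads, grad_prefix(b2$grads, sprintf("d%d.bn", i)))
      grads <- grad_merge(grads, grad_prefix(b3$grads, sprintf("d%d.conv", i)))
    }
    dh <- b3$dx
  }
  list(dx = dh, grads = grads)
}

#' @export
nn_param_refs.seg_discriminator <- function(module) {
  refs <- list()
  for (i in 1:6) {
    refs <- c(refs,
      refs_prefix(nn_param_refs(module$layers[[i]]$bn), sprintf("d%d.bn", i)),
      refs_prefix(nn_param_refs(module$layers[[i]]$conv), sprintf("d%d.conv", i)))
  }
  refs$head.W <- list(env = module, field = "head_w", decay = TRUE)
  refs$head.b <- list(env = module, field = "head_b", decay = FALSE)
  refs
}

#' Count trainable parameters of a network
#'
#' @param network a built generator, discriminator, or any module with
#'   parameter references.
#' @return total number of trainable scalar parameters.
#' @export
count_parameters <- function(network) {
  nn_count_params(nn_param_refs(network))
}
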