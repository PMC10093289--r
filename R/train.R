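# Alternating adversarial training: per batch the discriminator is updated
# to maximise the multi-scale feature MAE between (image, truth) and
# (image, generated) pairs, then the generator is updated to minimise the
# composite Dice + feature-MAE objective. Stochastic gradient descent with
# momentum and weight decay throughout; every random draw goes through R's
# RNG so a fixed seed reproduces the run bit-exactly on a single CPU thread.

#' Training configuration
#'
#' Defaults follow the reference optimiser settings: learning rate 1e-4,
#' weight decay 1e-4, momentum 0.9, read as stochastic gradient descent with
#' momentum (the only optimiser consistent with that triplet).
#'
#' @param learning_rate SGD learning rate, > 0.
#' @param weight_decay L2 penalty applied to convolution weights.
#' @param momentum SGD momentum.
#' @param batch_size items per batch, >= 1.
#' @param epochs training epochs, >= 1.
#' @param loss_weights a [loss_weights()] (default: unit weights, eps = 1);
#'   `delta = 0` disables the adversarial term (plain Dice training).
#' @param d_steps_per_g_step discriminator updates per generator update.
#' @param seed RNG seed for shuffling and weight initialisation downstream.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-4,
                         momentum = 0.9, batch_size = 1L, epochs = 12L,
                         loss_weights = NULL,
                         d_steps_per_g_step = 1L, seed = 1L) {
  if (is.null(loss_weights)) loss_weights <- ganseg_loss_weights_default()
  stopifnot(learning_rate > 0, weight_decay >= 0, momentum >= 0, momentum < 1,
            batch_size >= 1, epochs >= 1, d_steps_per_g_step >= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), loss_weights = loss_weights,
                 d_steps_per_g_step = as.integer(d_steps_per_g_step),
                 seed = as.integer(seed)),
            class = "train_config")
}

ganseg_loss_weights_default <- function() loss_weights()

sgd_step <- function(refs, grads, lr, momentum, weight_decay) {
  for (nm in names(grads)) {
    r <- refs[[nm]]
    if (is.null(r)) next
    g <- grads[[nm]]
    p <- r$env[[r$field]]
    if (!is.null(dim(p)) && is.null(dim(g))) dim(g) <- dim(p)
    if (r$decay && weight_decay > 0) g <- g + weight_decay * p
    vfield <- paste0(".v_", r$field)
    v <- r$env[[vfield]]
    if (is.null(v)) v <- 0
    v <- momentum * v - lr * g
    r$env[[vfield]] <- v
    r$env[[r$field]] <- p + v
  }
}

# extract (image, mask) batch tensors from a list of pairs
pairs_batch <- function(pairs, idx) {
  list(x = as_batch(purrr::map(pairs[idx], "image")),
       y = as_batch(purrr::map(pairs[idx], function(p) p$mask + 0)))
}

as_pair_list <- function(data) {
  if (inherits(data, "phantom_dataset")) return(data$pairs)
  stopifnot(is.list(data))
  data
}

check_finite_loss <- function(value, term, epoch) {
  if (!is.finite(value)) {
    abort(sprintf("non-finite %s (%g) at epoch %d; training aborted",
                  term, value, epoch))
  }
  value
}

#' Train the adversarial segmentation model
#'
#' Per batch the discriminator is updated first (minimising
#' [discriminator_objective()]), then the generator (minimising
#' [generator_objective()]). With `delta = 0` in the loss weights the
#' pipeline degenerates to plain soft-Dice training and the discriminator is
#' left untouched.
#'
#' @param gen a [build_generator()] network (updated in place).
#' @param disc a [build_discriminator()] network (updated in place), or
#'   `NULL` when `delta = 0`.
#' @param train_set,val_set `phantom_dataset`s or lists of pairs with
#'   `image` and `mask` matrices.
#' @param config a [train_config()].
#' @return a `train_history` tibble (one row per epoch: generator loss,
#'   discriminator loss, training soft-Dice, validation loss, validation
#'   soft-Dice), with the config as attribute. The trained networks are the
#'   (modified) `gen` and `disc` arguments.
#' @export
train <- function(gen, disc, train_set, val_set, config = train_config()) {
  stopifnot(inherits(gen, "seg_generator"), inherits(config, "train_config"))
  w <- config$loss_weights
  adversarial <- w$delta > 0
  if (adversarial && !inherits(disc, "seg_discriminator")) {
    abort("an adversarial run (delta > 0) needs a discriminator")
  }
  tr <- as_pair_list(train_set)
  va <- as_pair_list(val_set)
  if (length(tr) == 0) abort("empty training set")
  if (length(va) == 0) abort("empty validation set")
  g_refs <- nn_param_refs(gen)
  d_refs <- if (adversarial) nn_param_refs(disc) else NULL
  set.seed(config$seed)
  n <- length(tr)
  history <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    g_losses <- d_losses <- dices <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      b <- pairs_batch(tr, batches[[bi]])
      nb <- dim(b$x)[4]
      gf <- gen_forward(gen, b$x, training = TRUE)
      pred <- gf$y

      d_loss <- 0
      if (adversarial) {
        for (dstep in seq_len(config$d_steps_per_g_step)) {
          fr <- disc_forward(disc, b$x, b$y, training = TRUE)
          ff <- disc_forward(disc, b$x, pred, training = TRUE)
          mae <- mae_term(fr$feats, ff$feats)
          d_loss <- check_finite_loss(-w$delta * mae,
                                      "discriminator loss", epoch)
          dmf <- mae_term_grad_fake(fr$feats, ff$feats)
          # D maximises the MAE: dL_D/dfake = -delta * dmae/dfake, and the
          # real branch carries the opposite sign of the same element-wise
          # gradient (|r - f| is antisymmetric in its arguments)
          d_fake <- purrr::map(dmf, function(g) -w$delta * g)
          d_real <- purrr::map(dmf, function(g) w$delta * g)
          gr_f <- disc_backward(disc, ff$tape, dfeats = d_fake,
                                want_params = TRUE)
          gr_r <- disc_backward(disc, fr$tape, dfeats = d_real,
                                want_params = TRUE)
          sgd_step(d_refs, grad_merge(gr_f$grads, gr_r$grads),
                   config$learning_rate, config$momentum, config$weight_decay)
        }
      }

      # generator step against the updated discriminator
      dice_vals <- vapply(seq_len(nb), function(i) {
        dice_term(pred[, , , i, drop = FALSE], b$y[, , , i, drop = FALSE], w$eps)
      }, numeric(1))
      dpred <- array(0, dim(pred))
      for (i in seq_len(nb)) {
        dpred[, , , i] <- w$lam / nb *
          dice_term_grad(pred[, , , i, drop = FALSE],
                         b$y[, , , i, drop = FALSE], w$eps)
      }
      adv <- 0
      if (adversarial) {
        fr2 <- disc_forward(disc, b$x, b$y, training = TRUE)
        ff2 <- disc_forward(disc, b$x, pred, training = TRUE)
        adv <- mae_term(fr2$feats, ff2$feats)
        d_fake2 <- purrr::map(mae_term_grad_fake(fr2$feats, ff2$feats),
                              function(g) w$delta * g)
        din <- disc_backward(disc, ff2$tape, dfeats = d_fake2,
                             want_params = FALSE)
        # input gradient: channel 1 is the image (constant), channel 2 the mask
        dpred <- dpred + channel_slice(din$dx, 2L)
      }
      g_loss <- check_finite_loss(w$lam * mean(dice_vals) + w$delta * adv,
                                  "generator loss", epoch)
      gb <- gen_backward(gen, gf$tape, dpred)
      sgd_step(g_refs, gb$grads,
               config$learning_rate, config$momentum, config$weight_decay)

      g_losses[bi] <- g_loss
      # log D's loss on this batch against its post-update features: the
      # exact negation of the MAE component the generator just faced
      d_losses[bi] <- if (adversarial) -w$delta * adv else 0
      dices[bi] <- -mean(dice_vals)
    }
    val <- validation_pass(gen, if (adversarial) disc else NULL, va, w)
    history[[epoch]] <- tibble(
      epoch = epoch,
      g_loss = mean(g_losses), d_loss = mean(d_losses),
      train_dice = mean(dices),
      val_loss = val$loss, val_dice = val$dice)
  }
  out <- purrr::list_rbind(history)
  attr(out, "config") <- config
  class(out) <- c("train_history", class(out))
  out
}

# evaluation-mode pass over the validation set: soft Dice plus, when a
# discriminator is supplied, the full composite objective
validation_pass <- function(gen, disc, pairs, w, batch_size = 8L) {
  n <- length(pairs)
  dice_sum <- 0; adv_sum <- 0; nb_adv <- 0
  idxs <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  for (idx in idxs) {
    b <- pairs_batch(pairs, idx)
    gf <- gen_forward(gen, b$x, training = FALSE)
    for (i in seq_along(idx)) {
      dice_sum <- dice_sum + dice_term(gf$y[, , , i, drop = FALSE],
                                       b$y[, , , i, drop = FALSE], w$eps)
    }
    if (!is.null(disc)) {
      fr <- disc_forward(disc, b$x, b$y, training = FALSE)
      ff <- disc_forward(disc, b$x, gf$y, training = FALSE)
      adv_sum <- adv_sum + mae_term(fr$feats, ff$feats)
      nb_adv <- nb_adv + 1
    }
  }
  mean_dice_term <- dice_sum / n
  adv <- if (nb_adv > 0) adv_sum / nb_adv else 0
  list(loss = w$lam * mean_dice_term + w$delta * adv, dice = -mean_dice_term)
}

#' Predict segmentation masks for image slices
#'
#' Images whose sides are not divisible by 8 are zero-padded symmetrically
#' and the outputs cropped back.
#'
#' @param gen trained generator, or a function taking a list of image
#'   matrices and returning a list of probability matrices (useful as an
#'   oracle stub when validating the evaluation pipeline).
#' @param images a matrix, list of matrices, or `(H, W, 1, N)` array.
#' @param threshold binarisation threshold for the probability maps.
#' @param batch_size forward-pass batch size.
#' @return list with `prob` (list of probability matrices) and `mask` (list
#'   of binary matrices), input order preserved.
#' @export
predict_slices <- function(gen, images, threshold = 0.5, batch_size = 8L) {
  if (is.matrix(images)) images <- list(images)
  if (is.array(images) && length(dim(images)) == 4) {
    images <- purrr::map(seq_len(dim(images)[4]), function(i) images[, , 1, i])
  }
  if (is.function(gen)) {
    probs <- gen(images)
    return(list(prob = probs,
                mask = purrr::map(probs, function(p) {
                  matrix(as.integer(p >= threshold), nrow(p), ncol(p))
                })))
  }
  probs <- vector("list", length(images))
  idxs <- split(seq_along(images), ceiling(seq_along(images) / batch_size))
  for (idx in idxs) {
    grp <- images[idx]
    d0 <- dim(grp[[1]])
    ph <- (8 - d0[1] %% 8) %% 8
    pw <- (8 - d0[2] %% 8) %% 8
    top <- ph %/% 2; left <- pw %/% 2
    padded <- purrr::map(grp, function(im) {
      if (ph == 0 && pw == 0) return(im)
      out <- matrix(0, d0[1] + ph, d0[2] + pw)
      out[top + seq_len(d0[1]), left + seq_len(d0[2])] <- im
      out
    })
    gf <- gen_forward(gen, as_batch(padded), training = FALSE)
    for (k in seq_along(idx)) {
      p <- gf$y[, , 1, k]
      probs[[idx[k]]] <- p[top + seq_len(d0[1]), left + seq_len(d0[2]), drop = FALSE]
    }
  }
  list(prob = probs,
       mask = purrr::map(probs, function(p) {
         matrix(as.integer(p >= threshold), nrow(p), ncol(p))
       }))
}

#' Evaluate a generator on a test set
#'
#' Binarises the predicted probability maps and computes all six metrics per
#' slice, then aggregates them.
#'
#' @param gen trained generator.
#' @param test_set `phantom_dataset` or list of pairs.
#' @param spacing physical pixel spacing `c(row_mm, col_mm)`.
#' @param threshold binarisation threshold.
#' @return a [aggregate_metrics()] `metric_report`.
#' @export
evaluate <- function(gen, test_set, spacing = c(1, 1), threshold = 0.5) {
  pairs <- as_pair_list(test_set)
  if (length(pairs) == 0) abort("empty test set")
  pr <- predict_slices(gen, purrr::map(pairs, "image"), threshold = threshold)
  rows <- purrr::list_rbind(purrr::map(seq_along(pairs), function(i) {
    slice_metrics(pr$mask[[i]], pairs[[i]]$mask, spacing)
  }))
  n_na_asd <- sum(is.na(rows$asd))
  if (n_na_asd > 0) {
    warn(sprintf("average surface distance undefined on %d slice(s) (empty mask); excluded from aggregation",
                 n_na_asd))
  }
  aggregate_metrics(rows)
}

# ---- checkpoints -----------------------------------------------------------

module_state <- function(module) {
  refs <- nn_param_refs(module)
  state <- purrr::map(refs, function(r) r$env[[r$field]])
  # batch-norm running statistics are persistent state but not trainable
  for (nm in names(refs)[grepl("gamma$", names(refs))]) {
    e <- refs[[nm]]$env
    base <- sub("gamma$", "", nm)
    state[[paste0(base, "running_mean")]] <- e$running_mean
    state[[paste0(base, "running_var")]] <- e$running_var
  }
  state
}

module_load_state <- function(module, state) {
  refs <- nn_param_refs(module)
  for (nm in names(refs)) {
    if (is.null(state[[nm]])) abort(sprintf("checkpoint missing parameter '%s'", nm))
    r <- refs[[nm]]
    cur <- r$env[[r$field]]
    new <- state[[nm]]
    if (length(cur) != length(new)) {
      abort(sprintf("checkpoint/config mismatch for '%s': %d vs %d values",
                    nm, length(new), length(cur)))
    }
    if (!is.null(dim(cur))) dim(new) <- dim(cur)
    r$env[[r$field]] <- new
    if (grepl("gamma$", nm)) {
      base <- sub("gamma$", "", nm)
      r$env$running_mean <- as.numeric(state[[paste0(base, "running_mean")]])
      r$env$running_var <- as.numeric(state[[paste0(base, "running_var")]])
    }
  }
  invisible(module)
}

#' Save generator/discriminator weights and configs to an RDS checkpoint
#'
#' @param path output file.
#' @param gen generator (may be `NULL`).
#' @param disc discriminator (may be `NULL`).
#' @param history optional `train_history`.
#' @param extra optional list stored verbatim.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(path, gen = NULL, disc = NULL, history = NULL,
                            extra = list()) {
  ck <- list(
    gen_config = if (!is.null(gen)) gen$config,
    gen_state = if (!is.null(gen)) module_state(gen),
    disc_config = if (!is.null(disc)) disc$config,
    disc_state = if (!is.null(disc)) module_state(disc),
    history = history,
    extra = extra,
    package_version = as.character(utils::packageVersion("ganseg")))
  saveRDS(ck, path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint file.
#' @return list with rebuilt `gen`, `disc` (either may be `NULL`), `history`
#'   and `extra`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  gen <- NULL; disc <- NULL
  if (!is.null(ck$gen_config)) {
    gen <- build_generator(ck$gen_config)
    module_load_state(gen, ck$gen_state)
  }
  if (!is.null(ck$disc_config)) {
    disc <- build_discriminator(ck$disc_config)
    module_load_state(disc, ck$disc_state)
  }
  list(gen = gen, disc = disc, history = ck$history, extra = ck$extra)
}

#' Split a dataset into train/validation/test partitions
#'
#' @param dataset `phantom_dataset` or list of pairs.
#' @param fractions length-3 non-negative weights summing to 1.
#' @param seed shuffling seed.
#' @return list of three pair lists: `train`, `val`, `test`.
#' @export
split_dataset <- function(dataset, fractions = c(0.7, 0.15, 0.15), seed = 1L) {
  stopifnot(length(fractions) == 3, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8)
  pairs <- as_pair_list(dataset)
  n <- length(pairs)
  set.seed(seed)
  ord <- sample.int(n)
  n_tr <- round(fractions[1] * n)
  n_va <- round(fractions[2] * n)
  list(train = pairs[ord[seq_len(n_tr)]],
       val = pairs[ord[n_tr + seq_len(n_va)]],
       test = pairs[ord[(n_tr + n_va + 1):n]])
}
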