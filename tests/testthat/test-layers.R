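# Numerical gradient verification of every differentiable primitive and of
# the assembled networks. Central differences on tiny tensors; relative
# error thresholds are loose enough for double-precision round-off only.

num_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
`%||%` <- function(a, b) if (is.null(a)) b else a

rel_err <- function(a, b) max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))

test_that("convolution layers backpropagate exactly", {
  set.seed(1)
  nf <- ganseg:::nn_forward; nb <- ganseg:::nn_backward
  for (cfg in list(list(k = 3L, s = 1L), list(k = 4L, s = 2L))) {
    l <- ganseg:::layer_conv(2L, 3L, kernel = cfg$k, stride = cfg$s,
                             pad = if (cfg$k %% 2) cfg$k %/% 2L else 1L)
    x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
    fw <- nf(l, x)
    dy <- array(rnorm(length(fw$y)), dim(fw$y))
    bk <- nb(l, fw$cache, dy)
    gx <- num_grad(function(z) sum(nf(l, z)$y * dy), x)
    expect_lt(rel_err(bk$dx, gx), 1e-6)
    W0 <- l$W
    gw <- num_grad(function(z) { l$W <- array(z, dim(W0)); on.exit(l$W <- W0)
                                 sum(nf(l, x)$y * dy) }, W0)
    expect_lt(rel_err(bk$grads$W, gw), 1e-6)
  }
})

test_that("transposed convolution is the exact adjoint and backpropagates", {
  set.seed(2)
  nf <- ganseg:::nn_forward; nb <- ganseg:::nn_backward
  l <- ganseg:::layer_convt(3L, 2L, kernel = 2L, stride = 2L)
  x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  fw <- nf(l, x)
  expect_identical(dim(fw$y), c(8L, 8L, 2L, 2L))
  dy <- array(rnorm(length(fw$y)), dim(fw$y))
  bk <- nb(l, fw$cache, dy)
  gx <- num_grad(function(z) sum(nf(l, z)$y * dy), x)
  expect_lt(rel_err(bk$dx, gx), 1e-6)
  W0 <- l$W
  gw <- num_grad(function(z) { l$W <- array(z, dim(W0)); on.exit(l$W <- W0)
                               sum(nf(l, x)$y * dy) }, W0)
  expect_lt(rel_err(bk$grads$W, gw), 1e-6)
})

test_that("batch normalization backpropagates in both modes", {
  set.seed(3)
  nf <- ganseg:::nn_forward; nb <- ganseg:::nn_backward
  x <- array(rnorm(5 * 5 * 3 * 2, sd = 2), c(5, 5, 3, 2))
  for (training in c(TRUE, FALSE)) {
    l <- ganseg:::layer_bn(3L)
    l$running_mean <- rnorm(3); l$running_var <- runif(3, 0.5, 2)
    fw <- nf(l, x, training = training)
    dy <- array(rnorm(length(fw$y)), dim(fw$y))
    bk <- nb(l, fw$cache, dy)
    mk <- function(z) {
      l2 <- ganseg:::layer_bn(3L)
      l2$gamma <- l$gamma; l2$beta <- l$beta
      l2$running_mean <- l$running_mean; l2$running_var <- l$running_var
      sum(nf(l2, z, training = training)$y * dy)
    }
    expect_lt(rel_err(bk$dx, num_grad(mk, x)), 1e-5)
    g0 <- l$gamma
    gg <- num_grad(function(z) { l$gamma <- as.numeric(z); on.exit(l$gamma <- g0)
                                 sum(nf(l, x, training = training)$y * dy) },
                   g0)
    expect_lt(rel_err(bk$grads$gamma, gg), 1e-5)
  }
  # running statistics converge toward batch statistics under repeated passes
  l <- ganseg:::layer_bn(3L, momentum = 0.5)
  for (i in 1:20) invisible(nf(l, x, training = TRUE))
  expect_lt(max(abs(l$running_mean - apply(x, 3, mean))), 1e-3)
})

test_that("activations and pooling backpropagate", {
  set.seed(4)
  nf <- ganseg:::nn_forward; nb <- ganseg:::nn_backward
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  for (kind in c("relu", "lrelu", "sigmoid")) {
    l <- ganseg:::layer_act(kind)
    fw <- nf(l, x)
    dy <- array(rnorm(length(fw$y)), dim(fw$y))
    bk <- nb(l, fw$cache, dy)
    expect_lt(rel_err(bk$dx, num_grad(function(z) sum(nf(l, z)$y * dy), x)),
              1e-5)
  }
  mp <- ganseg:::maxpool_forward(x, 2L)
  dy <- array(rnorm(length(mp$y)), dim(mp$y))
  dx <- ganseg:::maxpool_backward(dy, mp$idx, 6L, 6L)
  gx <- num_grad(function(z) sum(ganseg:::maxpool_forward(z, 2L)$y * dy), x)
  expect_lt(rel_err(dx, gx), 1e-5)
})

test_that("the assembled generator backpropagates the dice objective", {
  set.seed(6)
  g <- build_generator(tiny_gen_config())
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 1, 2))
  loss_of <- function() {
    fw <- gen_forward(g, x)
    (dice_term(fw$y[, , , 1, drop = FALSE], y[, , , 1, drop = FALSE]) +
     dice_term(fw$y[, , , 2, drop = FALSE], y[, , , 2, drop = FALSE])) / 2
  }
  fw <- gen_forward(g, x)
  dpred <- array(0, dim(fw$y))
  for (i in 1:2) {
    dpred[, , , i] <- ganseg:::dice_term_grad(
      fw$y[, , , i, drop = FALSE], y[, , , i, drop = FALSE]) / 2
  }
  gb <- gen_backward(g, fw$tape, dpred)
  refs <- ganseg:::nn_param_refs(g)
  expect_setequal(names(gb$grads), names(refs))
  set.seed(7)
  for (nm in sample(names(refs), 10)) {
    r <- refs[[nm]]
    p <- r$env[[r$field]]
    i <- sample(length(p), 1)
    eps <- 1e-5; p0 <- p[i]
    r$env[[r$field]][i] <- p0 + eps; lp <- loss_of()
    r$env[[r$field]][i] <- p0 - eps; lm <- loss_of()
    r$env[[r$field]][i] <- p0
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - gb$grads[[nm]][i]) /
                max(1e-6, abs(num) + abs(gb$grads[[nm]][i])), 1e-4)
  }
})

test_that("the assembled discriminator backpropagates the feature MAE", {
  set.seed(8)
  d <- build_discriminator(discriminator_config(channels = rep(4L, 6)))
  xi <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  mr <- array(rbinom(32 * 32 * 2, 1, 0.3), c(32, 32, 1, 2))
  mf <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  loss_of <- function() {
    fr <- disc_forward(d, xi, mr)
    ff <- disc_forward(d, xi, mf)
    mae_term(fr$feats, ff$feats)
  }
  fr <- disc_forward(d, xi, mr)
  ff <- disc_forward(d, xi, mf)
  gm <- ganseg:::mae_term_grad_fake(fr$feats, ff$feats)
  grf <- disc_backward(d, ff$tape, dfeats = gm)
  grr <- disc_backward(d, fr$tape, dfeats = purrr::map(gm, function(z) -z))
  gall <- ganseg:::grad_merge(grf$grads, grr$grads)
  refs <- ganseg:::nn_param_refs(d)
  set.seed(9)
  for (nm in sample(setdiff(names(refs), c("head.W", "head.b")), 8)) {
    r <- refs[[nm]]
    p <- r$env[[r$field]]
    i <- sample(length(p), 1)
    eps <- 1e-5; p0 <- p[i]
    r$env[[r$field]][i] <- p0 + eps; lp <- loss_of()
    r$env[[r$field]][i] <- p0 - eps; lm <- loss_of()
    r$env[[r$field]][i] <- p0
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - gall[[nm]][i]) /
                max(1e-6, abs(num) + abs(gall[[nm]][i])), 1e-4)
  }
  # the scalar decision head backpropagates too
  sc <- disc_forward(d, xi, mr)
  gh <- disc_backward(d, sc$tape, dscore = c(1, -1))
  w0 <- d$head_w
  gnum <- num_grad(function(z) {
    d$head_w <- matrix(z, ncol = 1); on.exit(d$head_w <- w0)
    sum(disc_forward(d, xi, mr)$score * c(1, -1))
  }, as.numeric(w0))
  expect_lt(rel_err(as.numeric(gh$grads$head.W), as.numeric(gnum)), 1e-5)
})
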