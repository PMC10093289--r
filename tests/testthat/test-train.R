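# Training-loop contracts on deliberately tiny problems (32x32 phantoms,
# narrow networks) so the suite stays fast; the full desk-scale convergence
# run lives in the acceptance tests.

tiny_run <- function(seed, epochs = 2L, delta = 1, n = 8L) {
  ds <- tiny_phantoms(n, seed = seed)
  set.seed(seed + 1L)
  gen <- build_generator(tiny_gen_config())
  disc <- if (delta > 0) {
    build_discriminator(discriminator_config(channels = rep(4L, 6)))
  } else NULL
  cfg <- train_config(epochs = epochs, batch_size = 4L,
                      loss_weights = loss_weights(delta = delta),
                      seed = seed + 2L)
  hist <- train(gen, disc, ds$pairs[1:(n - 2)], ds$pairs[(n - 1):n], cfg)
  list(gen = gen, disc = disc, hist = hist)
}

test_that("one epoch produces one history record and updates both networks", {
  ds <- tiny_phantoms(4L, seed = 1L)
  set.seed(2)
  gen <- build_generator(tiny_gen_config())
  disc <- build_discriminator(discriminator_config(channels = rep(4L, 6)))
  w_g0 <- gen$stem$W
  w_d0 <- disc$layers[[1]]$conv$W
  hist <- train(gen, disc, ds$pairs[1:2], ds$pairs[3:4],
                train_config(epochs = 1L, batch_size = 2L, seed = 3L))
  expect_s3_class(hist, "train_history")
  expect_identical(nrow(hist), 1L)
  expect_true(all(c("epoch", "g_loss", "d_loss", "train_dice",
                    "val_loss", "val_dice") %in% names(hist)))
  expect_false(identical(gen$stem$W, w_g0))
  expect_false(identical(disc$layers[[1]]$conv$W, w_d0))
})

test_that("identical seeds reproduce bit-identical histories", {
  r1 <- tiny_run(seed = 10L)
  r2 <- tiny_run(seed = 10L)
  expect_identical(as.data.frame(r1$hist), as.data.frame(r2$hist))
  expect_identical(r1$gen$stem$W, r2$gen$stem$W)
  r3 <- tiny_run(seed = 11L)
  expect_false(identical(as.data.frame(r1$hist), as.data.frame(r3$hist)))
})

test_that("with lam = 0 the logged losses are an exact zero-sum pair", {
  ds <- tiny_phantoms(6L, seed = 20L)
  set.seed(21)
  gen <- build_generator(tiny_gen_config())
  disc <- build_discriminator(discriminator_config(channels = rep(4L, 6)))
  cfg <- train_config(epochs = 2L, batch_size = 3L,
                      loss_weights = loss_weights(lam = 0, delta = 1),
                      seed = 22L)
  hist <- train(gen, disc, ds$pairs[1:3], ds$pairs[4:6], cfg)
  # g_loss is the delta-weighted MAE alone; d_loss its exact negation
  expect_equal(hist$d_loss, -hist$g_loss, tolerance = 1e-12)
})

test_that("the dice-only ablation (delta = 0) trains without a discriminator", {
  r <- tiny_run(seed = 30L, epochs = 3L, delta = 0, n = 10L)
  expect_null(r$disc)
  expect_identical(r$hist$d_loss, rep(0, 3))
  expect_true(all(is.finite(r$hist$g_loss)))
  # soft Dice should move upward on this easy task even in three tiny epochs
  expect_gt(r$hist$train_dice[3], r$hist$train_dice[1])
})

test_that("non-finite losses abort with a diagnostic naming term and epoch", {
  ds <- tiny_phantoms(4L, seed = 40L)
  set.seed(41)
  gen <- build_generator(tiny_gen_config())
  gen$stem$W[] <- NaN
  expect_error(
    train(gen, NULL, ds$pairs[1:2], ds$pairs[3:4],
          train_config(epochs = 1L, batch_size = 2L,
                       loss_weights = loss_weights(delta = 0), seed = 42L)),
    "generator loss.*epoch 1")
})

test_that("prediction pads arbitrary sizes and preserves batch order", {
  set.seed(50)
  g <- build_generator(tiny_gen_config())
  img100 <- matrix(runif(100 * 100), 100, 100)
  out <- predict_slices(g, img100)
  expect_identical(dim(out$prob[[1]]), c(100L, 100L))
  expect_true(all(out$mask[[1]] %in% c(0L, 1L)))
  imgs <- purrr::map(1:5, function(i) matrix(runif(32 * 32), 32, 32))
  batch <- predict_slices(g, imgs, batch_size = 2L)
  single <- purrr::map(imgs, function(im) predict_slices(g, im)$prob[[1]])
  for (i in 1:5) expect_equal(batch$prob[[i]], single[[i]], tolerance = 1e-12)
})

test_that("evaluation against oracle stubs hits the metric extremes", {
  ds <- tiny_phantoms(5L, seed = 60L)
  # feed the ground truth through an identity stub: all metrics perfect
  pairs <- purrr::map(ds$pairs, function(p) list(image = p$mask + 0, mask = p$mask))
  truth_stub <- function(images) images
  rep1 <- evaluate(truth_stub, pairs)
  s <- rep1$summary
  expect_equal(s$mean[s$metric == "dsc"], 1)
  expect_equal(s$mean[s$metric == "voe"], 0)
  expect_equal(s$mean[s$metric == "asd"], 0)
  # constant all-background stub on slices with foreground: DSC 0, SEN 0
  bg_stub <- function(images) purrr::map(images, function(im) im * 0)
  rep2 <- suppressWarnings(evaluate(bg_stub, pairs))
  s2 <- rep2$summary
  expect_equal(s2$mean[s2$metric == "dsc"], 0)
  expect_equal(s2$mean[s2$metric == "sen"], 0)
  expect_error(evaluate(truth_stub, list()), "empty")
})

test_that("dataset splitting is exhaustive, disjoint and seed-stable", {
  ds <- tiny_phantoms(20L, seed = 70L)
  sp <- split_dataset(ds, c(0.7, 0.15, 0.15), seed = 7L)
  expect_length(sp$train, 14L)
  expect_length(sp$val, 3L)
  expect_length(sp$test, 3L)
  idx <- c(purrr::map_int(sp$train, function(p) p$meta$index),
           purrr::map_int(sp$val, function(p) p$meta$index),
           purrr::map_int(sp$test, function(p) p$meta$index))
  expect_setequal(idx, 0:19)
  sp2 <- split_dataset(ds, c(0.7, 0.15, 0.15), seed = 7L)
  expect_identical(purrr::map_int(sp2$test, function(p) p$meta$index),
                   purrr::map_int(sp$test, function(p) p$meta$index))
})
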