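test_that("generator preserves spatial size and emits probabilities", {
  set.seed(1)
  g <- build_generator(tiny_gen_config())
  x64 <- array(runif(64 * 64), c(64, 64, 1, 1))
  y <- gen_forward(g, x64)$y
  expect_identical(dim(y), c(64L, 64L, 1L, 1L))
  expect_true(all(y >= 0 & y <= 1))
  # fully convolutional: the same built network accepts other sizes
  x40 <- array(runif(40 * 40 * 2), c(40, 40, 1, 2))
  y40 <- gen_forward(g, x40)$y
  expect_identical(dim(y40), c(40L, 40L, 1L, 2L))
  # arbitrary finite inputs still land in [0, 1]
  xb <- array(rnorm(32 * 32, sd = 100), c(32, 32, 1, 1))
  expect_true(all(gen_forward(g, xb)$y >= 0 & gen_forward(g, xb)$y <= 1))
  expect_error(gen_forward(g, array(0, c(36, 36, 1, 1))), "divisible by 8")
})

test_that("dense blocks concatenate: output channels = in + n_layers * growth", {
  set.seed(2)
  nf <- ganseg:::nn_forward
  db <- ganseg:::build_dense_block(32L, dense_block_spec(4L, 16L))
  expect_identical(db$out_channels, 96L)    # 32 + 4 * 16
  x <- array(rnorm(8 * 8 * 32), c(8, 8, 32, 1))
  out <- nf(db, x)$y
  expect_identical(dim(out)[3], 96L)
  # dense connectivity: the first 32 output channels are the input itself
  # (a plainly chained block would not carry the input through)
  expect_identical(out[, , 1:32, ], x[, , , 1])
  # each later unit sees all earlier features: zeroing an early unit's
  # weights changes the deeper outputs
  db2 <- ganseg:::build_dense_block(4L, dense_block_spec(3L, 2L))
  x2 <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  y_ref <- nf(db2, x2)$y
  db2$layers[[1]]$conv$W[] <- 0
  y_ab <- nf(db2, x2)$y
  expect_false(identical(y_ref[, , 9:10, ], y_ab[, , 9:10, ]))
})

test_that("discriminator yields an ordered six-level pyramid and a score", {
  set.seed(3)
  d <- build_discriminator()
  xi <- array(runif(64 * 64), c(64, 64, 1, 1))
  mk <- array(rbinom(64 * 64, 1, 0.2), c(64, 64, 1, 1))
  r1 <- disc_forward(d, xi, mk)
  expect_length(r1$feats, 6L)
  expect_length(r1$score, 1L)
  sizes <- vapply(r1$feats, function(f) dim(f)[1], numeric(1))
  expect_true(all(diff(sizes) <= 0))          # non-increasing spatial size
  # evaluation mode is deterministic
  r2 <- disc_forward(d, xi, mk)
  expect_identical(r1$feats, r2$feats)
  expect_identical(r1$score, r2$score)
  expect_error(disc_forward(d, xi, mk[1:32, 1:32, , , drop = FALSE]),
               "spatial")
  expect_error(discriminator_config(kernel_sizes = c(9L, 5L, 4L, 4L, 3L, 3L)))
  expect_error(discriminator_config(kernel_sizes = c(7L, 5L, 4L, 3L)))
})

test_that("parameter counting matches the closed form and is monotone", {
  set.seed(4)
  # dense block, in = 8, growth = 4, 4 layers, 3x3 kernels, with BN:
  # per unit c_in in {8, 12, 16, 20}: BN 2*c_in; conv 9*c_in*4 + 4
  db <- ganseg:::build_dense_block(8L, dense_block_spec(4L, 4L))
  closed <- sum(2 * c(8, 12, 16, 20)) + sum(9 * c(8, 12, 16, 20) * 4 + 4)
  expect_identical(count_parameters(db), closed)
  # empty block adds nothing
  db0 <- ganseg:::build_dense_block(8L, dense_block_spec(0L, 4L))
  expect_identical(count_parameters(db0), 0)
  # doubling every width strictly increases the count
  g1 <- build_generator(generator_config(base_channels = 8L,
                                         dense = dense_block_spec(4L, 4L)))
  g2 <- build_generator(generator_config(base_channels = 16L,
                                         dense = dense_block_spec(4L, 8L),
                                         dec_channels = 32L))
  expect_gt(count_parameters(g2), count_parameters(g1))
})

test_that("architecture configs round-trip through JSON", {
  dir <- withr::local_tempdir()
  gc <- generator_config(base_channels = 6L, dense = dense_block_spec(3L, 5L))
  path <- file.path(dir, "gen.json")
  gl <- unclass(gc); gl$dense <- unclass(gl$dense)
  jsonlite::write_json(gl, path, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  gc2 <- generator_config(in_channels = back$in_channels,
                          base_channels = back$base_channels,
                          dense = dense_block_spec(back$dense$n_layers,
                                                   back$dense$growth),
                          compression = back$compression,
                          dec_channels = back$dec_channels)
  expect_equal(gc, gc2)
})

test_that("checkpoints restore networks exactly", {
  set.seed(5)
  dir <- withr::local_tempdir()
  g <- build_generator(tiny_gen_config())
  d <- build_discriminator(discriminator_config(channels = rep(4L, 6)))
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  y0 <- gen_forward(g, x)$y
  p <- file.path(dir, "ck.rds")
  save_checkpoint(p, g, d)
  back <- load_checkpoint(p)
  expect_identical(gen_forward(back$gen, x)$y, y0)
  m <- array(rbinom(16 * 16, 1, 0.2), c(16, 16, 1, 1))
  expect_identical(disc_forward(back$disc, x, m)$feats,
                   disc_forward(d, x, m)$feats)
  # size mismatch between checkpoint and rebuilt config is diagnosed
  ck <- readRDS(p)
  ck$gen_state$stem.W <- ck$gen_state$stem.W[, , , 1, drop = FALSE]
  p2 <- file.path(dir, "bad.rds"); saveRDS(ck, p2)
  expect_error(load_checkpoint(p2), "mismatch")
})
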