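# Independent brute-force oracles used to validate the fast implementations,
# plus small fixture builders. Oracles deliberately use naive per-pixel /
# all-pairs loops and never call the code paths they check.

# per-pixel confusion counting by explicit loop
brute_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j] == 1
      t <- truth[i, j] == 1
      if (p && t) tp <- tp + 1L
      else if (p && !t) fp <- fp + 1L
      else if (!p && t) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# boundary pixels by explicit neighbour inspection
brute_surface <- function(mask, connectivity = 4L) {
  h <- nrow(mask); w <- ncol(mask)
  offs <- if (connectivity == 4L) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    expand.grid(dr = -1:1, dc = -1:1) |>
      (\(d) d[!(d$dr == 0 & d$dc == 0), ])() |>
      (\(d) lapply(seq_len(nrow(d)), function(k) c(d$dr[k], d$dc[k])))()
  }
  out <- NULL
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mask[i, j] != 1) next
    on_surface <- FALSE
    for (o in offs) {
      ii <- i + o[1]; jj <- j + o[2]
      if (ii < 1 || ii > h || jj < 1 || jj > w || mask[ii, jj] == 0) {
        on_surface <- TRUE; break
      }
    }
    if (on_surface) out <- rbind(out, c(i, j))
  }
  out
}

# all-pairs symmetric mean nearest-surface distance
brute_asd <- function(pred, truth, spacing = c(1, 1)) {
  sa <- brute_surface(pred)
  sb <- brute_surface(truth)
  if (is.null(sa) || is.null(sb)) return(NA_real_)
  dmat <- outer(seq_len(nrow(sa)), seq_len(nrow(sb)),
                Vectorize(function(a, b) {
                  sqrt(((sa[a, 1] - sb[b, 1]) * spacing[1])^2 +
                       ((sa[a, 2] - sb[b, 2]) * spacing[2])^2)
                }))
  (sum(apply(dmat, 1, min)) + sum(apply(dmat, 2, min))) /
    (nrow(sa) + nrow(sb))
}

# random binary masks with non-trivial structure: phantom-style blobs mixed
# with salt-and-pepper, at 32x32
random_mask_pair <- function(seed) {
  cfg <- phantom_config(image_size = 32L, region_axis_range = c(4, 9),
                        noise_sd = 0, seed = seed)
  a <- generate_pair(cfg, 0L)$mask
  b <- generate_pair(cfg, 1L)$mask
  set.seed(seed)
  flip <- matrix(runif(32 * 32) < 0.03, 32, 32)
  b2 <- b
  b2[flip] <- 1L - b2[flip]
  list(a = a, b = b2)
}

tiny_gen_config <- function() {
  generator_config(base_channels = 4L, dense = dense_block_spec(2L, 2L),
                   dec_channels = 4L)
}

tiny_phantoms <- function(n, seed = 1L, image_size = 32L) {
  generate_dataset(phantom_config(image_size = image_size,
                                  region_axis_range = c(4, 9),
                                  seed = seed), n)
}
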