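# Small helpers for (H, W, C, N) tensors. Kept internal; user-facing data is
# tabular (tibbles) or plain matrices.

# stack a list of H x W matrices into an (H, W, 1, N) tensor
as_batch <- function(images) {
  if (is.matrix(images)) images <- list(images)
  d <- dim(images[[1]])
  arr <- array(0, c(d[1], d[2], 1L, length(images)))
  for (i in seq_along(images)) {
    if (!identical(dim(images[[i]]), d)) {
      abort("all images in a batch must share dimensions")
    }
    arr[, , 1L, i] <- images[[i]]
  }
  arr
}

# channel concatenation of two (H, W, C, N) tensors
ccat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(length(da) == 4L, length(db) == 4L,
            da[1] == db[1], da[2] == db[2], da[4] == db[4])
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

channel_slice <- function(x, idx) {
  x[, , idx, , drop = FALSE]
}

zeros_like <- function(x) array(0, dim(x))

# sum two possibly-NULL gradient tensors
gadd <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  a + b
}

# merge two flat named gradient lists, summing shared names
grad_merge <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- gadd(a[[nm]], b[[nm]])
  a
}

# prefix every name in a gradient list
grad_prefix <- function(g, prefix) {
  if (length(g)) names(g) <- paste0(prefix, ".", names(g))
  g
}

check_divisible <- function(h, w, by = 8L) {
  if (h %% by != 0L || w %% by != 0L) {
    abort(sprintf(
      "input spatial size %dx%d must be divisible by %d (the generator down-samples by 2 three times)",
      h, w, by))
  }
  invisible(TRUE)
}
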