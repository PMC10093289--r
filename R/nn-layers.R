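# Primitive differentiable layers. Each layer is a mutable environment holding
# its parameters; forward passes return the output plus a cache, backward
# passes consume the cache and return the input gradient and (optionally)
# parameter gradients as a flat named list. Tensors are (H, W, C, N) arrays.

new_layer <- function(type, ..., param_fields = character(), decay_fields = character()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$param_fields <- param_fields
  e$decay_fields <- decay_fields
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("layer_", type), "nn_layer")
  e
}

# He-normal initialisation, driven by R's RNG so runs are seed-reproducible
he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

layer_conv <- function(in_channels, out_channels, kernel = 3L, stride = 1L,
                       pad = kernel %/% 2L) {
  new_layer("conv",
    W = he_init(c(kernel, kernel, in_channels, out_channels),
                fan_in = kernel * kernel * in_channels),
    b = numeric(out_channels),
    stride = as.integer(stride), pad = as.integer(pad),
    in_channels = as.integer(in_channels), out_channels = as.integer(out_channels),
    param_fields = c("W", "b"), decay_fields = "W")
}

layer_convt <- function(in_channels, out_channels, kernel = 2L, stride = 2L,
                        pad = 0L) {
  new_layer("convt",
    W = he_init(c(kernel, kernel, out_channels, in_channels),
                fan_in = kernel * kernel * in_channels),
    b = numeric(out_channels),
    stride = as.integer(stride), pad = as.integer(pad),
    in_channels = as.integer(in_channels), out_channels = as.integer(out_channels),
    param_fields = c("W", "b"), decay_fields = "W")
}

layer_bn <- function(channels, momentum = 0.1, eps = 1e-5) {
  new_layer("bn",
    gamma = rep(1, channels), beta = numeric(channels),
    running_mean = numeric(channels), running_var = rep(1, channels),
    momentum = momentum, eps = eps, channels = as.integer(channels),
    param_fields = c("gamma", "beta"))
}

layer_act <- function(kind = c("relu", "lrelu", "sigmoid"), slope = 0.2) {
  kind <- match.arg(kind)
  new_layer("act", kind = kind, slope = slope)
}

nn_forward <- function(layer, x, training = FALSE) UseMethod("nn_forward")
nn_backward <- function(layer, cache, dy, want_params = TRUE) UseMethod("nn_backward")

#' @export
nn_forward.layer_conv <- function(layer, x, training = FALSE) {
  y <- .conv_forward(x, layer$W, layer$b, layer$stride, layer$pad)
  list(y = y, cache = list(x = x))
}

#' @export
nn_backward.layer_conv <- function(layer, cache, dy, want_params = TRUE) {
  r <- .conv_backward(cache$x, layer$W, dy, layer$stride, layer$pad,
                      TRUE, want_params)
  grads <- if (want_params) list(W = r$dw, b = r$db) else NULL
  list(dx = r$dx, grads = grads)
}

#' @export
nn_forward.layer_convt <- function(layer, x, training = FALSE) {
  y <- .convt_forward(x, layer$W, layer$b, layer$stride, layer$pad)
  list(y = y, cache = list(x = x))
}

#' @export
nn_backward.layer_convt <- function(layer, cache, dy, want_params = TRUE) {
  r <- .convt_backward(cache$x, layer$W, dy, layer$stride, layer$pad,
                       TRUE, want_params)
  grads <- if (want_params) list(W = r$dw, b = r$db) else NULL
  list(dx = r$dx, grads = grads)
}

#' @export
nn_forward.layer_bn <- function(layer, x, training = FALSE) {
  r <- .bn_forward(x, layer$gamma, layer$beta,
                   layer$running_mean, layer$running_var, layer$eps,
                   !training)
  if (training) {
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
      layer$momentum * r$mu
    layer$running_var <- (1 - layer$momentum) * layer$running_var +
      layer$momentum * r$var
  }
  list(y = r$y, cache = list(xhat = r$xhat, istd = r$istd, training = training))
}

#' @export
nn_backward.layer_bn <- function(layer, cache, dy, want_params = TRUE) {
  r <- .bn_backward(dy, cache$xhat, cache$istd, layer$gamma,
                    cache$training, want_params)
  grads <- if (want_params) list(gamma = r$dgamma, beta = r$dbeta) else NULL
  list(dx = r$dx, grads = grads)
}

#' @export
nn_forward.layer_act <- function(layer, x, training = FALSE) {
  y <- switch(layer$kind,
    relu = pmax(x, 0),
    lrelu = pmax(x, 0) + layer$slope * pmin(x, 0),
    sigmoid = 1 / (1 + exp(-x)))
  if (!is.array(y)) dim(y) <- dim(x)
  cache <- switch(layer$kind,
    relu = list(mask = x > 0),
    lrelu = list(mask = x > 0),
    sigmoid = list(y = y))
  list(y = y, cache = cache)
}

#' @export
nn_backward.layer_act <- function(layer, cache, dy, want_params = TRUE) {
  dx <- switch(layer$kind,
    relu = dy * cache$mask,
    lrelu = dy * (cache$mask + layer$slope * !cache$mask),
    sigmoid = dy * cache$y * (1 - cache$y))
  if (!is.array(dx)) dim(dx) <- dim(dy)
  list(dx = dx, grads = NULL)
}

maxpool_forward <- function(x, size = 2L) .maxpool_forward(x, size)
maxpool_backward <- function(dy, idx, h, w) .maxpool_backward(dy, idx, h, w)

# ---- parameter bookkeeping -------------------------------------------------

# Flat named references to every trainable parameter of a module tree.
# Each element: list(env, field, decay).
nn_param_refs <- function(module) UseMethod("nn_param_refs")

#' @export
nn_param_refs.nn_layer <- function(module) {
  refs <- list()
  for (f in module$param_fields) {
    refs[[f]] <- list(env = module, field = f, decay = f %in% module$decay_fields)
  }
  refs
}

refs_prefix <- function(refs, prefix) {
  if (length(refs)) names(refs) <- paste0(prefix, ".", names(refs))
  refs
}

# All persistent numeric state (parameters + batch-norm running stats).
state_fields <- function(layer) {
  intersect(c("W", "b", "gamma", "beta", "running_mean", "running_var"),
            names(layer))
}

nn_count_params <- function(refs) {
  sum(vapply(refs, function(r) length(r$env[[r$field]]), numeric(1)))
}
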