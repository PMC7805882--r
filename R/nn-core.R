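# Minimal neural-network core: layer objects with explicit forward/backward
# passes, built on im2col + BLAS GEMM.  Batches of images are numeric arrays
# with dim c(H, W, N, C); dense activations are N x K matrices.
#
# Every layer is an environment with fields
#   $par  named list of parameter arrays
#   $gr   named list of gradient arrays (same shapes), filled by nn_backward
# and S3 methods nn_forward(layer, x, train) / nn_backward(layer, dy).

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$par <- list()
  e$gr <- list()
  args <- list(...)
  for (nm in names(args)) assign(nm, args[[nm]], envir = e)
  class(e) <- c(paste0("nn_", type), "nn_layer")
  e
}

nn_forward <- function(layer, x, train = FALSE) UseMethod("nn_forward")
nn_backward <- function(layer, dy) UseMethod("nn_backward")

#' @keywords internal
nn_parameters <- function(layer) {
  if (inherits(layer, "nn_seq")) {
    return(do.call(c, lapply(layer$layers, nn_parameters)))
  }
  if (inherits(layer, "nn_resblock")) {
    return(c(nn_parameters(layer$body), if (!is.null(layer$proj)) nn_parameters(layer$proj)))
  }
  if (length(layer$par) == 0) return(list())
  lapply(names(layer$par), function(nm) list(layer = layer, name = nm))
}

n_parameters <- function(layer) {
  sum(vapply(nn_parameters(layer), function(p) length(p$layer$par[[p$name]]), numeric(1)))
}

# ---- dense ------------------------------------------------------------------

nn_dense <- function(n_in, n_out, init_sd = sqrt(2 / n_in)) {
  l <- new_layer("dense")
  l$par$W <- matrix(stats::rnorm(n_in * n_out, sd = init_sd), n_in, n_out)
  l$par$b <- numeric(n_out)
  l
}

#' @exportS3Method nn_forward nn_dense
nn_forward.nn_dense <- function(layer, x, train = FALSE) {
  layer$x <- x
  sweep_add(x %*% layer$par$W, layer$par$b)
}

#' @exportS3Method nn_backward nn_dense
nn_backward.nn_dense <- function(layer, dy) {
  layer$gr$W <- crossprod(layer$x, dy)
  layer$gr$b <- colSums(dy)
  tcrossprod(dy, layer$par$W)
}

sweep_add <- function(m, b) {
  # add a per-column bias to a matrix without forming a full sweep
  m + rep(b, each = nrow(m))
}

# ---- conv -------------------------------------------------------------------

nn_conv <- function(in_ch, out_ch, k = 3, stride = 1, pad = k %/% 2,
                    init_sd = sqrt(2 / (k * k * in_ch))) {
  l <- new_layer("conv", k = k, stride = stride, pad = pad,
                 in_ch = in_ch, out_ch = out_ch)
  l$par$W <- matrix(stats::rnorm(k * k * in_ch * out_ch, sd = init_sd),
                    k * k * in_ch, out_ch)
  l$par$b <- numeric(out_ch)
  l
}

#' @exportS3Method nn_forward nn_conv
nn_forward.nn_conv <- function(layer, x, train = FALSE) {
  d <- dim(x)
  stopifnot(length(d) == 4, d[4] == layer$in_ch)
  layer$x <- x
  cpp_conv_forward(x, layer$par$W, layer$par$b, d[1], d[2], d[3], d[4],
                   layer$k, layer$k, layer$stride, layer$pad)
}

#' @exportS3Method nn_backward nn_conv
nn_backward.nn_conv <- function(layer, dy) {
  d <- dim(layer$x)
  gr <- cpp_conv_backward(layer$x, layer$par$W, dy, d[1], d[2], d[3], d[4],
                          layer$k, layer$k, layer$stride, layer$pad)
  layer$gr$W <- gr$dW
  layer$gr$b <- gr$db
  gr$dx
}

# ---- batch normalization (per channel, over H, W, N) ------------------------

nn_bn <- function(ch, momentum = 0.9, eps = 1e-5) {
  l <- new_layer("bn", ch = ch, momentum = momentum, eps = eps)
  l$par$gamma <- rep(1, ch)
  l$par$beta <- rep(0, ch)
  l$run_mean <- rep(0, ch)
  l$run_var <- rep(1, ch)
  l
}

#' @exportS3Method nn_forward nn_bn
nn_forward.nn_bn <- function(layer, x, train = FALSE) {
  d <- dim(x)
  m <- x
  dim(m) <- c(prod(d[-length(d)]), d[length(d)])
  if (train) {
    mu <- colMeans(m)
    v <- colMeans(m * m) - mu^2
    layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
    layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- sweep_add(m, -mu) * rep(inv, each = nrow(m))
  layer$xhat <- xhat
  layer$inv <- inv
  layer$train_mode <- train
  y <- sweep_add(xhat * rep(layer$par$gamma, each = nrow(m)), layer$par$beta)
  dim(y) <- d
  y
}

#' @exportS3Method nn_backward nn_bn
nn_backward.nn_bn <- function(layer, dy) {
  d <- dim(dy)
  m <- dy
  dim(m) <- dim(layer$xhat)
  layer$gr$gamma <- colSums(m * layer$xhat)
  layer$gr$beta <- colSums(m)
  n <- nrow(m)
  gi <- layer$par$gamma * layer$inv
  if (isTRUE(layer$train_mode)) {
    t1 <- rep(colMeans(m), each = n)
    t2 <- layer$xhat * rep(colMeans(m * layer$xhat), each = n)
    dx <- (m - t1 - t2) * rep(gi, each = n)
  } else {
    dx <- m * rep(gi, each = n)
  }
  dim(dx) <- d
  dx
}

# ---- activations ------------------------------------------------------------

nn_act <- function(kind = c("relu", "lrelu", "sigmoid", "tanh"), slope = 0.2) {
  kind <- match.arg(kind)
  new_layer("act", kind = kind, slope = slope)
}

#' @exportS3Method nn_forward nn_act
nn_forward.nn_act <- function(layer, x, train = FALSE) {
  y <- switch(layer$kind,
    relu = pmax(x, 0),
    lrelu = ifelse(x > 0, x, layer$slope * x),
    sigmoid = 1 / (1 + exp(-x)),
    tanh = tanh(x))
  if (is.array(x)) dim(y) <- dim(x)
  if (layer$kind %in% c("relu", "lrelu")) layer$x <- x else layer$y <- y
  y
}

#' @exportS3Method nn_backward nn_act
nn_backward.nn_act <- function(layer, dy) {
  g <- switch(layer$kind,
    relu = dy * (layer$x > 0),
    lrelu = dy * ifelse(layer$x > 0, 1, layer$slope),
    sigmoid = dy * layer$y * (1 - layer$y),
    tanh = dy * (1 - layer$y^2))
  ref <- if (layer$kind %in% c("relu", "lrelu")) layer$x else layer$y
  if (is.array(ref)) dim(g) <- dim(ref)
  g
}

# ---- shape plumbing ---------------------------------------------------------

nn_upsample2 <- function() new_layer("up2")

#' @exportS3Method nn_forward nn_up2
nn_forward.nn_up2 <- function(layer, x, train = FALSE) {
  d <- dim(x)
  layer$in_dim <- d
  cpp_upsample2(x, d[1], d[2], d[3], d[4])
}

#' @exportS3Method nn_backward nn_up2
nn_backward.nn_up2 <- function(layer, dy) {
  d <- dim(dy)
  cpp_downsample2_sum(dy, d[1], d[2], d[3], d[4])
}

# matrix (N, H*W*C) <- array (H, W, N, C)
nn_flatten <- function() new_layer("flatten")

#' @exportS3Method nn_forward nn_flatten
nn_forward.nn_flatten <- function(layer, x, train = FALSE) {
  d <- dim(x)
  layer$in_dim <- d
  y <- aperm(x, c(1, 2, 4, 3))
  dim(y) <- c(d[1] * d[2] * d[4], d[3])
  t(y)
}

#' @exportS3Method nn_backward nn_flatten
nn_backward.nn_flatten <- function(layer, dy) {
  d <- layer$in_dim
  g <- t(dy)
  dim(g) <- c(d[1], d[2], d[4], d[3])
  aperm(g, c(1, 2, 4, 3))
}

# array (H, W, N, C) <- matrix (N, H*W*C); inverse of nn_flatten
nn_reshape <- function(h, w, ch) new_layer("reshape", h = h, w = w, ch = ch)

#' @exportS3Method nn_forward nn_reshape
nn_forward.nn_reshape <- function(layer, x, train = FALSE) {
  n <- nrow(x)
  g <- t(x)
  dim(g) <- c(layer$h, layer$w, layer$ch, n)
  aperm(g, c(1, 2, 4, 3))
}

#' @exportS3Method nn_backward nn_reshape
nn_backward.nn_reshape <- function(layer, dy) {
  d <- dim(dy)
  y <- aperm(dy, c(1, 2, 4, 3))
  dim(y) <- c(d[1] * d[2] * d[4], d[3])
  t(y)
}

# global average pool: (H, W, N, C) -> (N, C)
nn_gap <- function() new_layer("gap")

#' @exportS3Method nn_forward nn_gap
nn_forward.nn_gap <- function(layer, x, train = FALSE) {
  d <- dim(x)
  layer$in_dim <- d
  m <- x
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  y <- colMeans(m)
  dim(y) <- c(d[3], d[4])
  y
}

#' @exportS3Method nn_backward nn_gap
nn_backward.nn_gap <- function(layer, dy) {
  d <- layer$in_dim
  g <- rep(as.numeric(dy) / (d[1] * d[2]), each = d[1] * d[2])
  dim(g) <- d
  g
}

# ---- containers -------------------------------------------------------------

nn_sequential <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) && !inherits(layers[[1]], "nn_layer")) {
    layers <- layers[[1]]
  }
  new_layer("seq", layers = layers)
}

#' @exportS3Method nn_forward nn_seq
nn_forward.nn_seq <- function(layer, x, train = FALSE) {
  for (l in layer$layers) x <- nn_forward(l, x, train)
  x
}

#' @exportS3Method nn_backward nn_seq
nn_backward.nn_seq <- function(layer, dy) {
  for (l in rev(layer$layers)) dy <- nn_backward(l, dy)
  dy
}

# residual block: y = relu(body(x) + proj(x)); proj is identity or 1x1 conv
nn_resblock <- function(in_ch, out_ch, stride = 1) {
  body <- nn_sequential(
    nn_conv(in_ch, out_ch, 3, stride = stride),
    nn_bn(out_ch),
    nn_act("relu"),
    nn_conv(out_ch, out_ch, 3),
    nn_bn(out_ch))
  proj <- NULL
  if (stride != 1 || in_ch != out_ch) {
    proj <- nn_sequential(nn_conv(in_ch, out_ch, 1, stride = stride, pad = 0),
                          nn_bn(out_ch))
  }
  new_layer("resblock", body = body, proj = proj)
}

#' @exportS3Method nn_forward nn_resblock
nn_forward.nn_resblock <- function(layer, x, train = FALSE) {
  f <- nn_forward(layer$body, x, train)
  s <- if (is.null(layer$proj)) x else nn_forward(layer$proj, x, train)
  y <- f + s
  layer$pos <- y > 0
  pmax(y, 0)
}

#' @exportS3Method nn_backward nn_resblock
nn_backward.nn_resblock <- function(layer, dy) {
  dy <- dy * layer$pos
  dx <- nn_backward(layer$body, dy)
  ds <- if (is.null(layer$proj)) dy else nn_backward(layer$proj, dy)
  dx + ds
}

# ---- optimizer and losses ---------------------------------------------------

adam_new <- function(params, lr = 2e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr
  st$beta1 <- beta1
  st$beta2 <- beta2
  st$eps <- eps
  st$t <- 0
  st$m <- lapply(params, function(p) p$layer$par[[p$name]] * 0)
  st$v <- st$m
  st
}

adam_step <- function(st) {
  st$t <- st$t + 1
  b1 <- st$beta1; b2 <- st$beta2
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$layer$gr[[p$name]]
    if (is.null(g)) next
    st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
    st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g * g
    p$layer$par[[p$name]] <- p$layer$par[[p$name]] -
      st$lr * (st$m[[i]] / c1) / (sqrt(st$v[[i]] / c2) + st$eps)
  }
  invisible(st)
}

# binary cross-entropy on logits; returns loss and gradient wrt logits
bce_with_logits <- function(z, y) {
  n <- length(z)
  loss <- sum(pmax(z, 0) - z * y + log1p(exp(-abs(z)))) / n
  grad <- (1 / (1 + exp(-z)) - y) / n
  list(loss = loss, grad = grad)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- checkpoint (de)serialization -------------------------------------------

# Extract all parameters and batchnorm running statistics into plain lists so
# that networks can be rebuilt bit-exactly.
nn_state <- function(layer) {
  if (inherits(layer, "nn_seq")) return(lapply(layer$layers, nn_state))
  if (inherits(layer, "nn_resblock")) {
    return(list(body = nn_state(layer$body),
                proj = if (!is.null(layer$proj)) nn_state(layer$proj)))
  }
  s <- list(par = layer$par)
  if (inherits(layer, "nn_bn")) {
    s$run_mean <- layer$run_mean
    s$run_var <- layer$run_var
  }
  s
}

nn_load_state <- function(layer, state) {
  if (inherits(layer, "nn_seq")) {
    for (i in seq_along(layer$layers)) nn_load_state(layer$layers[[i]], state[[i]])
    return(invisible(layer))
  }
  if (inherits(layer, "nn_resblock")) {
    nn_load_state(layer$body, state$body)
    if (!is.null(layer$proj)) nn_load_state(layer$proj, state$proj)
    return(invisible(layer))
  }
  layer$par <- state$par
  if (inherits(layer, "nn_bn")) {
    layer$run_mean <- state$run_mean
    layer$run_var <- state$run_var
  }
  invisible(layer)
}

# Drop all forward/backward caches so evaluated networks do not pin
# batch-sized arrays; parameters and batchnorm statistics are kept.
nn_clear_cache <- function(layer) {
  if (inherits(layer, "nn_seq")) {
    for (l in layer$layers) nn_clear_cache(l)
    return(invisible(layer))
  }
  if (inherits(layer, "nn_resblock")) {
    nn_clear_cache(layer$body)
    if (!is.null(layer$proj)) nn_clear_cache(layer$proj)
    layer$pos <- NULL
    return(invisible(layer))
  }
  for (f in c("x", "y", "xhat", "inv", "in_dim")) {
    if (!is.null(layer[[f]])) layer[[f]] <- NULL
  }
  layer$gr <- list()
  invisible(layer)
}
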