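# Neural-network primitives in plain R.
#
# Images and feature maps are [H, W, C] arrays. Convolution is implemented
# as cross-correlation via im2col + matrix multiply, so the inner loops run
# in BLAS; backward passes are provided for everything the training module
# differentiates through. Index matrices for im2col are memoized per shape.

.im2col_cache <- new.env(parent = emptyenv())

# Linear-index matrix (n_patch x kh*kw*C) into a zero/-Inf padded [Hp,Wp,C]
# array; patch order (oh fastest, then ow) matches column-major output.
im2col_index <- function(H, W, C, kh, kw, stride, pad) {
  key <- paste(H, W, C, kh, kw, stride, pad, sep = "_")
  got <- .im2col_cache[[key]]
  if (!is.null(got)) return(got)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  H_out <- (Hp - kh) %/% stride + 1L
  W_out <- (Wp - kw) %/% stride + 1L
  off <- as.vector(outer(outer(0:(kh - 1L), (0:(kw - 1L)) * Hp, `+`),
                         (0:(C - 1L)) * Hp * Wp, `+`))
  starts <- as.vector(outer((0:(H_out - 1L)) * stride,
                            (0:(W_out - 1L)) * stride * Hp, `+`)) + 1L
  idx <- outer(starts, off, `+`)
  out <- list(idx = idx, H_out = H_out, W_out = W_out, Hp = Hp, Wp = Wp)
  .im2col_cache[[key]] <- out
  out
}

pad_array <- function(x, pad, fill = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(fill, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

as_hwc <- function(x) {
  if (is.null(dim(x))) stop_shape("expected an array input")
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop_shape("expected a [H, W, C] array")
  x
}

#' Convolutional layer parameters
#'
#' Weights are indexed `[row, col, in_channel, out_filter]`; the forward
#' pass is the deep-learning convention of cross-correlation plus a per-
#' filter bias, followed by the chosen activation.
#'
#' @param weights a `[kh, kw, c_in, c_out]` array.
#' @param bias per-filter bias vector (length `c_out`).
#' @param activation `"relu"` or `"identity"`.
#' @param stride spatial stride.
#' @param pad zero-padding on each side.
#' @return a `ConvLayer`.
#' @export
conv_layer <- function(weights, bias = NULL, activation = c("relu", "identity"),
                       stride = 1L, pad = 0L) {
  activation <- match.arg(activation)
  d <- dim(weights)
  if (length(d) != 4L) stop_shape("conv weights must be [kh, kw, c_in, c_out]")
  if (any(!is.finite(weights))) stop_invalid_input("conv weights must be finite")
  if (is.null(bias)) bias <- numeric(d[4])
  if (length(bias) != d[4]) stop_shape("bias length must equal c_out")
  structure(list(weights = weights, bias = bias, activation = activation,
                 stride = as.integer(stride), pad = as.integer(pad)),
            class = "ConvLayer")
}

conv_forward <- function(x, layer, keep_cache = FALSE) {
  x <- as_hwc(x)
  d <- dim(x); wd <- dim(layer$weights)
  if (d[3] != wd[3]) {
    stop_shape(sprintf("input has %d channels but kernel expects %d",
                       d[3], wd[3]))
  }
  if (d[1] + 2L * layer$pad < wd[1] || d[2] + 2L * layer$pad < wd[2]) {
    stop_shape(sprintf("kernel %dx%d does not fit input %dx%d (pad %d)",
                       wd[1], wd[2], d[1], d[2], layer$pad))
  }
  ii <- im2col_index(d[1], d[2], d[3], wd[1], wd[2], layer$stride, layer$pad)
  xp <- pad_array(x, layer$pad)
  Xcol <- matrix(xp[ii$idx], nrow(ii$idx), ncol(ii$idx))
  Wmat <- matrix(layer$weights, ncol = wd[4])
  Z <- sweep(Xcol %*% Wmat, 2, layer$bias, `+`)
  Y <- if (layer$activation == "relu") pmax(Z, 0) else Z
  out <- array(Y, dim = c(ii$H_out, ii$W_out, wd[4]))
  if (keep_cache) {
    attr(out, "cache") <- list(Xcol = Xcol, Z = Z, ii = ii, in_dim = d)
  }
  out
}

conv_backward <- function(dout, layer, cache) {
  wd <- dim(layer$weights)
  dY <- matrix(dout, ncol = wd[4])
  if (layer$activation == "relu") dY <- dY * (cache$Z > 0)
  Wmat <- matrix(layer$weights, ncol = wd[4])
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dXcol <- dY %*% t(Wmat)
  ii <- cache$ii
  acc <- rowsum(as.vector(dXcol), group = as.vector(ii$idx))
  dxp <- numeric(ii$Hp * ii$Wp * cache$in_dim[3])
  dxp[as.integer(rownames(acc))] <- acc[, 1]
  dxp <- array(dxp, dim = c(ii$Hp, ii$Wp, cache$in_dim[3]))
  p <- layer$pad
  dx <- dxp[p + seq_len(cache$in_dim[1]), p + seq_len(cache$in_dim[2]), ,
            drop = FALSE]
  list(dx = dx, dW = array(dW, dim = wd), db = db)
}

#' Apply a convolutional layer
#'
#' @param input a `[H, W, C]` array (a matrix is treated as one channel).
#' @param layer a [conv_layer()].
#' @return the `[H_out, W_out, c_out]` feature maps.
#' @export
conv2d <- function(input, layer) {
  stopifnot(inherits(layer, "ConvLayer"))
  conv_forward(input, layer)
}

#' Max pooling
#'
#' Per-channel maximum over sliding windows.
#'
#' @param input a `[H, W, C]` array.
#' @param window window side length.
#' @param stride stride (defaults to `window`).
#' @param pad `-Inf` padding on each side.
#' @return pooled `[H_out, W_out, C]` array.
#' @export
max_pool <- function(input, window, stride = window, pad = 0L) {
  pool_forward(input, window, stride, pad)
}

pool_forward <- function(x, window, stride = window, pad = 0L,
                         keep_cache = FALSE) {
  x <- as_hwc(x)
  d <- dim(x)
  if (d[1] + 2L * pad < window || d[2] + 2L * pad < window) {
    stop_shape(sprintf("pool window %d larger than input %dx%d", window,
                       d[1], d[2]))
  }
  Hp <- d[1] + 2L * pad; Wp <- d[2] + 2L * pad
  H_out <- (Hp - window) %/% stride + 1L
  W_out <- (Wp - window) %/% stride + 1L
  xp <- pad_array(x, pad, fill = -Inf)
  off <- as.vector(outer(0:(window - 1L), (0:(window - 1L)) * Hp, `+`))
  starts <- as.vector(outer(outer((0:(H_out - 1L)) * stride,
                                  (0:(W_out - 1L)) * stride * Hp, `+`),
                            (0:(d[3] - 1L)) * Hp * Wp, `+`)) + 1L
  idx <- outer(starts, off, `+`)
  vals <- matrix(xp[idx], nrow(idx), ncol(idx))
  which_mx <- max.col(vals, ties.method = "first")
  mx <- vals[cbind(seq_len(nrow(vals)), which_mx)]
  out <- array(mx, dim = c(H_out, W_out, d[3]))
  if (keep_cache) {
    attr(out, "cache") <- list(
      argmax = idx[cbind(seq_len(nrow(idx)), which_mx)],
      padded_dim = c(Hp, Wp, d[3]), in_dim = d, pad = pad)
  }
  out
}

pool_backward <- function(dout, cache) {
  dxp <- numeric(prod(cache$padded_dim))
  acc <- rowsum(as.vector(dout), group = cache$argmax)
  dxp[as.integer(rownames(acc))] <- acc[, 1]
  dxp <- array(dxp, dim = cache$padded_dim)
  p <- cache$pad
  dxp[p + seq_len(cache$in_dim[1]), p + seq_len(cache$in_dim[2]), ,
      drop = FALSE]
}

#' Dense (fully connected) layer parameters
#'
#' @param W weight matrix, `out x in`.
#' @param b bias vector, length `out`.
#' @return a `DenseLayer`.
#' @export
dense_layer <- function(W, b = NULL) {
  if (!is.matrix(W)) stop_shape("dense weights must be a matrix")
  if (is.null(b)) b <- numeric(nrow(W))
  if (length(b) != nrow(W)) stop_shape("bias length must equal output dim")
  structure(list(W = W, b = b), class = "DenseLayer")
}

dense_forward <- function(x, layer) {
  if (length(x) != ncol(layer$W)) {
    stop_shape(sprintf("dense layer expects input of length %d, got %d",
                       ncol(layer$W), length(x)))
  }
  as.vector(layer$W %*% x + layer$b)
}

#' A residual block
#'
#' Holds an inner path (a list of [conv_layer()]s applied in order, the
#' final one conventionally with identity activation) and an identity or
#' 1x1-projection shortcut. The block output is
#' `relu(inner(x) + shortcut(x))` when `final_relu` is `TRUE`, otherwise
#' the plain sum.
#'
#' @param layers list of [conv_layer()]s for the inner path.
#' @param shortcut `NULL` for identity, or a projection [conv_layer()].
#' @param final_relu apply ReLU after the addition.
#' @return a `ResidualBlock`.
#' @export
residual_block <- function(layers, shortcut = NULL, final_relu = TRUE) {
  stopifnot(all(vapply(layers, inherits, TRUE, "ConvLayer")))
  structure(list(layers = layers, shortcut = shortcut,
                 final_relu = final_relu), class = "ResidualBlock")
}

#' Forward pass through a residual block
#'
#' @param input a `[H, W, C]` array.
#' @param block a [residual_block()].
#' @return the block output; shapes of inner path and shortcut must agree.
#' @export
residual_forward <- function(input, block, keep_cache = FALSE) {
  stopifnot(inherits(block, "ResidualBlock"))
  input <- as_hwc(input)
  h <- input
  caches <- vector("list", length(block$layers))
  for (i in seq_along(block$layers)) {
    h <- conv_forward(h, block$layers[[i]], keep_cache = keep_cache)
    caches[[i]] <- attr(h, "cache")
    attr(h, "cache") <- NULL
  }
  sc <- if (is.null(block$shortcut)) input else {
    conv_forward(input, block$shortcut, keep_cache = keep_cache)
  }
  sc_cache <- attr(sc, "cache")
  attr(sc, "cache") <- NULL
  if (!identical(dim(h), dim(sc))) {
    stop_shape(sprintf("residual paths disagree: inner %s vs shortcut %s",
                       paste(dim(h), collapse = "x"),
                       paste(dim(sc), collapse = "x")))
  }
  pre <- h + sc
  out <- if (block$final_relu) pmax(pre, 0) else pre
  if (keep_cache) {
    attr(out, "cache") <- list(caches = caches, sc_cache = sc_cache, pre = pre)
  }
  out
}

residual_backward <- function(dout, block, cache) {
  if (block$final_relu) dout <- dout * (cache$pre > 0)
  grads <- vector("list", length(block$layers))
  dh <- dout
  for (i in rev(seq_along(block$layers))) {
    bk <- conv_backward(dh, block$layers[[i]], cache$caches[[i]])
    grads[[i]] <- list(dW = bk$dW, db = bk$db)
    dh <- bk$dx
  }
  if (is.null(block$shortcut)) {
    dx <- dh + dout
    sc_grad <- NULL
  } else {
    bk <- conv_backward(dout, block$shortcut, cache$sc_cache)
    dx <- dh + bk$dx
    sc_grad <- list(dW = bk$dW, db = bk$db)
  }
  list(dx = dx, layer_grads = grads, shortcut_grad = sc_grad)
}

global_avg_pool <- function(x) {
  x <- as_hwc(x)
  apply(x, 3, mean)
}

# Seeded He-style initializers ----------------------------------------------

init_conv <- function(kh, kw, c_in, c_out, activation = "relu",
                      stride = 1L, pad = 0L) {
  sd <- sqrt(2 / (kh * kw * c_in))
  conv_layer(array(stats::rnorm(kh * kw * c_in * c_out, 0, sd),
                   dim = c(kh, kw, c_in, c_out)),
             activation = activation, stride = stride, pad = pad)
}

init_dense <- function(n_out, n_in) {
  dense_layer(matrix(stats::rnorm(n_out * n_in, 0, sqrt(2 / n_in)),
                     n_out, n_in))
}

# Optimizers -----------------------------------------------------------------
# Parameters and gradients travel as flat named lists of arrays.

optimizer_new <- function(kind = c("adam", "rmsprop"), lr) {
  kind <- match.arg(kind)
  list(kind = kind, lr = lr, t = 0L, state = list())
}

optimizer_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st <- opt$state[[nm]]
    if (is.null(st)) st <- list(m = g * 0, v = g * 0)
    if (opt$kind == "adam") {
      b1 <- 0.9; b2 <- 0.999
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      mhat <- st$m / (1 - b1^opt$t)
      vhat <- st$v / (1 - b2^opt$t)
      params[[nm]] <- params[[nm]] - opt$lr * mhat / (sqrt(vhat) + 1e-8)
    } else {                                   # rmsprop
      st$v <- 0.9 * st$v + 0.1 * g^2
      params[[nm]] <- params[[nm]] - opt$lr * g / (sqrt(st$v) + 1e-8)
    }
    opt$state[[nm]] <- st
  }
  list(opt = opt, params = params)
}
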