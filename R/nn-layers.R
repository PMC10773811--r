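# Minimal neural-network engine.
#
# Activations are numeric arrays in channel-first layout (C, H, W, N); the
# spatial convolutions are evaluated as matrix products against an unrolled
# patch matrix (im2col), so the heavy lifting is BLAS GEMM. Layers are
# mutable environments holding parameters (`W`, `b`, `gamma`, ...), their
# gradients (`gW`, ...), and the forward cache needed by the backward pass.
# `layer_forward()` / `layer_backward()` dispatch on the layer class;
# `nn_params()` enumerates trainable parameters for the optimizer.

new_layer <- function(class, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(class, "nn_layer")
  e
}

layer_forward <- function(l, x, training = FALSE) UseMethod("layer_forward")
layer_backward <- function(l, dy) UseMethod("layer_backward")

# Parameter descriptors: list(env, par, grad, decay). `decay` marks weights
# subject to L2 regularization (biases and batch-norm affine terms are not).
nn_params <- function(l) UseMethod("nn_params")
#' @export
nn_params.default <- function(l) list()

he_init <- function(nrow, ncol, fan) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan)), nrow, ncol)
}

# ---- convolution ------------------------------------------------------------

nn_conv2d <- function(in_ch, out_ch, kernel = 3L, stride = 1L, pad = 1L,
                      bias = FALSE) {
  W <- he_init(out_ch, in_ch * kernel^2, fan = out_ch * kernel^2)
  new_layer("nn_conv2d",
            in_ch = in_ch, out_ch = out_ch, kernel = as.integer(kernel),
            stride = as.integer(stride), pad = as.integer(pad),
            W = W, b = if (bias) numeric(out_ch) else NULL,
            gW = NULL, gb = NULL, cache = NULL)
}

# Linear indices of each kernel offset's patch into the padded input,
# cached per layer and input geometry (minibatches share dimensions, so the
# cache almost always hits).
conv_geometry <- function(l, d) {
  geo <- l$geo
  if (!is.null(geo) && identical(geo$in_dim, d)) return(geo)
  C <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]
  k <- l$kernel; s <- l$stride; p <- l$pad
  Ho <- (H + 2L * p - k) %/% s + 1L
  Wo <- (Wd + 2L * p - k) %/% s + 1L
  pad_dim <- c(C, H + 2L * p, Wd + 2L * p, N)
  idx <- array(seq_len(prod(pad_dim)), pad_dim)
  lin <- vector("list", k * k)
  for (o in seq_len(k * k)) {
    ki <- (o - 1L) %% k
    kj <- (o - 1L) %/% k
    hsel <- ki + 1L + s * (seq_len(Ho) - 1L)
    wsel <- kj + 1L + s * (seq_len(Wo) - 1L)
    lin[[o]] <- as.vector(idx[, hsel, wsel, , drop = FALSE])
  }
  interior <- if (p > 0L)
    as.vector(idx[, p + seq_len(H), p + seq_len(Wd), , drop = FALSE])
  geo <- list(in_dim = d, pad_dim = pad_dim, Ho = Ho, Wo = Wo,
              lin = lin, interior = interior)
  l$geo <- geo
  geo
}

#' @export
layer_forward.nn_conv2d <- function(l, x, training = FALSE) {
  d <- dim(x)
  geo <- conv_geometry(l, d)
  C <- d[1]; k <- l$kernel
  if (l$pad > 0L) {
    xpad <- numeric(prod(geo$pad_dim))
    xpad[geo$interior] <- x
  } else xpad <- as.vector(x)
  M <- geo$Ho * geo$Wo * d[4]
  P <- matrix(0, C * k * k, M)
  for (o in seq_len(k * k))
    P[(o - 1L) * C + seq_len(C), ] <- xpad[geo$lin[[o]]]
  Y <- l$W %*% P
  if (!is.null(l$b)) Y <- Y + l$b
  l$cache <- P
  dim(Y) <- c(l$out_ch, geo$Ho, geo$Wo, d[4])
  Y
}

#' @export
layer_backward.nn_conv2d <- function(l, dy) {
  geo <- l$geo
  C <- geo$in_dim[1]
  dim(dy) <- c(l$out_ch, length(dy) %/% l$out_ch)
  l$gW <- tcrossprod(dy, l$cache)
  if (!is.null(l$b)) l$gb <- rowSums(dy)
  if (isTRUE(l$skip_input_grad)) return(NULL)
  dP <- crossprod(l$W, dy)
  g <- numeric(prod(geo$pad_dim))
  rows <- seq_len(C)
  for (o in seq_along(geo$lin)) {
    tgt <- geo$lin[[o]]
    g[tgt] <- g[tgt] + dP[(o - 1L) * C + rows, ]
  }
  dx <- if (l$pad > 0L) g[geo$interior] else g
  dim(dx) <- geo$in_dim
  dx
}

#' @export
nn_params.nn_conv2d <- function(l) {
  out <- list(list(env = l, par = "W", grad = "gW", decay = TRUE))
  if (!is.null(l$b))
    out <- c(out, list(list(env = l, par = "b", grad = "gb", decay = FALSE)))
  out
}

# ---- batch normalization ----------------------------------------------------

nn_batchnorm <- function(C, momentum = 0.1, eps = 1e-5) {
  new_layer("nn_batchnorm",
            C = C, momentum = momentum, eps = eps,
            gamma = rep(1, C), beta = numeric(C),
            rmean = numeric(C), rvar = rep(1, C),
            ggamma = NULL, gbeta = NULL, cache = NULL)
}

#' @export
layer_forward.nn_batchnorm <- function(l, x, training = FALSE) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(l$C, length(x) %/% l$C)
  M <- ncol(xm)
  if (training) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowSums(xc^2) / M
    ivar <- 1 / sqrt(v + l$eps)
    xhat <- xc * ivar
    mom <- l$momentum
    l$rmean <- (1 - mom) * l$rmean + mom * mu
    l$rvar <- (1 - mom) * l$rvar + mom * v * M / max(M - 1, 1)
  } else {
    ivar <- 1 / sqrt(l$rvar + l$eps)
    xhat <- (xm - l$rmean) * ivar
  }
  l$cache <- list(xhat = xhat, ivar = ivar, M = M, dims = d,
                  training = training)
  array(l$gamma * xhat + l$beta, d)
}

#' @export
layer_backward.nn_batchnorm <- function(l, dy) {
  ca <- l$cache
  dym <- dy
  dim(dym) <- c(l$C, length(dy) %/% l$C)
  l$ggamma <- rowSums(dym * ca$xhat)
  l$gbeta <- rowSums(dym)
  if (ca$training) {
    dxhat <- dym * l$gamma
    dx <- ca$ivar *
      (dxhat - rowSums(dxhat) / ca$M - ca$xhat * rowSums(dxhat * ca$xhat) / ca$M)
  } else {
    dx <- dym * l$gamma * ca$ivar
  }
  array(dx, ca$dims)
}

#' @export
nn_params.nn_batchnorm <- function(l) {
  list(list(env = l, par = "gamma", grad = "ggamma", decay = FALSE),
       list(env = l, par = "beta", grad = "gbeta", decay = FALSE))
}

# ---- activations and pooling ------------------------------------------------

nn_relu <- function() new_layer("nn_relu", mask = NULL)

#' @export
layer_forward.nn_relu <- function(l, x, training = FALSE) {
  l$mask <- x > 0
  x * l$mask
}

#' @export
layer_backward.nn_relu <- function(l, dy) dy * l$mask

nn_maxpool <- function(kernel = 3L, stride = 2L, pad = 1L) {
  new_layer("nn_maxpool", kernel = as.integer(kernel),
            stride = as.integer(stride), pad = as.integer(pad), cache = NULL)
}

#' @export
layer_forward.nn_maxpool <- function(l, x, training = FALSE) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; Wd <- d[3]; N <- d[4]
  k <- l$kernel; s <- l$stride; p <- l$pad
  Ho <- (H + 2L * p - k) %/% s + 1L
  Wo <- (Wd + 2L * p - k) %/% s + 1L
  pd <- c(C, H + 2L * p, Wd + 2L * p, N)
  geo <- l$geo
  if (is.null(geo) || !identical(geo$in_dim, d)) {
    idx <- array(seq_len(prod(pd)), pd)
    lin <- vector("list", k * k)
    for (o in seq_len(k * k)) {
      ki <- (o - 1L) %% k
      kj <- (o - 1L) %/% k
      hsel <- ki + 1L + s * (seq_len(Ho) - 1L)
      wsel <- kj + 1L + s * (seq_len(Wo) - 1L)
      lin[[o]] <- as.vector(idx[, hsel, wsel, , drop = FALSE])
    }
    geo <- list(in_dim = d, lin = lin,
                interior = as.vector(idx[, p + seq_len(H), p + seq_len(Wd), ,
                                         drop = FALSE]))
    l$geo <- geo
  }
  xpad <- rep(-Inf, prod(pd))
  xpad[geo$interior] <- x
  M <- C * Ho * Wo * N
  vals <- matrix(0, M, k * k)
  for (o in seq_len(k * k)) vals[, o] <- xpad[geo$lin[[o]]]
  amax <- max.col(vals, ties.method = "first")
  y <- vals[cbind(seq_len(M), amax)]
  l$cache <- list(amax = amax, pad_len = prod(pd))
  dim(y) <- c(C, Ho, Wo, N)
  y
}

#' @export
layer_backward.nn_maxpool <- function(l, dy) {
  ca <- l$cache
  geo <- l$geo
  g <- numeric(ca$pad_len)
  dyv <- as.vector(dy)
  for (o in seq_along(geo$lin)) {
    sel <- ca$amax == o
    if (any(sel)) {
      tgt <- geo$lin[[o]][sel]
      g[tgt] <- g[tgt] + dyv[sel]
    }
  }
  dx <- g[geo$interior]
  dim(dx) <- geo$in_dim
  dx
}

# Global average pooling: (C, H, W, N) -> feature matrix (C, N).
nn_gap <- function() new_layer("nn_gap", cache = NULL)

#' @export
layer_forward.nn_gap <- function(l, x, training = FALSE) {
  d <- dim(x)
  HW <- d[2] * d[3]
  xm <- matrix(x, d[1])
  y <- matrix(0, d[1], d[4])
  for (n in seq_len(d[4]))
    y[, n] <- rowMeans(xm[, (n - 1L) * HW + seq_len(HW), drop = FALSE])
  l$cache <- list(dims = d, HW = HW)
  y
}

#' @export
layer_backward.nn_gap <- function(l, dy) {
  ca <- l$cache
  f <- dy[, rep(seq_len(ca$dims[4]), each = ca$HW), drop = FALSE] / ca$HW
  array(f, ca$dims)
}

# ---- fully connected --------------------------------------------------------

nn_dense <- function(din, dout) {
  new_layer("nn_dense", din = din, dout = dout,
            W = he_init(dout, din, fan = din), b = numeric(dout),
            gW = NULL, gb = NULL, cache = NULL)
}

#' @export
layer_forward.nn_dense <- function(l, x, training = FALSE) {
  l$cache <- x
  l$W %*% x + l$b
}

#' @export
layer_backward.nn_dense <- function(l, dy) {
  l$gW <- dy %*% t(l$cache)
  l$gb <- rowSums(dy)
  crossprod(l$W, dy)
}

#' @export
nn_params.nn_dense <- function(l) {
  list(list(env = l, par = "W", grad = "gW", decay = TRUE),
       list(env = l, par = "b", grad = "gb", decay = FALSE))
}

# ---- wavelength attention ---------------------------------------------------

# Channel attention over spectral bands: per-channel global max and average
# descriptors pass through a shared two-layer bottleneck (1x1 convolutions,
# i.e. dense maps W0: C -> C/r with ReLU, then W1: C/r -> C); the two branch
# outputs are summed and squashed by a sigmoid, and the input is rescaled
# channel-wise by the resulting attention weights. Biases are zero-initialized
# so an all-zero input yields attention exactly 0.5. The expansion weights
# start small so the gate opens near the neutral 0.5 everywhere: a hard
# random gate at initialization can suppress the informative channels before
# the backbone has learned to use them and strand training in a bad optimum
# (same reasoning as zero-initializing residual branches).
nn_wa <- function(C, reduction) {
  if (C %% reduction != 0)
    stopf("channels (%d) must be divisible by the reduction ratio (%d)",
          C, reduction)
  Cr <- C %/% reduction
  new_layer("nn_wa", C = C, r = reduction,
            W0 = he_init(Cr, C, fan = C), b0 = numeric(Cr),
            W1 = 0.1 * he_init(C, Cr, fan = Cr), b1 = numeric(C),
            gW0 = NULL, gb0 = NULL, gW1 = NULL, gb1 = NULL,
            attention = NULL, cache = NULL)
}

#' @export
layer_forward.nn_wa <- function(l, x, training = FALSE) {
  d <- dim(x)
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  xm <- x
  dim(xm) <- c(C, HW * N)
  x3 <- aperm(array(x, c(C, HW, N)), c(1, 3, 2))   # (C, N, HW)
  xavg <- rowMeans(x3, dims = 2)
  xmax <- matrix(0, C, N)
  amax <- matrix(0L, C, N)
  for (n in seq_len(N)) {
    blk <- xm[, (n - 1L) * HW + seq_len(HW), drop = FALSE]
    j <- max.col(blk, ties.method = "first")
    amax[, n] <- j
    xmax[, n] <- blk[cbind(seq_len(C), j)]
  }
  pre_a <- l$W0 %*% xavg + l$b0
  pre_m <- l$W0 %*% xmax + l$b0
  h_a <- pre_a * (pre_a > 0)
  h_m <- pre_m * (pre_m > 0)
  z <- (l$W1 %*% h_a + l$b1) + (l$W1 %*% h_m + l$b1)
  s <- 1 / (1 + exp(-z))
  f <- s[, rep(seq_len(N), each = HW), drop = FALSE]
  l$attention <- s
  l$cache <- list(xm = xm, xavg = xavg, xmax = xmax, amax = amax,
                  pre_a = pre_a, pre_m = pre_m, h_a = h_a, h_m = h_m,
                  s = s, f = f, dims = d, HW = HW)
  array(xm * f, d)
}

#' @export
layer_backward.nn_wa <- function(l, dy) {
  ca <- l$cache
  d <- ca$dims
  C <- d[1]; HW <- ca$HW; N <- d[4]
  dym <- dy
  dim(dym) <- c(C, HW * N)
  # gradient through the attention weights
  tmp <- dym * ca$xm
  ds <- rowSums(aperm(array(tmp, c(C, HW, N)), c(1, 3, 2)), dims = 2)
  dz <- ds * ca$s * (1 - ca$s)
  l$gW1 <- dz %*% t(ca$h_a + ca$h_m)
  l$gb1 <- 2 * rowSums(dz)
  dh <- crossprod(l$W1, dz)
  da <- dh * (ca$pre_a > 0)
  dm <- dh * (ca$pre_m > 0)
  l$gW0 <- da %*% t(ca$xavg) + dm %*% t(ca$xmax)
  l$gb0 <- rowSums(da) + rowSums(dm)
  if (isTRUE(l$skip_input_grad)) return(NULL)
  dxavg <- crossprod(l$W0, da)
  dxmax <- crossprod(l$W0, dm)
  # product rule: gradient through the rescaled input, plus the attention
  # branches — average spreads evenly, max routes to the argmax pixel
  dx <- dym * ca$f +
    dxavg[, rep(seq_len(N), each = HW), drop = FALSE] / HW
  for (n in seq_len(N)) {
    cols <- (n - 1L) * HW + ca$amax[, n]
    idx <- cbind(seq_len(C), cols)
    dx[idx] <- dx[idx] + dxmax[, n]
  }
  dim(dx) <- d
  dx
}

#' @export
nn_params.nn_wa <- function(l) {
  list(list(env = l, par = "W0", grad = "gW0", decay = TRUE),
       list(env = l, par = "b0", grad = "gb0", decay = FALSE),
       list(env = l, par = "W1", grad = "gW1", decay = TRUE),
       list(env = l, par = "b1", grad = "gb1", decay = FALSE))
}

# ---- residual block ---------------------------------------------------------

# Standard basic block: conv3x3(stride)-BN-ReLU-conv3x3-BN plus an identity
# shortcut, or a 1x1 stride-matched projection when shape changes; ReLU after
# the addition.
nn_resblock <- function(in_ch, out_ch, stride = 1L) {
  down <- stride != 1L || in_ch != out_ch
  new_layer("nn_resblock",
            conv1 = nn_conv2d(in_ch, out_ch, 3L, stride, 1L),
            bn1 = nn_batchnorm(out_ch),
            relu1 = nn_relu(),
            conv2 = nn_conv2d(out_ch, out_ch, 3L, 1L, 1L),
            bn2 = nn_batchnorm(out_ch),
            down_conv = if (down) nn_conv2d(in_ch, out_ch, 1L, stride, 0L),
            down_bn = if (down) nn_batchnorm(out_ch),
            out_mask = NULL)
}

#' @export
layer_forward.nn_resblock <- function(l, x, training = FALSE) {
  h <- layer_forward(l$conv1, x, training)
  h <- layer_forward(l$bn1, h, training)
  h <- layer_forward(l$relu1, h, training)
  h <- layer_forward(l$conv2, h, training)
  h <- layer_forward(l$bn2, h, training)
  sc <- if (!is.null(l$down_conv)) {
    layer_forward(l$down_bn, layer_forward(l$down_conv, x, training), training)
  } else x
  y <- h + sc
  l$out_mask <- y > 0
  y * l$out_mask
}

#' @export
layer_backward.nn_resblock <- function(l, dy) {
  dy <- dy * l$out_mask
  g <- layer_backward(l$bn2, dy)
  g <- layer_backward(l$conv2, g)
  g <- layer_backward(l$relu1, g)
  g <- layer_backward(l$bn1, g)
  dx <- layer_backward(l$conv1, g)
  dsc <- if (!is.null(l$down_conv)) {
    layer_backward(l$down_conv, layer_backward(l$down_bn, dy))
  } else dy
  dx + dsc
}

#' @export
nn_params.nn_resblock <- function(l) {
  subs <- list(l$conv1, l$bn1, l$conv2, l$bn2)
  if (!is.null(l$down_conv)) subs <- c(subs, list(l$down_conv, l$down_bn))
  do.call(c, lapply(subs, nn_params))
}
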