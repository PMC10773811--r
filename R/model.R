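#' Focal loss hyperparameters
#'
#' `alpha` weights the positive (viable) class; the negative class receives
#' `1 - alpha`. `gamma` is the focusing exponent that down-weights easy
#' samples: the modulating factor `(1 - p_t)^gamma` vanishes as the predicted
#' probability of the true class approaches 1. With `gamma = 0` the loss
#' reduces to alpha-weighted cross entropy. With the viable majority as the
#' positive class, the canonical `alpha = 0.25` places weight 0.75 on the
#' non-viable minority.
#'
#' @param alpha positive-class weight, strictly in (0, 1). Default 0.25.
#' @param gamma focusing exponent `>= 0`. Default 2.
#' @param reduction `"mean"` or `"sum"`.
#' @return Object of class `focal_loss_params`.
#' @export
focal_loss_params <- function(alpha = 0.25, gamma = 2, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1)
    stopf("`alpha` must be strictly between 0 and 1")
  if (!is_number(gamma) || gamma < 0) stopf("`gamma` must be >= 0")
  structure(list(alpha = alpha, gamma = gamma, reduction = reduction),
            class = "focal_loss_params")
}

PROB_EPS <- 1e-7

#' Focal loss
#'
#' Cross entropy modulated by `(1 - p_t)^gamma` and the class weight
#' `alpha_t`: `FL = -alpha_t * (1 - p_t)^gamma * log(p_t)`, where
#' `p_t` is the predicted probability of the true class (`p` when `y = 1`,
#' `1 - p` otherwise) and `alpha_t = alpha` for positives, `1 - alpha` for
#' negatives. Probabilities are clamped to `[1e-7, 1 - 1e-7]` before the log.
#'
#' @param x either a numeric vector of per-sample probabilities of the true
#'   class (`p_t`), or an `N x 2` matrix of logits with columns
#'   (non-viable, viable) from which class probabilities are obtained by
#'   softmax.
#' @param labels integer vector in `{0, 1}`; `1` = viable (positive).
#' @param params a [focal_loss_params()].
#' @return The reduced loss (scalar).
#' @examples
#' # gamma = 0, alpha = 0.5, p_t = 0.5 reduces to 0.5 * log(2)
#' focal_loss(0.5, labels = 1, params = focal_loss_params(0.5, 0))
#' @export
focal_loss <- function(x, labels, params = focal_loss_params()) {
  stopifnot(inherits(params, "focal_loss_params"))
  if (!all(labels %in% c(0, 1)))
    stopf("labels must be 0 (non-viable) or 1 (viable)")
  if (is.matrix(x)) {
    if (ncol(x) != 2L) stopf("logit matrix must have 2 columns")
    if (nrow(x) != length(labels)) stopf("logits and labels length mismatch")
    z <- t(x)                      # -> (2, N)
    z <- z - rep(apply(z, 2L, max), each = 2L)
    p <- exp(z)
    p <- p / rep(colSums(p), each = 2L)
    pt <- p[cbind(labels + 1L, seq_along(labels))]
  } else {
    if (length(x) != length(labels)) stopf("p_t and labels length mismatch")
    pt <- as.numeric(x)
  }
  pt <- pmin(pmax(pt, PROB_EPS), 1 - PROB_EPS)
  at <- ifelse(labels == 1, params$alpha, 1 - params$alpha)
  per <- -at * (1 - pt)^params$gamma * log(pt)
  if (params$reduction == "mean") mean(per) else sum(per)
}

# Loss + gradient on logits (2 x N engine layout), mean-reduced.
# `loss` is "ce" (plain cross entropy) or "focal".
loss_and_grad <- function(logits, labels, loss = c("focal", "ce"),
                          params = focal_loss_params()) {
  loss <- match.arg(loss)
  N <- ncol(logits)
  z <- logits - rep(apply(logits, 2L, max), each = nrow(logits))
  e <- exp(z)
  p <- e / rep(colSums(e), each = nrow(logits))
  ti <- labels + 1L
  sel <- cbind(ti, seq_len(N))
  u <- pmin(pmax(p[sel], PROB_EPS), 1 - PROB_EPS)
  if (loss == "ce") {
    lval <- mean(-log(u))
    dz <- p
    dz[sel] <- dz[sel] - 1
    dz <- dz / N
  } else {
    at <- ifelse(labels == 1, params$alpha, 1 - params$alpha)
    g <- params$gamma
    lval <- mean(-at * (1 - u)^g * log(u))
    # dL/du, with the gamma * (1-u)^(gamma-1) term dropped when gamma == 0
    dldu <- if (g == 0) -at / u
            else -at * ((1 - u)^g / u - g * (1 - u)^(g - 1) * log(u))
    # softmax jacobian: dp_t/dz_j = u * (1[j = t] - p_j)
    dz <- -p * rep(dldu * u, each = nrow(logits))
    dz[sel] <- dz[sel] + dldu * u
    dz <- dz / N
  }
  list(loss = lval, dlogits = dz, probs = p)
}

#' Network architecture configuration
#'
#' @param in_channels number of input spectral channels `C`.
#' @param num_classes output classes (default 2).
#' @param width stem output width; stages use `width, 2w, 4w, 8w`.
#'   Default 64 (full scale); reduce (e.g. 8) for quick experiments.
#' @param input_size spatial side length of inputs, `>= 16` (default 64).
#' @return Object of class `net_config`.
#' @export
net_config <- function(in_channels, num_classes = 2, width = 64,
                       input_size = 64) {
  stopifnot(is_count(in_channels, 1), is_count(num_classes, 2))
  if (!is_count(width, 8)) stopf("`width` must be an integer >= 8")
  if (!is_count(input_size, 16)) stopf("`input_size` must be an integer >= 16")
  structure(list(in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 width = as.integer(width),
                 input_size = as.integer(input_size)),
            class = "net_config")
}

#' Wavelength-attention configuration
#'
#' The bottleneck maps `C` channels to `C / reduction` and back; with the
#' full 176-band sensor and the default `reduction = 16` the bottleneck
#' width is 11.
#'
#' @param channels number of spectral channels `C`.
#' @param reduction bottleneck divisor `r`; must divide `C`. Default 16.
#' @return Object of class `wa_config`.
#' @export
wa_config <- function(channels, reduction = 16) {
  stopifnot(is_count(channels, 2), is_count(reduction, 1))
  if (channels %% reduction != 0)
    stopf("`channels` (%d) must be divisible by `reduction` (%d)",
          channels, reduction)
  structure(list(channels = as.integer(channels),
                 reduction = as.integer(reduction)),
            class = "wa_config")
}

build_backbone <- function(net) {
  w <- net$width
  layers <- list(
    stem_conv = nn_conv2d(net$in_channels, w, 3L, 2L, 1L),
    stem_bn = nn_batchnorm(w),
    stem_relu = nn_relu(),
    stem_pool = nn_maxpool(3L, 2L, 1L),
    s1b1 = nn_resblock(w, w, 1L),
    s1b2 = nn_resblock(w, w, 1L),
    s2b1 = nn_resblock(w, 2L * w, 2L),
    s2b2 = nn_resblock(2L * w, 2L * w, 1L),
    s3b1 = nn_resblock(2L * w, 4L * w, 2L),
    s3b2 = nn_resblock(4L * w, 4L * w, 1L),
    s4b1 = nn_resblock(4L * w, 8L * w, 2L),
    s4b2 = nn_resblock(8L * w, 8L * w, 1L),
    gap = nn_gap(),
    fc = nn_dense(8L * w, net$num_classes))
  layers
}

new_model <- function(layers, net, wa = NULL) {
  # the gradient with respect to the model input is never consumed, so the
  # first layer may skip its (expensive) input-gradient computation
  layers[[1]]$skip_input_grad <- TRUE
  e <- new.env(parent = emptyenv())
  e$record <- NULL
  structure(list(layers = layers, net = net, wa = wa, env = e),
            class = "wanet")
}

#' Build the wavelength-attention residual classifier (WAResNet)
#'
#' The forward pass applies the wavelength-attention module to the input
#' cube, then a ResNet18-style backbone adapted to small inputs: a 3x3
#' stride-2 stem (in place of the usual 7x7), a 3x3 stride-2 max pool, four
#' stages of two basic residual blocks with identity/projection shortcuts,
#' global average pooling, and a fully connected layer producing class
#' logits. Pairing this architecture with focal loss during training gives
#' the Focal-WAResNet configuration.
#'
#' @param net a [net_config()].
#' @param wa a [wa_config()]; its `channels` must equal `net$in_channels`.
#' @param seed RNG seed for weight initialization.
#' @return Object of class `wanet`.
#' @seealso [build_resnet18_baseline()], [get_attention()], [train_model()]
#' @export
build_waresnet <- function(net, wa = wa_config(net$in_channels), seed = 1) {
  stopifnot(inherits(net, "net_config"), inherits(wa, "wa_config"))
  if (wa$channels != net$in_channels)
    stopf("wa_config channels (%d) differ from net in_channels (%d)",
          wa$channels, net$in_channels)
  layers <- with_rng_seed(seed, {
    c(list(wa = nn_wa(wa$channels, wa$reduction)), build_backbone(net))
  })
  new_model(layers, net, wa)
}

#' Build the plain ResNet18-style baseline
#'
#' Identical to [build_waresnet()] without the wavelength-attention module;
#' the ablation baseline. Train it under cross entropy or focal loss to
#' realize the four ablation arms (baseline/attention x CE/focal).
#'
#' @inheritParams build_waresnet
#' @return Object of class `wanet`.
#' @export
build_resnet18_baseline <- function(net, seed = 1) {
  stopifnot(inherits(net, "net_config"))
  layers <- with_rng_seed(seed, build_backbone(net))
  new_model(layers, net, NULL)
}

# Forward pass through the whole model. Returns logits (num_classes x N).
# With record = TRUE, per-layer outputs are stashed in model$env$record.
model_forward <- function(model, x, training = FALSE, record = FALSE) {
  if (dim(x)[2] < 16L || dim(x)[3] < 16L)
    stopf("input spatial size %dx%d is below the minimum of 16",
          dim(x)[2], dim(x)[3])
  acts <- if (record) list()
  for (nm in names(model$layers)) {
    x <- layer_forward(model$layers[[nm]], x, training)
    if (record) acts[[nm]] <- x
  }
  model$env$record <- acts
  x
}

# Backward pass from a gradient on the logits. Optionally captures the
# gradient with respect to the output of layer `capture`.
model_backward <- function(model, dlogits, capture = NULL) {
  g <- dlogits
  captured <- NULL
  for (nm in rev(names(model$layers))) {
    if (!is.null(capture) && nm == capture) captured <- g
    g <- layer_backward(model$layers[[nm]], g)
  }
  list(dx = g, captured = captured)
}

model_params <- function(model) do.call(c, lapply(model$layers, nn_params))

#' Number of trainable parameters
#'
#' @param model a `wanet` model.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model_params(model),
             function(p) length(p$env[[p$par]]), 0))
}

#' Wavelength-attention forward computation
#'
#' Functional form of the attention module for a given input batch and
#' weight set: per-channel global max/average descriptors through the shared
#' bottleneck, sigmoid-squashed sum, channel-wise rescaling of the input.
#'
#' @param x numeric array `(C, H, W, N)`.
#' @param W0 bottleneck weight matrix `(C/r) x C`.
#' @param W1 expansion weight matrix `C x (C/r)`.
#' @param b0,b1 optional bias vectors (default zero).
#' @return List with `attention` (`C x N` matrix of weights in (0, 1)) and
#'   `output` (rescaled array shaped like `x`).
#' @export
wa_forward <- function(x, W0, W1, b0 = NULL, b1 = NULL) {
  stopifnot(length(dim(x)) == 4L)
  C <- dim(x)[1]
  l <- new_layer("nn_wa", C = C, r = 1L,
                 W0 = W0, b0 = if (is.null(b0)) numeric(nrow(W0)) else b0,
                 W1 = W1, b1 = if (is.null(b1)) numeric(nrow(W1)) else b1,
                 attention = NULL, cache = NULL)
  out <- layer_forward(l, x)
  list(attention = l$attention, output = out)
}

#' Per-channel attention of the last forward pass
#'
#' Runs the model on a batch in eval mode and returns the wavelength
#' attention averaged over the batch: a length-C vector in (0, 1) indicating
#' which spectral channels the network amplifies.
#'
#' @param model a `wanet` built with [build_waresnet()].
#' @param batch array `(C, S, S, N)` or list of [seed_sample()] objects.
#' @return Named numeric vector of length `C` (names are channel indices).
#' @export
get_attention <- function(model, batch) {
  if (is.null(model$wa))
    stopf("model was built without a wavelength-attention module")
  x <- if (is.list(batch)) samples_to_batch(batch) else batch
  model_forward(model, x, training = FALSE)
  att <- rowMeans(model$layers$wa$attention)
  names(att) <- seq_along(att)
  att
}

#' Assemble seed samples into an engine batch
#'
#' Stacks `S x S x C` sample cubes into the channel-first `(C, S, S, N)`
#' array layout the network consumes.
#'
#' @param samples list of [seed_sample()] objects.
#' @return Numeric array `(C, S, S, N)`.
#' @export
samples_to_batch <- function(samples) {
  stopifnot(length(samples) > 0)
  d <- dim(samples[[1]]$cube)
  x <- array(0, c(d[3], d[1], d[2], length(samples)))
  for (i in seq_along(samples))
    x[, , , i] <- aperm(samples[[i]]$cube, c(3, 1, 2))
  x
}

# ---- checkpointing ----------------------------------------------------------

snapshot_state <- function(model) {
  ps <- model_params(model)
  state <- lapply(ps, function(p) p$env[[p$par]])
  bns <- Filter(function(l) inherits(l, "nn_batchnorm"), flatten_layers(model))
  list(params = state,
       bn = lapply(bns, function(b) list(rmean = b$rmean, rvar = b$rvar)))
}

restore_state <- function(model, state) {
  ps <- model_params(model)
  stopifnot(length(ps) == length(state$params))
  for (i in seq_along(ps)) ps[[i]]$env[[ps[[i]]$par]] <- state$params[[i]]
  bns <- Filter(function(l) inherits(l, "nn_batchnorm"), flatten_layers(model))
  stopifnot(length(bns) == length(state$bn))
  for (i in seq_along(bns)) {
    bns[[i]]$rmean <- state$bn[[i]]$rmean
    bns[[i]]$rvar <- state$bn[[i]]$rvar
  }
  invisible(model)
}

flatten_layers <- function(model) {
  out <- list()
  for (l in model$layers) {
    if (inherits(l, "nn_resblock")) {
      subs <- list(l$conv1, l$bn1, l$relu1, l$conv2, l$bn2)
      if (!is.null(l$down_conv)) subs <- c(subs, list(l$down_conv, l$down_bn))
      out <- c(out, subs)
    } else out <- c(out, list(l))
  }
  out
}

#' Save and load model checkpoints
#'
#' `save_model()` writes a single-file checkpoint (serialized weights,
#' batch-norm statistics and architecture configuration) plus a human-
#' readable JSON sidecar `<path>.json` describing the architecture.
#' `load_model()` rebuilds the architecture and restores the weights;
#' evaluation after a round trip reproduces results exactly.
#'
#' @param model a `wanet` model.
#' @param path checkpoint file path.
#' @return `load_model()` returns the restored `wanet`.
#' @export
save_model <- function(model, path) {
  ck <- list(net = unclass(model$net),
             wa = if (!is.null(model$wa)) unclass(model$wa),
             state = snapshot_state(model))
  saveRDS(ck, path)
  jsonlite::write_json(list(net = unclass(model$net),
                            wa = if (!is.null(model$wa)) unclass(model$wa),
                            n_parameters = count_parameters(model)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  net <- do.call(net_config, ck$net)
  model <- if (!is.null(ck$wa)) {
    build_waresnet(net, do.call(wa_config, ck$wa))
  } else {
    build_resnet18_baseline(net)
  }
  restore_state(model, ck$state)
  model
}
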