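#' Training configuration
#'
#' @param epochs number of passes over the training set (default 30).
#' @param batch_size minibatch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param weight_decay L2 penalty on convolution/dense weights (default 1e-4).
#' @param optimizer only `"adam"` is provided.
#' @param seed RNG seed; fixes shuffling, augmentation and initialization of
#'   the run, making training deterministic.
#' @param loss `"focal"` or `"ce"`.
#' @param loss_params a [focal_loss_params()] (used when `loss = "focal"`).
#' @param rotate_degrees set of rotation angles sampled uniformly; the
#'   default right angles are applied exactly, with no interpolation.
#' @param hflip_prob probability of a horizontal flip (default 0.5).
#' @param scale_range isotropic rescale factor range within (0, 2),
#'   default `c(0.9, 1.1)`; rescaled cubes are centre-cropped or padded
#'   back to size.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 30, batch_size = 32, learning_rate = 1e-3,
                         weight_decay = 1e-4, optimizer = "adam", seed = 1,
                         loss = c("focal", "ce"),
                         loss_params = focal_loss_params(),
                         rotate_degrees = c(0, 90, 180, 270),
                         hflip_prob = 0.5, scale_range = c(0.9, 1.1)) {
  loss <- match.arg(loss)
  stopifnot(is_count(epochs, 1), is_count(batch_size, 1),
            learning_rate > 0, weight_decay >= 0,
            identical(optimizer, "adam"),
            hflip_prob >= 0, hflip_prob <= 1)
  if (length(scale_range) != 2 || scale_range[1] <= 0 || scale_range[2] >= 2 ||
      scale_range[1] > scale_range[2])
    stopf("`scale_range` must lie within (0, 2)")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 optimizer = optimizer, seed = as.integer(seed), loss = loss,
                 loss_params = loss_params, rotate_degrees = rotate_degrees,
                 hflip_prob = hflip_prob, scale_range = scale_range),
            class = "train_config")
}

rot90_cube <- function(cube, k) {
  k <- k %% 4L
  if (k == 0L) return(cube)
  for (i in seq_len(k)) {
    d <- dim(cube)
    # 90 degrees counter-clockwise: (r, c) -> (C - c + 1, r)
    cube <- aperm(cube, c(2, 1, 3))[rev(seq_len(d[2])), , , drop = FALSE]
  }
  cube
}

# Rescale spatially by `f`, then centre-crop or pad back to the original
# size. Padding uses the per-channel median of the border ring so the board
# background continues naturally.
rescale_cube <- function(cube, f) {
  d <- dim(cube)
  S <- d[1]
  S2 <- max(4L, round(S * f))
  if (S2 == S) return(cube)
  res <- array(EBImage::imageData(
    EBImage::resize(EBImage::Image(cube), w = S2, h = S2,
                    filter = "bilinear")), c(S2, S2, d[3]))
  if (S2 > S) {
    off <- (S2 - S) %/% 2L
    res[off + seq_len(S), off + seq_len(S), , drop = FALSE]
  } else {
    border <- rbind(cube[c(1, S), , ], aperm(cube[, c(1, S), ], c(2, 1, 3)))
    fill <- apply(matrix(border, ncol = d[3]), 2L, stats::median)
    out <- array(rep(fill, each = S * S), d)
    off <- (S - S2) %/% 2L
    out[off + seq_len(S2), off + seq_len(S2), ] <- res
    out
  }
}

#' Randomly augment one seed sample
#'
#' Online augmentation: a rotation drawn from the configured angle set
#' (right angles are exact index permutations; other angles use bilinear
#' interpolation), a horizontal flip with probability `hflip_prob`, and an
#' isotropic rescale within `scale_range` followed by a centre crop/pad back
#' to size. The label and the spectral axis are never touched. Randomness
#' comes from R's global RNG stream (seeded by [train_model()]).
#'
#' @param sample a [seed_sample()].
#' @param cfg a [train_config()] supplying the augmentation parameters.
#' @return An augmented [seed_sample()].
#' @export
augment_sample <- function(sample, cfg) {
  cube <- sample$cube
  ang <- if (length(cfg$rotate_degrees) > 1)
    sample(cfg$rotate_degrees, 1) else cfg$rotate_degrees
  if (ang %% 360 != 0) {
    if (ang %% 90 == 0) {
      cube <- rot90_cube(cube, ang %/% 90)
    } else {
      S <- dim(cube)[1]
      cube <- array(EBImage::imageData(
        EBImage::rotate(EBImage::Image(cube), ang, output.dim = c(S, S),
                        bg.col = stats::median(cube[c(1, S), , ]))),
        dim(cube))
    }
  }
  if (cfg$hflip_prob > 0 && stats::runif(1) < cfg$hflip_prob)
    cube <- cube[, rev(seq_len(dim(cube)[2])), , drop = FALSE]
  if (cfg$scale_range[1] != 1 || cfg$scale_range[2] != 1) {
    f <- stats::runif(1, cfg$scale_range[1], cfg$scale_range[2])
    cube <- rescale_cube(cube, f)
  }
  out <- sample
  out$cube <- cube
  out
}

adam_step <- function(params, lr, wd, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (p in params) {
    e <- p$env
    g <- e[[p$grad]]
    if (is.null(g)) next
    if (wd > 0 && p$decay) g <- g + wd * e[[p$par]]
    key <- paste0(".adam_", p$par)
    st <- e[[key]]
    if (is.null(st)) st <- list(m = g * 0, v = g * 0)
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    e[[key]] <- st
    mh <- st$m / (1 - beta1^t)
    vh <- st$v / (1 - beta2^t)
    e[[p$par]] <- e[[p$par]] - lr * mh / (sqrt(vh) + eps)
  }
}

predict_logits <- function(model, samples, batch_size = 64) {
  n <- length(samples)
  out <- matrix(0, n, 2)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    x <- samples_to_batch(samples[i:j])
    out[i:j, ] <- t(model_forward(model, x, training = FALSE))
    i <- j + 1L
  }
  out
}

#' Predicted class labels
#'
#' @param model a trained `wanet`.
#' @param samples list of [seed_sample()] objects.
#' @return Integer vector of predictions (1 viable, 0 non-viable).
#' @export
predict_labels <- function(model, samples) {
  lg <- predict_logits(model, samples)
  as.integer(max.col(lg, ties.method = "first") - 1L)
}

#' Train a classifier
#'
#' Minibatch training with online augmentation and Adam. Each epoch records
#' the mean training loss and the validation metrics; the returned model
#' carries the weights of the epoch with the best validation macro-F1
#' (ties resolved in favour of the earlier epoch). Runs are deterministic
#' given `cfg$seed`. A non-finite loss aborts with a diagnostic.
#'
#' @param model a `wanet` from [build_waresnet()] or
#'   [build_resnet18_baseline()]; modified in place and returned.
#' @param train_set,val_set non-empty lists of [seed_sample()] objects.
#' @param cfg a [train_config()].
#' @return List with `model` (best-validation weights restored) and
#'   `history`, a data.frame with one row per epoch
#'   (`epoch`, `train_loss`, `val_loss`, `val_accuracy`, `val_macro_f1`).
#' @export
train_model <- function(model, train_set, val_set, cfg = train_config()) {
  stopifnot(inherits(model, "wanet"), inherits(cfg, "train_config"),
            length(train_set) > 0, length(val_set) > 0)
  n <- length(train_set)
  history <- data.frame()
  best_f1 <- -Inf
  best_state <- NULL
  val_labels <- vapply(val_set, function(s) s$label, 0L)
  with_rng_seed(cfg$seed, {
    t_step <- 0L
    params <- model_params(model)
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      losses <- c()
      i <- 1L
      while (i <= n) {
        j <- min(i + cfg$batch_size - 1L, n)
        idx <- perm[i:j]
        batch <- lapply(train_set[idx], augment_sample, cfg = cfg)
        x <- samples_to_batch(batch)
        labels <- vapply(batch, function(s) s$label, 0L)
        logits <- model_forward(model, x, training = TRUE)
        lg <- loss_and_grad(logits, labels, cfg$loss, cfg$loss_params)
        if (!is.finite(lg$loss))
          stopf("non-finite loss at epoch %d (batch starting %d); %s",
                epoch, i, "lower the learning rate or check the inputs")
        model_backward(model, lg$dlogits)
        t_step <- t_step + 1L
        adam_step(params, cfg$learning_rate, cfg$weight_decay, t_step)
        losses <- c(losses, lg$loss)
        i <- j + 1L
      }
      vl <- predict_logits(model, val_set)
      vres <- loss_and_grad(t(vl), val_labels, cfg$loss, cfg$loss_params)
      vpred <- as.integer(max.col(vl, ties.method = "first") - 1L)
      vrep <- eval_report(vpred, val_labels)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = mean(losses), val_loss = vres$loss,
        val_accuracy = vrep$accuracy, val_macro_f1 = vrep$macro$f1))
      if (vrep$macro$f1 > best_f1) {
        best_f1 <- vrep$macro$f1
        best_state <- snapshot_state(model)
      }
    }
  })
  if (!is.null(best_state)) restore_state(model, best_state)
  list(model = model, history = history)
}

# Confusion counts and derived metrics with viable (label 1) as positive.
eval_report <- function(pred, labels) {
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  n <- tp + fp + fn + tn
  prf <- function(tp, fp, fn) {
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    list(precision = precision, recall = recall, f1 = f1)
  }
  pos <- prf(tp, fp, fn)
  neg <- prf(tn, fn, fp)  # swap roles: negatives as the class of interest
  macro <- list(precision = (pos$precision + neg$precision) / 2,
                recall = (pos$recall + neg$recall) / 2,
                f1 = (pos$f1 + neg$f1) / 2)
  structure(list(confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
                 accuracy = (tp + tn) / n,
                 positive = pos, negative = neg, macro = macro),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Confusion (viable = positive): TP", x$confusion["TP"],
      "FP", x$confusion["FP"], "FN", x$confusion["FN"],
      "TN", x$confusion["TN"], "\n")
  cat(sprintf("accuracy %.4f | macro P %.4f R %.4f F1 %.4f\n",
              x$accuracy, x$macro$precision, x$macro$recall, x$macro$f1))
  cat(sprintf("viable     P %.4f R %.4f F1 %.4f\n",
              x$positive$precision, x$positive$recall, x$positive$f1))
  cat(sprintf("non-viable P %.4f R %.4f F1 %.4f\n",
              x$negative$precision, x$negative$recall, x$negative$f1))
  invisible(x)
}

#' Evaluate a classifier on a test set
#'
#' Argmax predictions are scored against the labels with viable seeds as the
#' positive class: the 2x2 confusion matrix, accuracy, and precision/recall/
#' F1 both per class and macro-averaged (the unweighted mean over the two
#' classes, the robust headline under imbalance).
#'
#' @param model a trained `wanet`.
#' @param test_set non-empty list of [seed_sample()] objects.
#' @return Object of class `eval_report`: a list with `confusion`
#'   (`TP/FP/FN/TN`), `accuracy`, `positive`, `negative` and `macro`
#'   precision/recall/F1.
#' @export
evaluate_model <- function(model, test_set) {
  stopifnot(length(test_set) > 0)
  labels <- vapply(test_set, function(s) s$label, 0L)
  eval_report(predict_labels(model, test_set), labels)
}

#' Four-arm ablation: baseline/attention x cross-entropy/focal
#'
#' Trains `{ResNet18 + CE, ResNet18 + focal, WAResNet + CE,
#' WAResNet + focal}` under one shared configuration and seed, and evaluates
#' each on the test split. Isolates the contribution of the
#' wavelength-attention module and of the focal loss under class imbalance.
#'
#' @param dataset list with `train`, `val`, `test` lists of
#'   [seed_sample()] objects (each containing both classes).
#' @param cfg a [train_config()]; its `loss` field is overridden per arm.
#' @param net a [net_config()].
#' @param wa a [wa_config()] for the attention arms.
#' @return List with `reports` (named [evaluate_model()] reports), `models`,
#'   and `summary`, a data.frame with one row per arm (macro and per-class
#'   metrics, in percent).
#' @export
run_ablation <- function(dataset, cfg, net,
                         wa = wa_config(net$in_channels)) {
  stopifnot(all(c("train", "val", "test") %in% names(dataset)))
  for (part in c("train", "val", "test")) {
    labs <- vapply(dataset[[part]], function(s) s$label, 0L)
    if (length(unique(labs)) < 2)
      stopf("%s split does not contain both classes", part)
  }
  arms <- list(
    resnet18_ce = list(wa = FALSE, loss = "ce"),
    focal_resnet18 = list(wa = FALSE, loss = "focal"),
    waresnet_ce = list(wa = TRUE, loss = "ce"),
    focal_waresnet = list(wa = TRUE, loss = "focal"))
  reports <- list()
  models <- list()
  for (nm in names(arms)) {
    arm <- arms[[nm]]
    model <- if (arm$wa) build_waresnet(net, wa, seed = cfg$seed)
             else build_resnet18_baseline(net, seed = cfg$seed)
    acfg <- cfg
    acfg$loss <- arm$loss
    fit <- train_model(model, dataset$train, dataset$val, acfg)
    reports[[nm]] <- evaluate_model(fit$model, dataset$test)
    models[[nm]] <- fit$model
  }
  summary <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(arm = nm,
               accuracy = 100 * r$accuracy,
               macro_precision = 100 * r$macro$precision,
               macro_recall = 100 * r$macro$recall,
               macro_f1 = 100 * r$macro$f1,
               viable_recall = 100 * r$positive$recall,
               nonviable_recall = 100 * r$negative$recall)
  }))
  list(reports = reports, models = models, summary = summary)
}
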