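# Model interpretation: Grad-CAM heatmaps, last-layer feature embedding,
# and the attention-recovery score used as the package's quantitative
# benchmark on synthetic data with a known informative-channel mask.

#' Grad-CAM class activation heatmap
#'
#' Computes the gradient of a class score with respect to the feature maps
#' of a convolutional stage, averages the gradient spatially to obtain
#' per-channel weights, and forms `ReLU(sum_k w_k A_k)`, min-max normalized
#' to `[0, 1]`. The map localizes the image regions driving the class score.
#'
#' @param model a trained `wanet`.
#' @param sample a [seed_sample()] (or `S x S x C` array).
#' @param layer name of the stage whose output is targeted; one of the
#'   model's layer names (default `"s4b2"`, the last residual block).
#' @param target_class class whose score is explained: 1 viable (default)
#'   or 0 non-viable.
#' @param upsample if `TRUE` (default), bilinearly upsample the map to the
#'   input resolution.
#' @return List of class `grad_cam` with `values` (the normalized map),
#'   `raw` (pre-normalization, non-negative), `layer`, `target_class`.
#' @export
grad_cam <- function(model, sample, layer = "s4b2", target_class = 1,
                     upsample = TRUE) {
  stopifnot(inherits(model, "wanet"), target_class %in% c(0, 1))
  if (!layer %in% names(model$layers))
    stopf("unknown layer '%s'; available: %s", layer,
          paste(names(model$layers), collapse = ", "))
  cube <- if (inherits(sample, "seed_sample")) sample$cube else sample
  x <- array(aperm(cube, c(3, 1, 2)), c(dim(cube)[3], dim(cube)[1:2], 1))
  logits <- model_forward(model, x, training = FALSE, record = TRUE)
  acts <- model$env$record[[layer]]
  dlog <- matrix(0, nrow(logits), 1)
  dlog[target_class + 1L, 1] <- 1
  captured <- model_backward(model, dlog, capture = layer)$captured
  d <- dim(acts)
  w <- rowMeans(matrix(captured, d[1]))           # spatially averaged grads
  amat <- matrix(acts, d[1])
  cam <- matrix(colSums(amat * w), d[2], d[3])
  cam[cam < 0] <- 0
  raw <- cam
  if (max(cam) > 0) cam <- cam / max(cam)
  if (upsample && !identical(dim(cam), dim(cube)[1:2])) {
    cam <- EBImage::imageData(EBImage::resize(
      EBImage::Image(cam), w = dim(cube)[1], h = dim(cube)[2],
      filter = "bilinear"))
    cam[cam < 0] <- 0
    cam[cam > 1] <- 1
  }
  structure(list(values = cam, raw = raw, layer = layer,
                 target_class = as.integer(target_class)),
            class = "grad_cam")
}

#' False-RGB composite of a cube
#'
#' Three-band composite from the bands nearest 640, 550 and 460 nm,
#' each min-max scaled; a reproducible backdrop for heatmap overlays.
#'
#' @param cube an [hsi_cube()] or an `S x S x C` array with a wavelength
#'   attribute supplied via `wavelengths_nm`.
#' @param wavelengths_nm required when `cube` is a bare array.
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
false_rgb <- function(cube, wavelengths_nm = NULL) {
  if (inherits(cube, "hsi_cube")) {
    wavelengths_nm <- cube$wavelengths_nm
    cube <- cube$reflectance
  }
  if (is.null(wavelengths_nm)) stopf("wavelengths_nm required")
  bands <- vapply(c(640, 550, 460), function(t)
    which.min(abs(wavelengths_nm - t)), 0L)
  out <- array(0, c(dim(cube)[1:2], 3))
  for (i in 1:3) {
    b <- cube[, , bands[i]]
    rng <- range(b)
    out[, , i] <- if (diff(rng) > 0) (b - rng[1]) / diff(rng) else 0
  }
  out
}

#' Last-layer features before the classifier head
#'
#' Runs the model in eval mode and returns the global-average-pooled
#' backbone features (the representation t-SNE visualizes).
#'
#' @param model a `wanet`.
#' @param samples non-empty list of [seed_sample()] objects.
#' @param batch_size forward batch size.
#' @return `N x D` matrix, `D` = backbone output width.
#' @export
extract_features <- function(model, samples, batch_size = 64) {
  stopifnot(length(samples) > 0)
  n <- length(samples)
  i <- 1L
  out <- NULL
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    x <- samples_to_batch(samples[i:j])
    model_forward(model, x, training = FALSE, record = TRUE)
    feats <- t(model$env$record$gap)
    if (is.null(out)) out <- matrix(0, n, ncol(feats))
    out[i:j, ] <- feats
    i <- j + 1L
  }
  out
}

#' Two-dimensional t-SNE embedding of features
#'
#' Wraps the Barnes-Hut t-SNE implementation with a fixed seed for
#' deterministic coordinates.
#'
#' @param features `N x D` numeric matrix.
#' @param perplexity t-SNE perplexity; requires `N > 3 * perplexity`.
#' @param seed RNG seed.
#' @param max_iter optimization iterations (default 1000).
#' @return Object of class `embedding2d`: list with `coords` (`N x 2`),
#'   `perplexity`, `seed`.
#' @export
tsne_embed <- function(features, perplexity = 30, seed = 1, max_iter = 1000) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n <= 3 * perplexity)
    stopf("t-SNE requires N > 3 * perplexity (N = %d, perplexity = %g)",
          n, perplexity)
  coords <- with_rng_seed(seed,
    Rtsne::Rtsne(features, perplexity = perplexity, max_iter = max_iter,
                 check_duplicates = FALSE, pca = ncol(features) > 50,
                 verbose = FALSE)$Y)
  structure(list(coords = coords, perplexity = perplexity, seed = seed),
            class = "embedding2d")
}

#' Attention-recovery score
#'
#' Rank-based AUC measuring how well a per-channel attention vector
#' discriminates the truly informative channels from the rest (ties handled
#' by midranks). 1 means every informative channel outranks every
#' uninformative one; 0.5 is chance. On synthetic data with a planted
#' informative mask this is the package's quantitative stand-in for
#' characteristic-wavelength selection quality.
#'
#' @param attention numeric vector of per-channel attention values.
#' @param informative_mask logical vector of the same length with at least
#'   one `TRUE` and one `FALSE`.
#' @return AUC in `[0, 1]`.
#' @export
attention_recovery <- function(attention, informative_mask) {
  if (length(attention) != length(informative_mask))
    stopf("attention and mask lengths differ")
  informative_mask <- as.logical(informative_mask)
  n1 <- sum(informative_mask)
  n0 <- sum(!informative_mask)
  if (n1 == 0 || n0 == 0)
    stopf("informative mask must contain both TRUE and FALSE channels")
  r <- rank(attention)  # midranks for ties
  (sum(r[informative_mask]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Silhouette of a feature matrix by class label
#'
#' Mean silhouette width of the Euclidean feature space under the true
#' labels — the quantitative analogue of judging class separation in a
#' t-SNE plot.
#'
#' @param features `N x D` matrix.
#' @param labels class labels (length N, 2+ classes).
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
feature_silhouette <- function(features, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(features))
  mean(sil[, "sil_width"])
}
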