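#' Hyperspectral reflectance cube
#'
#' The central container of the package: a corrected reflectance cube
#' `I(X, Y, lambda)` with two spatial axes and one spectral axis, stored as an
#' `H x W x C` numeric array together with its wavelength axis and an optional
#' foreground mask.
#'
#' @param reflectance numeric `H x W x C` array of reflectance values; all
#'   values must be finite.
#' @param wavelengths_nm strictly increasing numeric vector of length `C`,
#'   the band-centre wavelengths in nanometres.
#' @param mask optional `H x W` logical matrix marking foreground (seed)
#'   pixels.
#' @return An object of class `hsi_cube` (a list with elements `reflectance`,
#'   `wavelengths_nm`, `mask`).
#' @examples
#' cube <- hsi_cube(array(0.5, c(4, 4, 3)), c(400, 500, 600))
#' dim(cube$reflectance)
#' @export
hsi_cube <- function(reflectance, wavelengths_nm, mask = NULL) {
  if (!is.array(reflectance) || length(dim(reflectance)) != 3L)
    stopf("`reflectance` must be an H x W x C array")
  if (!all(is.finite(reflectance)))
    stopf("`reflectance` contains non-finite values")
  C <- dim(reflectance)[3L]
  if (length(wavelengths_nm) != C)
    stopf("length(wavelengths_nm) = %d but cube has %d bands",
          length(wavelengths_nm), C)
  if (C > 1L && any(diff(wavelengths_nm) <= 0))
    stopf("`wavelengths_nm` must be strictly increasing")
  if (!is.null(mask)) {
    if (!is.logical(mask)) mask <- mask != 0
    if (!identical(dim(mask), dim(reflectance)[1:2]))
      stopf("`mask` dimensions must match the spatial dimensions of the cube")
  }
  structure(list(reflectance = reflectance,
                 wavelengths_nm = as.numeric(wavelengths_nm),
                 mask = mask),
            class = "hsi_cube")
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$reflectance)
  cat(sprintf("<hsi_cube> %d x %d pixels, %d bands (%.1f-%.1f nm)%s\n",
              d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm),
              if (is.null(x$mask)) "" else ", with mask"))
  invisible(x)
}

#' Uncorrected hyperspectral scene with reference frames
#'
#' Holds a raw intensity frame `I` together with the black (shutter closed)
#' and white (reference panel) frames `I_b`, `I_w` used for reflectance
#' correction. References may be full `H x W x C` arrays or per-band vectors
#' of length `C` (broadcast over pixels).
#'
#' @param raw numeric `H x W x C` array of non-negative raw intensities.
#' @param black_ref,white_ref reference frames; arrays shaped like `raw` or
#'   numeric vectors of length `C`.
#' @param wavelengths_nm strictly increasing band-centre wavelengths (nm).
#' @return An object of class `raw_scene`.
#' @seealso [correct_reflectance()]
#' @export
raw_scene <- function(raw, black_ref, white_ref, wavelengths_nm) {
  if (!is.array(raw) || length(dim(raw)) != 3L)
    stopf("`raw` must be an H x W x C array")
  if (any(raw < 0)) stopf("`raw` intensities must be non-negative")
  C <- dim(raw)[3L]
  if (length(wavelengths_nm) != C)
    stopf("wavelength axis length %d does not match %d bands",
          length(wavelengths_nm), C)
  if (C > 1L && any(diff(wavelengths_nm) <= 0))
    stopf("`wavelengths_nm` must be strictly increasing")
  chk <- function(x, nm) {
    if (is.array(x) && length(dim(x)) == 3L) {
      if (!identical(dim(x), dim(raw))) stopf("`%s` shape differs from `raw`", nm)
    } else if (!(is.numeric(x) && length(x) == C)) {
      stopf("`%s` must be an array shaped like `raw` or a length-C vector", nm)
    }
    x
  }
  structure(list(raw = raw,
                 black_ref = chk(black_ref, "black_ref"),
                 white_ref = chk(white_ref, "white_ref"),
                 wavelengths_nm = as.numeric(wavelengths_nm)),
            class = "raw_scene")
}

# Broadcast a per-band reference vector to the full cube shape.
broadcast_ref <- function(x, dims) {
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  array(rep(x, each = dims[1] * dims[2]), dims)
}

#' One segmented seed ready for classification
#'
#' @param cube numeric `S x S x C` reflectance array at the model input
#'   resolution.
#' @param label integer class: `1` viable, `0` non-viable.
#' @param sample_id character identifier.
#' @param aging_group optional provenance tag (e.g. aging treatment).
#' @param bbox optional source bounding box `c(r0, c0, r1, c1)` (1-based,
#'   inclusive) in the original scene.
#' @return Object of class `seed_sample`.
#' @export
seed_sample <- function(cube, label, sample_id = NA_character_,
                        aging_group = NA_character_, bbox = NULL) {
  if (!is.array(cube) || length(dim(cube)) != 3L || dim(cube)[1] != dim(cube)[2])
    stopf("`cube` must be an S x S x C array")
  if (!label %in% c(0, 1)) stopf("`label` must be 0 (non-viable) or 1 (viable)")
  structure(list(cube = cube, label = as.integer(label),
                 meta = list(sample_id = sample_id,
                             aging_group = aging_group, bbox = bbox)),
            class = "seed_sample")
}

#' Black/white reference reflectance correction
#'
#' Converts raw sensor counts to reflectance with the standard two-point
#' calibration `I_o = (I - I_b) / (I_w - I_b)`, removing uneven illumination
#' and dark current. The correction is invariant to any common positive
#' rescaling of the three frames. Specular pixels can exceed 1, so values are
#' clipped to `[0, clip_max]`.
#'
#' @param scene a [raw_scene()].
#' @param clip_max upper reflectance clip (default 1.5).
#' @return An [hsi_cube()] with the scene's wavelength axis.
#' @examples
#' sc <- raw_scene(array(1, c(2, 2, 1)), black_ref = 0, white_ref = 2,
#'                 wavelengths_nm = 500)
#' correct_reflectance(sc)$reflectance[1, 1, 1]  # 0.5
#' @export
correct_reflectance <- function(scene, clip_max = 1.5) {
  stopifnot(inherits(scene, "raw_scene"))
  d <- dim(scene$raw)
  ib <- broadcast_ref(scene$black_ref, d)
  iw <- broadcast_ref(scene$white_ref, d)
  den <- iw - ib
  if (any(den <= 0)) {
    bad <- which(apply(den <= 0, 3L, any))
    stopf("white reference does not exceed black reference in band(s): %s",
          paste(bad, collapse = ", "))
  }
  refl <- (scene$raw - ib) / den
  refl[refl < 0] <- 0
  refl[refl > clip_max] <- clip_max
  hsi_cube(refl, scene$wavelengths_nm)
}

#' Segment seeds from a dark-board scene
#'
#' Thresholds the band-averaged reflectance image with Otsu's method, fills
#' enclosed holes (pinholes never bridge distinct seeds, unlike a closing),
#' labels connected foreground components, and drops components below a
#' minimum area. Components are returned ordered by bounding-box top-left
#' corner (row, then column).
#'
#' @param cube an [hsi_cube()].
#' @param min_area smallest component area kept, in pixels (default 25).
#' @return A list of components, each a list with `mask` (`H x W` logical) and
#'   `bbox` (`c(r0, c0, r1, c1)`, 1-based inclusive). Empty list when no
#'   component survives.
#' @export
segment_seeds <- function(cube, min_area = 25) {
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$reflectance)
  avg <- matrix(rowMeans(matrix(cube$reflectance, d[1] * d[2], d[3])),
                d[1], d[2])
  rng <- range(avg)
  if (diff(rng) <= 0) return(list())  # flat image: nothing to segment
  thr <- EBImage::otsu(EBImage::Image(avg), range = rng)
  bw <- EBImage::imageData(EBImage::fillHull(EBImage::Image(avg > thr)))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw)))
  out <- list()
  for (k in seq_len(max(lab))) {
    m <- lab == k
    if (sum(m) < min_area) next
    rr <- range(which(rowSums(m) > 0))
    cc <- range(which(colSums(m) > 0))
    out[[length(out) + 1L]] <- list(mask = m,
                                    bbox = c(rr[1], cc[1], rr[2], cc[2]))
  }
  if (length(out) > 1L) {
    key <- vapply(out, function(o) o$bbox[1] * (d[2] + 1) + o$bbox[2], 0)
    out <- out[order(key)]
  }
  out
}

#' Mean spectrum over a pixel mask
#'
#' The per-band arithmetic mean of the reflectance over masked pixels — the
#' "average spectral curve" representation of one seed.
#'
#' @param cube an [hsi_cube()].
#' @param mask `H x W` logical matrix with at least one `TRUE` pixel;
#'   defaults to the cube's own mask.
#' @return Numeric vector of length `C`.
#' @export
mean_spectrum <- function(cube, mask = cube$mask) {
  stopifnot(inherits(cube, "hsi_cube"))
  if (is.null(mask)) stopf("no mask supplied and the cube carries none")
  if (!is.logical(mask)) mask <- mask != 0
  d <- dim(cube$reflectance)
  if (!identical(dim(mask), d[1:2])) stopf("mask dimensions do not match cube")
  if (!any(mask)) stopf("mask is empty")
  colMeans(matrix(cube$reflectance, d[1] * d[2], d[3])[as.vector(mask), ,
                                                       drop = FALSE])
}

#' Crop a bounding box and resample to the model resolution
#'
#' Channel-wise bilinear resampling (pixel-centre convention) of a cropped
#' region to `size x size`, as used to normalize segmented seeds before
#' classification. Constant regions stay constant and an `S x S` crop is
#' returned unchanged.
#'
#' @param cube an [hsi_cube()].
#' @param bbox `c(r0, c0, r1, c1)` 1-based inclusive bounding box.
#' @param size output side length (default 64).
#' @return `size x size x C` numeric array.
#' @export
crop_resize <- function(cube, bbox, size = 64) {
  stopifnot(inherits(cube, "hsi_cube"), length(bbox) == 4L)
  d <- dim(cube$reflectance)
  if (bbox[1] < 1 || bbox[2] < 1 || bbox[3] > d[1] || bbox[4] > d[2] ||
      bbox[3] < bbox[1] || bbox[4] < bbox[2])
    stopf("bbox [%s] is empty or outside the cube", paste(bbox, collapse = ", "))
  crop <- cube$reflectance[bbox[1]:bbox[3], bbox[2]:bbox[4], , drop = FALSE]
  res <- EBImage::resize(EBImage::Image(crop), w = size, h = size,
                         filter = "bilinear")
  array(EBImage::imageData(res), c(size, size, d[3]))
}

#' Train/validation/test split by largest-remainder apportionment
#'
#' Splits `n` samples at the given ratios. Global split sizes are fixed by
#' largest-remainder apportionment of `n` (e.g. 1133 at 8:1:1 gives
#' 907/113/113). Under stratification the per-class allocations are rounded
#' subject to those global sizes, so each class's proportion is preserved to
#' within one sample per split.
#'
#' @param labels class label per sample (any atomic vector), or a list of
#'   [seed_sample()] objects; its length defines `n`.
#' @param ratios positive split weights, default `c(8, 1, 1)`.
#' @param seed RNG seed controlling the shuffle; same seed, same split.
#' @param stratified preserve class proportions per split (default `TRUE`).
#' @return List with integer index vectors `train`, `val`, `test`; disjoint
#'   and jointly exhaustive.
#' @export
split_dataset <- function(labels, ratios = c(8, 1, 1), seed = 1,
                          stratified = TRUE) {
  if (is.list(labels) && length(labels) && inherits(labels[[1]], "seed_sample"))
    labels <- vapply(labels, function(s) s$label, 0L)
  n <- length(labels)
  stopifnot(all(ratios > 0), n >= length(ratios))
  k <- length(ratios)
  sizes <- largest_remainder(n, ratios)
  idx_sets <- vector("list", k)
  if (!stratified) {
    perm <- with_rng_seed(seed, sample.int(n))
    ends <- cumsum(sizes)
    starts <- c(1L, head(ends, -1L) + 1L)
    for (s in seq_len(k)) idx_sets[[s]] <- sort(perm[starts[s]:ends[s]])
  } else {
    classes <- sort(unique(labels))
    ncls <- vapply(classes, function(cl) sum(labels == cl), 0L)
    if (any(ncls < k))
      stopf("class '%s' has fewer samples than splits; cannot stratify",
            classes[which(ncls < k)[1]])
    # per-class quotas, floored; leftover units assigned greedily by
    # fractional remainder subject to the global split capacities
    quota <- outer(ncls, ratios / sum(ratios))
    base <- floor(quota)
    take <- matrix(0L, length(classes), k)
    cap <- sizes - colSums(base)
    need <- ncls - rowSums(base)
    if (any(cap < 0) || any(need < 0))
      stopf("ratios too extreme for stratified split at n = %d", n)
    frac <- quota - base
    ord <- order(-frac)
    for (pos in ord) {
      i <- (pos - 1L) %% length(classes) + 1L
      j <- (pos - 1L) %/% length(classes) + 1L
      if (need[i] > 0L && cap[j] > 0L) {
        g <- min(need[i], cap[j], 1L)
        take[i, j] <- take[i, j] + g
        need[i] <- need[i] - g
        cap[j] <- cap[j] - g
      }
    }
    # force any residue into remaining capacity
    while (any(need > 0L)) {
      i <- which(need > 0L)[1L]
      j <- which(cap > 0L)[1L]
      take[i, j] <- take[i, j] + 1L
      need[i] <- need[i] - 1L
      cap[j] <- cap[j] - 1L
    }
    alloc <- base + take
    perm_by_class <- with_rng_seed(seed, lapply(classes, function(cl)
      sample(which(labels == cl))))
    for (s in seq_len(k)) idx_sets[[s]] <- integer(0)
    for (ci in seq_along(classes)) {
      pool <- perm_by_class[[ci]]
      ends <- cumsum(alloc[ci, ])
      starts <- c(1L, head(ends, -1L) + 1L)
      for (s in seq_len(k))
        if (alloc[ci, s] > 0)
          idx_sets[[s]] <- c(idx_sets[[s]], pool[starts[s]:ends[s]])
    }
    idx_sets <- lapply(idx_sets, sort)
  }
  names(idx_sets) <- if (k == 3L) c("train", "val", "test")
                     else paste0("split", seq_len(k))
  idx_sets
}
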