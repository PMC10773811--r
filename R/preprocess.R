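#' A set of spectra sharing one wavelength axis
#'
#' Thin container for an `N x C` matrix of reflectance spectra (rows are
#' samples) plus its wavelength axis. All preprocessing transforms accept
#' either a `spectrum_set` or a bare matrix and return the same kind.
#'
#' @param values numeric `N x C` matrix, all finite.
#' @param wavelengths_nm strictly increasing numeric vector of length `C`.
#' @return Object of class `spectrum_set`.
#' @export
spectrum_set <- function(values, wavelengths_nm) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stopf("`values` contains non-finite entries")
  if (length(wavelengths_nm) != ncol(values))
    stopf("wavelength axis length differs from spectrum length")
  if (ncol(values) > 1L && any(diff(wavelengths_nm) <= 0))
    stopf("`wavelengths_nm` must be strictly increasing")
  structure(list(values = values, wavelengths_nm = as.numeric(wavelengths_nm)),
            class = "spectrum_set")
}

spec_values <- function(x) if (inherits(x, "spectrum_set")) x$values else as.matrix(x)

spec_rewrap <- function(x, values) {
  if (inherits(x, "spectrum_set")) spectrum_set(values, x$wavelengths_nm)
  else values
}

#' Mean centering (MC)
#'
#' Subtracts the per-channel column mean, removing the common offset so that
#' between-class contrasts dominate. The centering vector can be supplied
#' (e.g. estimated on a training split and applied frozen elsewhere).
#'
#' @param x `spectrum_set` or `N x C` matrix.
#' @param center length-C centering vector; defaults to the column means of
#'   `x` itself.
#' @return Same type as `x`; column means are zero when `center` is internal.
#' @export
mean_center <- function(x, center = NULL) {
  v <- spec_values(x)
  if (is.null(center)) center <- colMeans(v)
  if (length(center) != ncol(v)) stopf("`center` has wrong length")
  spec_rewrap(x, sweep(v, 2L, center))
}

#' Moving average smoothing (MA)
#'
#' Centred mean filter along the spectral axis with reflect padding at the
#' edges.
#'
#' @param x `spectrum_set` or matrix.
#' @param window odd window length `<= C` (default 5).
#' @return Same type as `x`.
#' @export
moving_average <- function(x, window = 5) {
  v <- spec_values(x)
  C <- ncol(v)
  if (!is_count(window, 1) || window %% 2 == 0)
    stopf("`window` must be an odd positive integer")
  if (window > C) stopf("`window` (%d) exceeds number of channels (%d)",
                        window, C)
  if (window == 1) return(x)
  h <- (window - 1L) / 2L
  pad_idx <- c(rev(seq_len(h) + 1L), seq_len(C), C - seq_len(h))
  vp <- v[, pad_idx, drop = FALSE]
  ker <- rep(1 / window, window)
  out <- t(apply(vp, 1L, function(r)
    stats::filter(r, ker, sides = 2)[(h + 1L):(h + C)]))
  if (nrow(v) == 1L) out <- matrix(out, 1L)
  spec_rewrap(x, out)
}

#' Standard normal variate (SNV)
#'
#' Standardizes each spectrum to mean 0 and standard deviation 1, removing
#' per-sample multiplicative scatter and offset. Invariant to positive
#' affine transforms of a spectrum.
#'
#' @param x `spectrum_set` or matrix; every row must have non-zero sd.
#' @return Same type as `x`.
#' @export
snv <- function(x) {
  v <- spec_values(x)
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  if (any(sdv == 0))
    stopf("constant spectrum in row(s): %s",
          paste(which(sdv == 0), collapse = ", "))
  spec_rewrap(x, (v - mu) / sdv)
}

#' Multiplicative scatter correction (MSC)
#'
#' Regresses each spectrum on a reference spectrum, `x ~ a * ref + b`, and
#' returns `(x - b) / a`. A spectrum generated as `a * ref + b` is restored
#' exactly to `ref`.
#'
#' @param x `spectrum_set` or matrix.
#' @param reference `"mean"` (column mean of `x`; the usual choice, or fit it
#'   on a training split and pass the vector here) or a length-C spectrum.
#' @return Same type as `x`.
#' @export
msc <- function(x, reference = "mean") {
  v <- spec_values(x)
  ref <- if (identical(reference, "mean")) colMeans(v) else as.numeric(reference)
  if (length(ref) != ncol(v)) stopf("`reference` has wrong length")
  refc <- ref - mean(ref)
  ss <- sum(refc^2)
  if (ss == 0) stopf("reference spectrum has zero variance")
  a <- as.numeric((v - rowMeans(v)) %*% refc) / ss
  if (any(abs(a) < 1e-8))
    stopf("fitted slope ~ 0 in row(s): %s",
          paste(which(abs(a) < 1e-8), collapse = ", "))
  b <- rowMeans(v) - a * mean(ref)
  spec_rewrap(x, (v - b) / a)
}

#' Savitzky-Golay smoothing and derivatives (SG / FD / SD)
#'
#' Local least-squares polynomial convolution along the spectral axis.
#' `deriv = 0` smooths (SG), `deriv = 1` and `2` give the first (FD) and
#' second (SD) derivatives with respect to channel index (bands are close to
#' uniformly spaced in nm, so index spacing is the conventional choice).
#' Polynomials up to `polyorder` are reproduced exactly in the interior.
#'
#' @param x `spectrum_set` or matrix.
#' @param window odd filter length, `polyorder < window <= C` (default 7).
#' @param polyorder fitted polynomial degree (default 2).
#' @param deriv derivative order, one of 0, 1, 2; `deriv <= polyorder`.
#' @return Same type as `x`.
#' @export
savgol <- function(x, window = 7, polyorder = 2, deriv = 0) {
  v <- spec_values(x)
  C <- ncol(v)
  if (!is_count(window, 1) || window %% 2 == 0)
    stopf("`window` must be odd")
  if (window > C) stopf("`window` exceeds number of channels")
  if (polyorder >= window) stopf("`polyorder` must be < `window`")
  if (!deriv %in% 0:2) stopf("`deriv` must be 0, 1 or 2")
  if (deriv > polyorder) stopf("`deriv` must be <= `polyorder`")
  out <- t(apply(v, 1L, signal::sgolayfilt, p = polyorder, n = window,
                 m = deriv))
  if (nrow(v) == 1L) out <- matrix(out, 1L)
  spec_rewrap(x, out)
}

# ---- wavelet denoising ------------------------------------------------------

# Daubechies-4 (8-tap) orthonormal scaling filter.
DB4_LO <- c(0.230377813308855230, 0.714846570552541500,
            0.630880767929590400, -0.027983769416983850,
            -0.187034811718881140, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278)

# Orthogonal analysis matrix of one periodized DWT level for even length n:
# rows 1..n/2 are the shifted low-pass filter, rows n/2+1..n the high-pass.
# Orthonormality gives exact reconstruction via the transpose.
dwt_level_matrix <- function(n) {
  h <- DB4_LO
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  L <- length(h)
  W <- matrix(0, n, n)
  for (k in seq_len(n / 2)) {
    for (m in seq_len(L)) {
      j <- ((2 * (k - 1) + (m - 1)) %% n) + 1
      W[k, j] <- W[k, j] + h[m]
      W[n / 2 + k, j] <- W[n / 2 + k, j] + g[m]
    }
  }
  W
}

#' Wavelet denoising (WT)
#'
#' Per-spectrum periodized orthonormal db4 wavelet decomposition, soft
#' thresholding of the detail coefficients, and reconstruction. With
#' `threshold = 0` the reconstruction equals the input to float tolerance.
#' The default `"universal"` rule uses `sigma * sqrt(2 log C)` with `sigma`
#' estimated from the median absolute deviation of the finest-level detail
#' coefficients (per spectrum).
#'
#' Spectra are symmetrically extended on both sides (to a multiple of
#' `2^level`) before the transform and truncated after reconstruction, which
#' keeps the periodic wrap-around of the transform away from the data and
#' suppresses edge artifacts.
#'
#' @param x `spectrum_set` or matrix.
#' @param level decomposition depth (default 3). Too deep a level for the
#'   spectrum length is an error.
#' @param threshold `"universal"` or a non-negative number applied to all
#'   detail coefficients.
#' @return Same type as `x`.
#' @export
wavelet_denoise <- function(x, level = 3, threshold = "universal") {
  v <- spec_values(x)
  C <- ncol(v)
  if (!is_count(level, 1)) stopf("`level` must be a positive integer")
  blk <- 2^level
  n <- ceiling((C + 2L * blk + 8L) / blk) * blk
  if (n / 2^level < length(DB4_LO))
    stopf("level %d too deep for %d channels (coarsest length %d < filter %d)",
          level, C, n / 2^level, length(DB4_LO))
  # symmetric extension on both sides to a multiple of 2^level
  pl <- (n - C) %/% 2L
  pr <- n - C - pl
  if (pl > C || pr > C)
    stopf("level %d too deep for %d channels", level, C)
  pad_idx <- c(rev(seq_len(pl)), seq_len(C), C + 1L - seq_len(pr))
  Ws <- list()
  len <- n
  for (l in seq_len(level)) {
    Ws[[l]] <- dwt_level_matrix(len)
    len <- len / 2
  }
  soft <- function(d, t) sign(d) * pmax(abs(d) - t, 0)
  out <- v
  for (i in seq_len(nrow(v))) {
    s <- v[i, pad_idx]
    approx <- s
    details <- vector("list", level)
    for (l in seq_len(level)) {
      y <- Ws[[l]] %*% approx
      half <- length(approx) / 2
      approx <- y[seq_len(half)]
      details[[l]] <- y[half + seq_len(half)]
    }
    thr <- if (identical(threshold, "universal")) {
      sigma <- stats::median(abs(details[[1]])) / 0.6745
      sigma * sqrt(2 * log(n))
    } else {
      if (!is_number(threshold) || threshold < 0)
        stopf("`threshold` must be \"universal\" or a non-negative number")
      threshold
    }
    if (thr > 0) details <- lapply(details, soft, t = thr)
    for (l in rev(seq_len(level)))
      approx <- crossprod(Ws[[l]], c(approx, details[[l]]))
    out[i, ] <- approx[pl + seq_len(C)]
  }
  spec_rewrap(x, out)
}

#' Apply a named preprocessing transform
#'
#' Dispatcher used by the command-line interface and convenient for
#' comparing the full transform family programmatically.
#'
#' @param x `spectrum_set` or matrix.
#' @param method one of `"mc"`, `"ma"`, `"snv"`, `"msc"`, `"sg"`, `"fd"`,
#'   `"sd"`, `"wt"`.
#' @param ... passed to the underlying transform.
#' @return Same type as `x`.
#' @export
preprocess_spectra <- function(x, method, ...) {
  method <- match.arg(tolower(method),
                      c("mc", "ma", "snv", "msc", "sg", "fd", "sd", "wt"))
  switch(method,
         mc = mean_center(x, ...),
         ma = moving_average(x, ...),
         snv = snv(x),
         msc = msc(x, ...),
         sg = savgol(x, deriv = 0, ...),
         fd = savgol(x, deriv = 1, ...),
         sd = savgol(x, deriv = 2, ...),
         wt = wavelet_denoise(x, ...))
}

#' Apply a spectral transform to every pixel of a cube
#'
#' Reshapes the cube to a pixels-by-channels matrix, applies the transform,
#' and restores the spatial layout; equivalent to transforming each pixel's
#' spectrum individually.
#'
#' @param cube an [hsi_cube()].
#' @param method,... as in [preprocess_spectra()].
#' @return An [hsi_cube()] with transformed reflectance.
#' @export
preprocess_cube <- function(cube, method, ...) {
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$reflectance)
  m <- matrix(cube$reflectance, d[1] * d[2], d[3])
  res <- preprocess_spectra(m, method, ...)
  out <- cube
  out$reflectance <- array(res, d)
  out
}
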