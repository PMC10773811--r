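#' Configuration of the synthetic hyperspectral seed generator
#'
#' Defines the study conditions the generator emulates: seeds as bright
#' elliptical regions on a near-black board, two classes whose mean spectra
#' differ only inside stated wavelength windows (non-viable reflecting more
#' than viable), a class imbalance matching a germination-test outcome of
#' 915 viable / 218 non-viable, and the three nuisance components every
#' chemometric transform targets — per-seed multiplicative scatter, per-seed
#' additive baseline offset, and i.i.d. per-pixel noise.
#'
#' @param n_seeds number of seeds to generate (default 1133).
#' @param imbalance fraction of the viable class, strictly in (0, 1);
#'   default `915/1133`.
#' @param n_channels number of spectral bands. Default 60 (desk scale);
#'   set 176 for the full-sensor scale.
#' @param wavelength_range_nm band-centre range, default `c(393.7, 1001.4)`.
#' @param informative_windows list of `c(first, last)` channel windows
#'   (1-based, inclusive) carrying the class signal. The default maps the
#'   393.7–580 nm and 620–950 nm ranges onto the channel axis.
#' @param effect_size reflectance offset (non-viable minus viable) inside
#'   informative windows; `>= 0`. Default 0.08.
#' @param scatter_sd sd of the per-seed multiplicative scatter factor
#'   `a ~ N(1, scatter_sd)`. Default 0.05.
#' @param noise_sd sd of i.i.d. per-pixel additive noise. Default 0.02.
#' @param drift_amp sd of the per-seed additive baseline offset
#'   `b ~ N(0, drift_amp)`. Default 0.02.
#' @param resolution side length of generated per-seed cubes. Default 32
#'   (desk scale); the full-scale protocol uses 64.
#' @param seed RNG seed; identical configs regenerate identical data.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_seeds = 1133, imbalance = 915 / 1133,
                         n_channels = 60,
                         wavelength_range_nm = c(393.7, 1001.4),
                         informative_windows = NULL,
                         effect_size = 0.08, scatter_sd = 0.05,
                         noise_sd = 0.02, drift_amp = 0.02,
                         resolution = 32, seed = 1) {
  stopifnot(is_count(n_seeds, 1), is_count(n_channels, 2),
            is_count(resolution, 8), is_count(seed))
  if (!is_number(imbalance) || imbalance <= 0 || imbalance >= 1)
    stopf("`imbalance` must be strictly between 0 and 1")
  if (effect_size < 0) stopf("`effect_size` must be >= 0")
  if (scatter_sd < 0 || noise_sd < 0 || drift_amp < 0)
    stopf("spread parameters must be >= 0")
  wl <- seq(wavelength_range_nm[1], wavelength_range_nm[2],
            length.out = n_channels)
  if (is.null(informative_windows))
    informative_windows <- default_windows(wl)
  prev_end <- 0
  for (w in informative_windows) {
    if (length(w) != 2L || w[1] > w[2] || w[1] < 1 || w[2] > n_channels)
      stopf("window [%s] outside 1..%d or reversed",
            paste(w, collapse = ", "), n_channels)
    if (w[1] <= prev_end)
      stopf("informative windows overlap or are unordered")
    prev_end <- w[2]
  }
  structure(list(n_seeds = as.integer(n_seeds), imbalance = imbalance,
                 n_channels = as.integer(n_channels),
                 wavelengths_nm = wl,
                 informative_windows = informative_windows,
                 effect_size = effect_size, scatter_sd = scatter_sd,
                 noise_sd = noise_sd, drift_amp = drift_amp,
                 resolution = as.integer(resolution),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Channel windows for the 393.7-580 nm and 620-950 nm ranges on a given axis.
default_windows <- function(wl) {
  win <- function(lo, hi) {
    idx <- which(wl >= lo & wl <= hi)
    c(min(idx), max(idx))
  }
  list(win(min(wl), 580), win(620, 950))
}

window_mask <- function(config) {
  m <- logical(config$n_channels)
  for (w in config$informative_windows) m[w[1]:w[2]] <- TRUE
  m
}

#' Class endmember spectra with a planted, window-limited difference
#'
#' Builds two smooth non-negative spectra from low-frequency basis functions
#' (a broad reflectance ramp, a red-edge-like sigmoid and a water-absorption
#' valley, echoing the shared peak/valley structure of real seed spectra).
#' The two classes are identical outside the informative windows; inside
#' them the non-viable endmember sits exactly `effect_size` above the viable
#' one — aged, non-viable seeds reflect more.
#'
#' @param config a [synth_config()].
#' @return Matrix `2 x C` with rows `viable`, `non_viable`.
#' @export
make_endmembers <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  wl <- config$wavelengths_nm
  u <- (wl - 393.7) / (1001.4 - 393.7)
  base <- 0.22 + 0.25 / (1 + exp(-(wl - 700) / 40)) +  # red-edge-like rise
    0.08 * sin(2 * pi * u) -                            # gentle undulation
    0.10 * exp(-((wl - 970) / 28)^2) +                  # water band valley
    0.05 * exp(-((wl - 480) / 45)^2)                    # blue bump
  base <- pmax(base, 0.05)
  mask <- window_mask(config)
  viable <- base
  non_viable <- base + config$effect_size * mask
  rbind(viable = viable, non_viable = non_viable)
}

# Deterministic label vector with round(imbalance * n) viable seeds,
# shuffled under the config seed (offset so it does not collide with the
# streams used for geometry/noise).
synth_labels <- function(config, n = config$n_seeds) {
  n_viable <- round(config$imbalance * n)
  with_rng_seed(config$seed + 999L,
                sample(c(rep(1L, n_viable), rep(0L, n - n_viable))))
}

# Fill elliptical seed regions of a reflectance field.
# Returns the modified field plus realized per-seed masks.
paint_seeds <- function(refl, centers, radii, labels, config, endm) {
  d <- dim(refl)
  mlist <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    rr <- outer((seq_len(d[1]) - centers[i, 1]) / radii[i, 1], rep(1, d[2]))
    cc <- outer(rep(1, d[1]), (seq_len(d[2]) - centers[i, 2]) / radii[i, 2])
    m <- rr^2 + cc^2 <= 1
    mlist[[i]] <- m
    npix <- sum(m)
    a <- rnorm(1, 1, config$scatter_sd)
    b <- rnorm(1, 0, config$drift_amp)
    spec <- endm[labels[i] + 1L, ]  # endm row 1 = label 0, row 2 = label 1
    px <- outer(rep(a, npix), spec) + b +
      matrix(rnorm(npix * d[3], 0, config$noise_sd), npix, d[3])
    flat <- matrix(refl, d[1] * d[2], d[3])
    flat[as.vector(m), ] <- px
    refl <- array(flat, d)
  }
  list(refl = refl, masks = mlist)
}

#' Generate a synthetic raw scene with reference frames
#'
#' Places `n_in_scene` non-overlapping elliptical seeds on a near-black board
#' (background reflectance 0.02), draws each seed's per-pixel spectra from
#' its class endmember under the scatter/drift/noise model, and converts the
#' reflectance field to raw counts via `I = I_b + R (I_w - I_b)` so that
#' reflectance correction inverts it exactly.
#'
#' @param config a [synth_config()].
#' @param n_in_scene number of seeds to place (`>= 0`).
#' @param scene_dim optional `c(H, W)`; by default sized to fit the seeds on
#'   a jittered grid. Too small a scene raises a placement error.
#' @return List with `scene` ([raw_scene()]), `reflectance` (the realized
#'   reflectance field as an [hsi_cube()]), `masks` (list of per-seed
#'   `H x W` logicals, disjoint), and `labels` (1 viable / 0 non-viable).
#' @export
synth_raw_scene <- function(config, n_in_scene, scene_dim = NULL) {
  stopifnot(inherits(config, "synth_config"), is_count(n_in_scene))
  cell <- 26L; margin <- 8L
  if (is.null(scene_dim)) {
    g <- max(1L, ceiling(sqrt(n_in_scene)))
    scene_dim <- rep(g * cell + 2L * margin, 2L)
  }
  H <- scene_dim[1]; W <- scene_dim[2]
  grows <- (H - 2L * margin) %/% cell
  gcols <- (W - 2L * margin) %/% cell
  if (n_in_scene > 0 && grows * gcols < n_in_scene)
    stopf("scene %dx%d fits at most %d non-overlapping seeds, %d requested",
          H, W, grows * gcols, n_in_scene)
  em <- make_endmembers(config)
  endm <- rbind(em["non_viable", ], em["viable", ])  # row 1 = label 0
  C <- config$n_channels
  out <- with_rng_seed(config$seed, {
    labels <- if (n_in_scene > 0) {
      n_v <- round(config$imbalance * n_in_scene)
      sample(c(rep(1L, n_v), rep(0L, n_in_scene - n_v)))
    } else integer(0)
    refl <- array(0.02, c(H, W, C))
    masks <- list()
    if (n_in_scene > 0) {
      cells <- sample(grows * gcols)[seq_len(n_in_scene)]
      centers <- cbind(margin + ((cells - 1L) %/% gcols) * cell + cell / 2 +
                         runif(n_in_scene, -2, 2),
                       margin + ((cells - 1L) %% gcols) * cell + cell / 2 +
                         runif(n_in_scene, -2, 2))
      radii <- cbind(runif(n_in_scene, 6, 9), runif(n_in_scene, 6, 9))
      painted <- paint_seeds(refl, centers, radii, labels, config, endm)
      refl <- painted$refl
      masks <- painted$masks
    }
    list(refl = refl, masks = masks, labels = labels)
  })
  refl <- out$refl
  refl[refl < 0] <- 0
  wl <- config$wavelengths_nm
  ib <- 80 + 30 * seq(0, 1, length.out = C)     # dark current rises with band
  iw <- 3200 + 600 * sin(pi * seq(0, 1, length.out = C))  # lamp spectrum
  raw <- sweep(sweep(refl, 3L, iw - ib, "*"), 3L, ib, "+")
  list(scene = raw_scene(raw, ib, iw, wl),
       reflectance = hsi_cube(refl, wl),
       masks = out$masks,
       labels = out$labels)
}

#' Generate a labeled synthetic seed dataset with ground truth
#'
#' Draws `n_seeds` single-seed cubes at the configured model resolution:
#' one jittered ellipse per cube on the dark board, per-seed scatter and
#' baseline offset, per-pixel noise. Class counts equal
#' `round(imbalance * n)` exactly, and regenerating with the same config is
#' bit-identical.
#'
#' @param config a [synth_config()].
#' @return List with `samples` (list of [seed_sample()]) and `truth`, a list
#'   holding `labels`, the per-channel logical `informative_mask`, and
#'   `class_endmembers` (the `2 x C` matrix of [make_endmembers()]).
#' @export
synth_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  endm <- make_endmembers(config)
  labels <- synth_labels(config)
  S <- config$resolution
  C <- config$n_channels
  samples <- with_rng_seed(config$seed, {
    lapply(seq_len(config$n_seeds), function(i) {
      ctr <- S / 2 + runif(2, -0.05 * S, 0.05 * S)
      rad <- runif(2, 0.275 * S, 0.375 * S)
      refl <- array(0.02, c(S, S, C))
      painted <- paint_seeds(refl, matrix(ctr, 1), matrix(rad, 1),
                             labels[i], config,
                             rbind(endm["non_viable", ], endm["viable", ]))
      cube <- painted$refl
      cube[cube < 0] <- 0
      seed_sample(cube, labels[i],
                  sample_id = sprintf("synth_%04d", i),
                  aging_group = "synthetic")
    })
  })
  list(samples = samples,
       truth = list(labels = labels,
                    informative_mask = window_mask(config),
                    class_endmembers = endm))
}
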