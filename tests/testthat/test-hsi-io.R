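test_that("reflectance correction matches its defining identities", {
  wl <- c(400, 500, 600)
  ib <- array(50, c(4, 4, 3))
  iw <- array(250, c(4, 4, 3))
  sc_w <- raw_scene(iw, ib, iw, wl)
  expect_true(all(correct_reflectance(sc_w)$reflectance == 1))
  sc_b <- raw_scene(ib, ib, iw, wl)
  expect_true(all(correct_reflectance(sc_b)$reflectance == 0))
  sc_h <- raw_scene(array(1, c(4, 4, 3)), rep(0, 3), rep(2, 3), wl)
  expect_true(all(correct_reflectance(sc_h)$reflectance == 0.5))
})

test_that("reflectance correction is invariant to common rescaling", {
  set.seed(1)
  raw <- array(runif(4 * 5 * 3, 100, 900), c(4, 5, 3))
  ib <- array(runif(4 * 5 * 3, 0, 50), c(4, 5, 3))
  iw <- array(runif(4 * 5 * 3, 1000, 2000), c(4, 5, 3))
  wl <- c(400, 500, 600)
  r1 <- correct_reflectance(raw_scene(raw, ib, iw, wl))
  r2 <- correct_reflectance(raw_scene(3.7 * raw, 3.7 * ib, 3.7 * iw, wl))
  expect_equal(r1$reflectance, r2$reflectance, tolerance = 1e-12)
})

test_that("degenerate references are reported with the offending band", {
  wl <- c(400, 500)
  raw <- array(1, c(2, 2, 2))
  iw <- array(2, c(2, 2, 2))
  iw[1, 1, 2] <- 0  # below the black level in band 2
  expect_error(correct_reflectance(raw_scene(raw, array(1, c(2, 2, 2)) * 0.5,
                                             iw, wl)),
               "band.*2")
})

test_that("segmentation recovers planted seeds", {
  cfg <- synth_config(n_seeds = 5, n_channels = 8, seed = 13)
  sc <- synth_raw_scene(cfg, 3)
  cube <- correct_reflectance(sc$scene)
  comps <- segment_seeds(cube)
  expect_length(comps, 3)
  # match each component to its ground-truth mask by IoU
  for (comp in comps) {
    ious <- vapply(sc$masks, function(m)
      sum(m & comp$mask) / sum(m | comp$mask), 0)
    expect_gte(max(ious), 0.8)
  }
})

test_that("segmentation handles flat scenes and close pairs", {
  flat <- hsi_cube(array(0.02, c(20, 20, 3)), c(400, 500, 600))
  expect_length(segment_seeds(flat), 0)

  # two blobs separated by a 2-px background gap stay separate
  refl <- array(0.02, c(20, 30, 3))
  refl[5:14, 5:12, ] <- 0.6
  refl[5:14, 15:22, ] <- 0.6
  comps <- segment_seeds(hsi_cube(refl, c(400, 500, 600)))
  expect_length(comps, 2)
  expect_equal(comps[[1]]$bbox, c(5, 5, 14, 12))
  expect_equal(comps[[2]]$bbox, c(5, 15, 14, 22))
})

test_that("mean spectra are arithmetic means over masked pixels", {
  refl <- array(0, c(3, 3, 2))
  refl[1, 1, ] <- c(1, 2)
  refl[1, 2, ] <- c(3, 6)
  cube <- hsi_cube(refl + 0.5, c(400, 500))
  m1 <- matrix(FALSE, 3, 3); m1[1, 1] <- TRUE
  expect_equal(mean_spectrum(cube, m1), c(1.5, 2.5))
  m2 <- m1; m2[1, 2] <- TRUE
  expect_equal(mean_spectrum(cube, m2), c((1.5 + 3.5) / 2, (2.5 + 6.5) / 2))
  const <- hsi_cube(array(0.4, c(3, 3, 2)), c(400, 500))
  expect_equal(mean_spectrum(const, m2), c(0.4, 0.4))
  expect_error(mean_spectrum(cube, matrix(FALSE, 3, 3)), "empty")
})

test_that("crop_resize is bilinear with sane degenerate behaviour", {
  const <- hsi_cube(array(2.5, c(10, 8, 3)), c(400, 500, 600))
  out <- crop_resize(const, c(2, 2, 9, 7), size = 6)
  expect_equal(dim(out), c(6, 6, 3))
  expect_true(all(abs(out - 2.5) < 1e-12))

  set.seed(2)
  refl <- array(runif(6 * 6 * 2), c(6, 6, 2))
  cube <- hsi_cube(refl, c(400, 500))
  same <- crop_resize(cube, c(1, 1, 6, 6), size = 6)
  expect_equal(same, refl, tolerance = 1e-12)

  # downsampling a linear ramp keeps it linear with the same endpoints
  S <- 8
  ramp <- array(rep(seq(0, 1, length.out = 2 * S), times = 2 * S), c(2 * S, 2 * S, 1))
  cube_r <- hsi_cube(ramp, 500)
  down <- crop_resize(cube_r, c(1, 1, 2 * S, 2 * S), size = S)
  ideal <- seq(0, 1, length.out = S)
  step_in <- 1 / (2 * S - 1)
  expect_lt(max(abs(down[, 1, 1] - ideal)), 2 * step_in)
  expect_lt(max(abs(diff(down[, 1, 1]) - diff(down[, 1, 1])[1])), 1e-8)

  expect_error(crop_resize(cube, c(5, 5, 2, 2)), "empty|outside")
})

test_that("splits follow largest-remainder apportionment", {
  labels <- c(rep(1, 915), rep(0, 218))
  sp <- split_dataset(labels, c(8, 1, 1), seed = 4)
  expect_equal(lengths(sp), c(train = 907L, val = 113L, test = 113L))
  all_idx <- sort(unname(unlist(sp)))
  expect_equal(all_idx, seq_len(1133))        # exhaustive
  expect_equal(anyDuplicated(unlist(sp)), 0L) # disjoint
  # stratification: per-class proportions within one sample per split
  for (part in sp) {
    expect_lte(abs(sum(labels[part] == 0) - 218 / 1133 * length(part)), 1)
  }
  # unstratified keeps the same global sizes
  spu <- split_dataset(labels, c(8, 1, 1), seed = 4, stratified = FALSE)
  expect_equal(lengths(spu), c(train = 907L, val = 113L, test = 113L))
})

test_that("splits are deterministic and validate inputs", {
  labels <- rep(c(0, 1), 5)
  expect_equal(lengths(split_dataset(labels, c(8, 1, 1), seed = 1)),
               c(train = 8L, val = 1L, test = 1L))
  expect_identical(split_dataset(labels, seed = 42),
                   split_dataset(labels, seed = 42))
  expect_error(split_dataset(c(0, rep(1, 20)), c(8, 1, 1), seed = 1),
               "fewer samples than splits")
})

test_that("ENVI round trips are bit-identical across interleaves", {
  set.seed(5)
  refl <- array(runif(7 * 9 * 4), c(7, 9, 4))
  mask <- matrix(runif(63) > 0.5, 7, 9)
  cube <- hsi_cube(refl, c(400.5, 500.25, 600.125, 700), mask)
  for (il in c("bsq", "bil", "bip")) {
    path <- file.path(withr::local_tempdir(), paste0("cube_", il))
    write_envi(cube, path, interleave = il)
    back <- read_envi(paste0(path, ".hdr"))
    expect_identical(back$reflectance, refl)
    expect_identical(back$wavelengths_nm, cube$wavelengths_nm)
    expect_identical(back$mask, mask)
  }
})

test_that("ENVI reader validates headers", {
  tmp <- withr::local_tempdir()
  refl <- array(1, c(2, 2, 3))
  cube <- hsi_cube(refl, c(400, 500, 600))
  p <- file.path(tmp, "bad")
  write_envi(cube, p)
  # corrupt: drop one wavelength from the header
  hdr <- readLines(paste0(p, ".hdr"))
  hdr <- sub("wavelength = \\{.*\\}", "wavelength = { 400, 500 }", hdr)
  writeLines(hdr, paste0(p, ".hdr"))
  expect_error(read_envi(paste0(p, ".hdr")), "3 bands")
  hdr <- hdr[!grepl("^wavelength =", hdr)]
  writeLines(hdr, paste0(p, ".hdr"))
  expect_error(read_envi(paste0(p, ".hdr")), "wavelength")
})

test_that("native cube container preserves everything", {
  set.seed(6)
  cube <- hsi_cube(array(runif(4 * 4 * 2), c(4, 4, 2)), c(450, 650),
                   matrix(TRUE, 4, 4))
  path <- file.path(withr::local_tempdir(), "cube.rds")
  write_cube(cube, path)
  expect_identical(read_cube(path), cube)
})
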