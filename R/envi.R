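# ENVI header + raster I/O and the native cube container.
#
# ENVI files store a plain-text `.hdr` describing a headerless binary raster.
# Conventions: `samples` = image columns (X), `lines` = rows (Y); data are
# written little-endian; interleaves supported are BSQ (band sequential),
# BIL (band interleaved by line) and BIP (band interleaved by pixel).
# Doubles (ENVI data type 5) are the default so round trips are bit-exact.

envi_paths <- function(path) {
  base <- sub("\\.(hdr|dat|img)$", "", path)
  list(hdr = paste0(base, ".hdr"), dat = paste0(base, ".dat"),
       mask = paste0(base, "_mask.txt"))
}

#' Write a cube as an ENVI header + raster pair
#'
#' Writes `<base>.hdr` (text header including the wavelength list) and
#' `<base>.dat` (little-endian binary raster). A foreground mask, if present,
#' goes to a plain-text sidecar `<base>_mask.txt` of 0/1 rows.
#'
#' @param cube an [hsi_cube()].
#' @param path destination path; any `.hdr`/`.dat`/`.img` extension is
#'   stripped to form the pair.
#' @param interleave one of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type ENVI data type code: 4 (float32) or 5 (float64, default;
#'   bit-exact round trip).
#' @return Invisibly, the `.hdr` path.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       data_type = 5) {
  stopifnot(inherits(cube, "hsi_cube"), data_type %in% c(4, 5))
  interleave <- match.arg(interleave)
  p <- envi_paths(path)
  d <- dim(cube$reflectance)  # (lines, samples, bands)
  hdr <- c("ENVI",
           "description = {hsivigor reflectance cube}",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           sprintf("data type = %d", data_type),
           sprintf("interleave = %s", interleave),
           "byte order = 0",
           "wavelength units = Nanometers",
           sprintf("wavelength = { %s }",
                   paste(format(cube$wavelengths_nm, trim = TRUE,
                                digits = 15), collapse = ", ")))
  writeLines(hdr, p$hdr)
  x <- cube$reflectance
  # reorder to the requested interleave; as.vector of an array runs fastest
  # over the first dimension, and ENVI runs fastest over samples
  v <- switch(interleave,
    bsq = as.vector(aperm(x, c(2, 1, 3))),  # sample, line, band
    bil = as.vector(aperm(x, c(2, 3, 1))),  # sample, band, line
    bip = as.vector(aperm(x, c(3, 2, 1))))  # band, sample, line
  con <- file(p$dat, "wb")
  on.exit(close(con))
  writeBin(v, con, size = if (data_type == 5) 8L else 4L, endian = "little")
  if (!is.null(cube$mask))
    utils::write.table(matrix(as.integer(cube$mask), d[1], d[2]), p$mask,
                       row.names = FALSE, col.names = FALSE)
  invisible(p$hdr)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  kv <- list()
  # key = value, where value may be a { multi-line list }
  rx <- gregexpr("([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)",
                 txt, perl = TRUE)[[1]]
  starts <- rx
  lens <- attr(rx, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    eq <- regexpr("=", piece, fixed = TRUE)
    key <- tolower(trimws(substr(piece, 1L, eq - 1L)))
    val <- trimws(substr(piece, eq + 1L, nchar(piece)))
    kv[[key]] <- val
  }
  kv
}

#' Read an ENVI cube
#'
#' Parses the text header, checks that the wavelength list matches the band
#' count, and reads the raster in its declared interleave. A mask sidecar
#' written by [write_envi()] is picked up automatically.
#'
#' @param path path to the `.hdr` (or its `.dat` sibling).
#' @return An [hsi_cube()].
#' @export
read_envi <- function(path) {
  p <- envi_paths(path)
  if (!file.exists(p$hdr)) stopf("ENVI header not found: %s", p$hdr)
  kv <- parse_envi_header(p$hdr)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  for (k in need) if (is.null(kv[[k]])) stopf("ENVI header lacks key '%s'", k)
  if (is.null(kv[["wavelength"]]))
    stopf("ENVI header lacks key 'wavelength' (band centres required)")
  ns <- as.integer(kv[["samples"]]); nl <- as.integer(kv[["lines"]])
  nb <- as.integer(kv[["bands"]])
  dt <- as.integer(kv[["data type"]])
  if (!dt %in% c(4L, 5L)) stopf("unsupported ENVI data type %d", dt)
  il <- tolower(trimws(kv[["interleave"]]))
  wl <- as.numeric(strsplit(gsub("[{}]", "", kv[["wavelength"]]),
                            ",")[[1]])
  if (length(wl) != nb)
    stopf("header lists %d wavelengths but %d bands", length(wl), nb)
  con <- file(p$dat, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = ns * nl * nb,
               size = if (dt == 5L) 8L else 4L, endian = "little")
  if (length(v) != ns * nl * nb)
    stopf("raster %s is truncated", p$dat)
  x <- switch(il,
    bsq = aperm(array(v, c(ns, nl, nb)), c(2, 1, 3)),
    bil = aperm(array(v, c(ns, nb, nl)), c(3, 1, 2)),
    bip = aperm(array(v, c(nb, ns, nl)), c(3, 2, 1)),
    stopf("unsupported interleave '%s'", il))
  mask <- NULL
  if (file.exists(p$mask)) {
    mask <- as.matrix(utils::read.table(p$mask)) != 0
    dimnames(mask) <- NULL
  }
  hsi_cube(x, wl, mask)
}

#' Read or write a cube, dispatching on file extension
#'
#' `.hdr`/`.dat`/`.img` go through the ENVI pair ([read_envi()] /
#' [write_envi()]); `.rds` uses R's native serialization (exact round trip
#' including the mask).
#'
#' @param cube an [hsi_cube()] (write only).
#' @param path file path.
#' @param ... passed through to [write_envi()].
#' @return `read_cube()` returns an [hsi_cube()]; `write_cube()` its input,
#'   invisibly.
#' @export
write_cube <- function(cube, path, ...) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    stopifnot(inherits(cube, "hsi_cube"))
    saveRDS(cube, path)
  } else {
    write_envi(cube, path, ...)
  }
  invisible(cube)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    cube <- readRDS(path)
    stopifnot(inherits(cube, "hsi_cube"))
    cube
  } else {
    read_envi(path)
  }
}

#' Read and write per-seed label tables
#'
#' Plain CSV with columns `sample_id`, `label` (1 viable / 0 non-viable) and
#' `aging_group`.
#'
#' @param samples list of [seed_sample()] objects, or a data.frame with the
#'   three columns.
#' @param path CSV path.
#' @return `read_labels_csv()` returns a data.frame.
#' @export
write_labels_csv <- function(samples, path) {
  df <- if (is.data.frame(samples)) samples else
    data.frame(
      sample_id = vapply(samples, function(s) s$meta$sample_id, ""),
      label = vapply(samples, function(s) s$label, 0L),
      aging_group = vapply(samples, function(s)
        as.character(s$meta$aging_group), ""))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
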