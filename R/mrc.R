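## Minimal MRC2014 image / stack I/O.
##
## MRC is the standard container for electron-microscopy images: a fixed
## 1024-byte header followed by the voxel data, X axis fastest. Only 2-D
## images and stacks of equally-sized 2-D images are handled here. Output is
## always mode 2 (IEEE float32, little endian); modes 0 (int8), 1 (int16),
## 2 (float32) and 6 (uint16) are accepted on input.

#' Write a 2-D image or image stack as an MRC2014 file
#'
#' @param x A numeric matrix, or a list of equally-shaped numeric matrices
#'   (written as a stack along Z).
#' @param path Output file path.
#' @param pixel_size Physical pixel size in Angstrom per pixel, stored in the
#'   cell dimensions. Default 1.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(x, path, pixel_size = 1) {
  if (is.matrix(x)) x <- list(x)
  if (!length(x) || !all(vapply(x, is.matrix, logical(1))))
    stop("'x' must be a matrix or a non-empty list of matrices")
  dims <- vapply(x, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all stack sections must share one shape")
  nr <- dims[1, 1]; nc <- dims[2, 1]; nz <- length(x)
  all_px <- unlist(lapply(x, function(m) as.numeric(t(m))), use.names = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wi(c(nc, nr, nz))                        # NX NY NZ (X = columns)
  wi(2L)                                   # MODE 2: float32
  wi(c(0L, 0L, 0L))                        # N*START
  wi(c(nc, nr, nz))                        # MX MY MZ
  wf(pixel_size * c(nc, nr, nz))           # CELLA
  wf(c(90, 90, 90))                        # CELLB
  wi(c(1L, 2L, 3L))                        # MAPC MAPR MAPS
  wf(c(min(all_px), max(all_px), mean(all_px)))  # DMIN DMAX DMEAN
  wi(c(0L, 0L))                            # ISPG, NSYMBT
  wi(rep(0L, 3))                           # EXTRA words 25-27
  wi(20140L)                               # NVERSION
  wi(rep(0L, 21))                          # EXTRA words 29-49
  wf(c(0, 0, 0))                           # ORIGIN
  writeBin(charToRaw("MAP "), con)         # map id
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little endian
  wf(stats::sd(all_px))                    # RMS
  wi(1L)                                   # NLABL
  lab <- sprintf("%-80s", "cryopick")
  writeBin(charToRaw(lab), con)
  writeBin(raw(80L * 9L), con)
  wf(all_px)
  invisible(path)
}

#' Read an MRC2014 image or image stack
#'
#' @param path Path to an MRC file (modes 0, 1, 2 and 6 supported).
#' @return For a single section, a numeric matrix with attribute
#'   `pixel_size`; for a stack, a list of matrices with the same attribute.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", n = k, size = 4L, endian = "little")
  rf <- function(k) readBin(con, "numeric", n = k, size = 4L, endian = "little")
  nxyz <- ri(3)                            # NX NY NZ
  mode <- ri(1)
  if (length(nxyz) < 3L || length(mode) < 1L || anyNA(nxyz) ||
      any(nxyz < 1) || any(nxyz > 1e6) || prod(nxyz) > 5e8)
    stop("corrupt or unsupported MRC header in ", path)
  ri(3); mxyz <- ri(3)
  cella <- rf(3); rf(3); ri(3); rf(3); ri(2)
  seek(con, 1024)
  nc <- nxyz[1]; nr <- nxyz[2]; nz <- nxyz[3]
  npx <- as.numeric(nc) * nr * nz
  px <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", npx, size = 1L, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", npx, size = 2L, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", npx, size = 4L, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", npx, size = 2L, signed = FALSE,
                             endian = "little")),
    stop("unsupported MRC mode: ", mode))
  if (length(px) != npx) stop("truncated MRC data in ", path)
  apix <- if (mxyz[1] > 0) cella[1] / mxyz[1] else 1
  secs <- lapply(seq_len(nz), function(z) {
    off <- (z - 1L) * nc * nr
    t(matrix(px[off + seq_len(nc * nr)], nc, nr))  # stored X-fastest
  })
  out <- if (nz == 1L) secs[[1L]] else secs
  attr(out, "pixel_size") <- apix
  out
}

#' Read a grayscale image from MRC, TIFF, PNG or plain text
#'
#' Convenience ingestion for toy fixtures: dispatches on file extension.
#' TIFF/PNG images are collapsed to grayscale by channel averaging; `.tsv` /
#' `.txt` files are read as whitespace-separated numeric matrices.
#'
#' @param path Input image path.
#' @return A numeric matrix (rows x cols).
#' @export
read_image_any <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mrc", "mrcs", "map")) {
    img <- read_mrc(path)
    if (is.list(img)) stop("expected a single 2-D image, got a stack: ", path)
    return(img)
  }
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' required to read ", path)
    a <- tiff::readTIFF(path)
    return(if (length(dim(a)) == 3L) apply(a, c(1, 2), mean) else a)
  }
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("package 'png' required to read ", path)
    a <- png::readPNG(path)
    return(if (length(dim(a)) == 3L) apply(a, c(1, 2), mean) else a)
  }
  if (ext %in% c("tsv", "txt", "dat"))
    return(as.matrix(utils::read.table(path)))
  stop("unrecognized image format: ", path)
}
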