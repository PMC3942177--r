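#' Construct a micrograph object
#'
#' A micrograph is a 2-D grayscale intensity image (rows x cols) with
#' optional physical pixel size and a source identifier.
#'
#' @param pixels Numeric matrix of intensities; all values must be finite.
#' @param pixel_size Optional physical size per pixel (Angstrom/pixel).
#' @param source_id Identifier string, e.g. the originating file name.
#' @return An object of class `micrograph`.
#' @export
micrograph <- function(pixels, pixel_size = NULL, source_id = "micrograph") {
  if (!is.matrix(pixels) || !is.numeric(pixels) ||
      nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("'pixels' must be a non-empty numeric matrix")
  if (!all(is.finite(pixels)))
    stop("micrograph pixels must all be finite")
  structure(
    list(pixels = pixels, pixel_size = pixel_size,
         source_id = as.character(source_id)),
    class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %s: %d x %d px", x$source_id,
              nrow(x$pixels), ncol(x$pixels)))
  if (!is.null(x$pixel_size)) cat(sprintf(" @ %.3g A/px", x$pixel_size))
  cat(sprintf("  [%.3g, %.3g]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a micrograph from file
#'
#' @param path MRC (preferred), TIFF, PNG or plain-text image file.
#' @param source_id Identifier; defaults to the file name.
#' @return A [micrograph] object.
#' @export
read_micrograph <- function(path, source_id = basename(path)) {
  px <- read_image_any(path)
  micrograph(px, pixel_size = attr(px, "pixel_size"), source_id = source_id)
}

#' Box-average (mean) filter
#'
#' Smooths an image with a k x k averaging kernel, the standard pre-treatment
#' that suppresses pixel-level shot noise before correlation. Boundaries are
#' handled by reflect-padding (edge row/column mirrored including the edge
#' itself), so the output shape equals the input shape. For even `k` the
#' window anchor is `floor((k-1)/2)`, i.e. the window extends one pixel
#' further down/right than up/left.
#'
#' @param image Numeric matrix (or a [micrograph], filtered in place).
#' @param k Window size in pixels (k x k); must not exceed either image
#'   dimension.
#' @return Filtered image, same class and shape as the input.
#' @examples
#' m <- matrix(rnorm(64), 8, 8)
#' all.equal(dim(mean_filter(m, 4)), dim(m))
#' @export
mean_filter <- function(image, k) {
  if (inherits(image, "micrograph")) {
    image$pixels <- mean_filter(image$pixels, k)
    return(image)
  }
  if (!is.matrix(image) || !length(image)) stop("'image' must be a non-empty matrix")
  if (length(k) != 1L || k < 1 || k != round(k)) stop("'k' must be a positive integer")
  k <- as.integer(k)
  if (k > nrow(image) || k > ncol(image))
    stop("filter window larger than the image")
  if (k == 1L) return(image)
  a <- (k - 1L) %/% 2L           # pixels above/left of the anchor
  b <- k - 1L - a                # pixels below/right
  padded <- reflect_pad(image, a, b)
  ## summed-area table; window sum via 4-corner differences
  sat <- apply(apply(padded, 2, cumsum), 1, cumsum)  # transposed cumsum
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  nr <- nrow(image); nc <- ncol(image)
  i1 <- seq_len(nr); i2 <- i1 + k; j1 <- seq_len(nc); j2 <- j1 + k
  (sat[i2, j2] - sat[i1, j2] - sat[i2, j1] + sat[i1, j1]) / (k * k)
}

## reflect-pad a matrix by `a` rows/cols before and `b` after (edge included)
reflect_pad <- function(m, a, b) {
  ridx <- c(rev(seq_len(a)), seq_len(nrow(m)), nrow(m) + 1L - seq_len(b))
  cidx <- c(rev(seq_len(a)), seq_len(ncol(m)), ncol(m) + 1L - seq_len(b))
  m[ridx, cidx, drop = FALSE]
}
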