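## Instrumented FFT dispatch.
##
## All discrete Fourier transforms in the package go through fft_fwd() /
## fft_inv() so that a global counter can audit exactly how many transforms a
## correlation run schedules. The counter is the basis of the FFT accounting
## contract: building the micrograph-side spectra costs 2 forward transforms,
## and every template costs 2 forward + 3 inverse transforms.

.fft_state <- new.env(parent = emptyenv())
.fft_state$count <- 0L

#' Reset the global FFT execution counter
#'
#' @return The previous counter value, invisibly.
#' @seealso [fft_count()], [fft_op_count()]
#' @export
fft_count_reset <- function() {
  old <- .fft_state$count
  .fft_state$count <- 0L
  invisible(old)
}

#' Read the global FFT execution counter
#'
#' Counts every forward and inverse transform executed since the last
#' [fft_count_reset()].
#'
#' @return Integer number of transforms executed.
#' @export
fft_count <- function() .fft_state$count

## forward 2-D DFT (unnormalized, as stats::fft)
fft_fwd <- function(x) {
  .fft_state$count <- .fft_state$count + 1L
  stats::fft(x)
}

## inverse 2-D DFT, normalized, real part returned
fft_inv <- function(x) {
  .fft_state$count <- .fft_state$count + 1L
  Re(stats::fft(x, inverse = TRUE)) / length(x)
}

## zero-pad a matrix into the top-left corner of a `dim`-shaped matrix
pad_to <- function(x, dim) {
  if (nrow(x) > dim[1] || ncol(x) > dim[2])
    stop("array larger than requested padded shape")
  out <- matrix(0, dim[1], dim[2])
  out[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  out
}
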