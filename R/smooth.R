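#' Next 7-smooth FFT length
#'
#' FFT libraries decompose a transform of length \eqn{N} recursively into
#' small kernels of size 2, 3, 5 and 7; lengths with larger prime factors
#' fall back to much slower generic algorithms. It therefore pays to zero-pad
#' images up to the next integer whose prime factors are all \eqn{\le 7}
#' (a "7-smooth" number) before transforming.
#'
#' @param n Positive integer (scalar), the minimum required length.
#' @return The smallest integer `m >= n` such that `m` factors entirely into
#'   the primes 2, 3, 5 and 7.
#' @examples
#' smooth_size(4096)  # 4096 = 2^12, already smooth
#' smooth_size(4097)  # 4116 = 2^2 * 3 * 7^3
#' smooth_size(97)    # 98 = 2 * 7^2
#' @export
smooth_size <- function(n) {
  if (length(n) != 1L || !is.numeric(n) || !is.finite(n) || n < 1)
    stop("'n' must be a single positive integer")
  m <- ceiling(n)
  while (!is_7smooth(m)) m <- m + 1
  as.integer(m)
}

## TRUE iff m factors into primes {2,3,5,7}
is_7smooth <- function(m) {
  for (p in c(2, 3, 5, 7)) while (m %% p == 0) m <- m / p
  m == 1
}
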