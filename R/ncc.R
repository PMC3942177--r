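## Masked, locally normalized cross-correlation via FFTs.
##
## For a template T with binary mask M (P = sum(M) pixels) slid over a
## micrograph I, the score at offset v is the Pearson correlation computed
## over mask pixels only:
##
##   num(v)  = sum_M I(x+v) T(x)  -  (1/P) (sum_M I(x+v)) (sum_M T)
##   den(v)  = sqrt(sum_M I(x+v)^2 - (sum_M I(x+v))^2 / P)
##           * sqrt(sum_M T^2     - (sum_M T)^2     / P)
##
## All three image-dependent sums are cross-correlations of I (or I^2)
## against M or M*T, so the whole map costs 2 shared forward transforms of
## the micrograph side (I and I^2, reused for every template), plus per
## template 2 forward transforms (M*T and M) and 3 inverse transforms.

#' Precompute shared micrograph spectra
#'
#' Transforms the zero-padded micrograph and its square once; the two
#' spectra are then reused by [masked_ncc()] for every template of the same
#' shape, so the image-side FFT cost is paid once per micrograph.
#'
#' @param m A [micrograph] (or plain numeric matrix).
#' @param template_shape Integer vector `c(rows, cols)` of the templates the
#'   spectra will serve; must fit inside the micrograph.
#' @param padded_shape Optional FFT shape override; each dimension must be
#'   7-smooth and at least `image + template - 1`. The default is the
#'   smallest such shape; any larger smooth shape gives identical
#'   correlation results (linear, zero-padded correlation is insensitive to
#'   extra padding).
#' @return An object of class `shared_spectra` with the padded shape
#'   (each dimension a 7-smooth integer, see [smooth_size()]), the two
#'   spectra, the valid-offset shape, the micrograph's global intensity
#'   variance (used by the low-variance guard) and `fft_count = 2`.
#' @export
micrograph_spectra <- function(m, template_shape, padded_shape = NULL) {
  px <- if (inherits(m, "micrograph")) m$pixels else m
  if (!is.matrix(px)) stop("'m' must be a micrograph or matrix")
  template_shape <- as.integer(template_shape)
  if (length(template_shape) != 2L || any(template_shape < 1L))
    stop("'template_shape' must be two positive integers")
  if (any(template_shape > dim(px)))
    stop("template larger than micrograph")
  minimal <- c(smooth_size(nrow(px) + template_shape[1] - 1L),
               smooth_size(ncol(px) + template_shape[2] - 1L))
  padded <- if (is.null(padded_shape)) minimal else as.integer(padded_shape)
  if (any(padded < minimal) ||
      !all(vapply(padded, function(d) smooth_size(d) == d, logical(1))))
    stop("'padded_shape' must be 7-smooth and cover image + template - 1")
  structure(
    list(padded_shape = padded,
         img_shape = dim(px),
         template_shape = template_shape,
         spectrum_I = fft_fwd(pad_to(px, padded)),
         spectrum_I2 = fft_fwd(pad_to(px^2, padded)),
         global_var = stats::var(as.vector(px)),
         fft_count = 2L),
    class = "shared_spectra")
}

#' Masked normalized cross-correlation map for one template
#'
#' Correlates one template/mask pair against the micrograph whose spectra
#' were prepared by [micrograph_spectra()]. Correlation is linear (zero
#' padded), so only offsets where the template lies fully inside the
#' micrograph are returned; the offset `v = (0, 0)` puts the template's
#' top-left corner at the micrograph's top-left corner.
#'
#' Windows that are essentially flat under the mask (window variance no more
#' than `1e-12` times the micrograph's global variance) get score 0 rather
#' than an unstable ratio.
#'
#' @param spectra A `shared_spectra` object.
#' @param t A [template_with_mask] whose shape matches
#'   `spectra$template_shape`.
#' @return An object of class `ncc_map`: `scores` (matrix over valid
#'   offsets, values in `[-1, 1]` up to roundoff), `k`, and `valid_shape`.
#' @export
masked_ncc <- function(spectra, t) {
  stopifnot(inherits(spectra, "shared_spectra"),
            inherits(t, "template_with_mask"))
  if (!all(dim(t$image) == spectra$template_shape))
    stop("template shape does not match the shared spectra")
  padded <- spectra$padded_shape
  vr <- spectra$img_shape[1] - nrow(t$image) + 1L
  vc <- spectra$img_shape[2] - ncol(t$image) + 1L
  F_tm <- fft_fwd(pad_to(t$image * t$mask, padded))
  F_m  <- fft_fwd(pad_to(t$mask, padded))
  iv <- seq_len(vr); jv <- seq_len(vc)
  cross <- fft_inv(spectra$spectrum_I  * Conj(F_tm))[iv, jv, drop = FALSE]
  sum_i <- fft_inv(spectra$spectrum_I  * Conj(F_m))[iv, jv, drop = FALSE]
  sum_i2 <- fft_inv(spectra$spectrum_I2 * Conj(F_m))[iv, jv, drop = FALSE]
  P <- t$mask_area
  num <- cross - sum_i * t$template_mean_in_mask
  win_ss <- sum_i2 - sum_i^2 / P          # P * window variance under mask
  den_t <- sqrt(P * t$template_var_in_mask)
  scores <- num / (sqrt(pmax(win_ss, 0)) * den_t)
  low <- win_ss <= 1e-12 * P * spectra$global_var | !is.finite(scores)
  scores[low] <- 0
  structure(list(scores = scores, k = t$k, valid_shape = c(vr, vc)),
            class = "ncc_map")
}

#' @export
print.ncc_map <- function(x, ...) {
  cat(sprintf("<ncc_map> template k=%d, %d x %d offsets, range [%.4f, %.4f]\n",
              x$k, nrow(x$scores), ncol(x$scores),
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' FFT schedule and total operation count for a picking run
#'
#' `fft_schedule()` lists every transform the engine dispatches when
#' correlating `n_templates` templates against one micrograph under the
#' shared-spectrum scheme: 2 image-side forward transforms (I and I^2), then
#' per template 2 forward (masked template, mask) and 3 inverse (cross term,
#' windowed sum, windowed sum of squares). `fft_op_count()` is its length,
#' and equals the counter observed when actually executing the run (see
#' [fft_count()]).
#'
#' @param n_templates Number of templates (non-negative integer).
#' @return For `fft_schedule()`, a data.frame with columns `op` and
#'   `template` (NA for shared image-side transforms); for
#'   `fft_op_count()`, the integer number of forward + inverse transforms
#'   (0 when no templates are scheduled).
#' @examples
#' fft_op_count(1)      # 7
#' fft_op_count(14630)  # 73152
#' @export
fft_op_count <- function(n_templates) {
  nrow(fft_schedule(n_templates))
}

#' @rdname fft_op_count
#' @export
fft_schedule <- function(n_templates) {
  if (length(n_templates) != 1L || !is.finite(n_templates) ||
      n_templates < 0 || n_templates != round(n_templates))
    stop("'n_templates' must be a single non-negative integer")
  K <- as.integer(n_templates)
  if (K == 0L)
    return(data.frame(op = character(0), template = integer(0)))
  per_template <- c("fwd_masked_template", "fwd_mask",
                    "inv_cross", "inv_window_sum", "inv_window_sumsq")
  data.frame(
    op = c("fwd_image", "fwd_image_sq", rep(per_template, K)),
    template = c(NA_integer_, NA_integer_, rep(seq_len(K) - 1L, each = 5L)))
}
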