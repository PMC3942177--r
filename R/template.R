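#' Construct a base projection
#'
#' A base projection is one reference 2-D view of the particle (for KLH-like
#' particles: the rectangular side view or the circular top view) together
#' with its binary mask, from which a rotation series of templates is built.
#'
#' @param image Square numeric matrix, the projection intensities.
#' @param mask Binary matrix (exactly 0/1), same shape as `image`, marking
#'   pixels that participate in correlation.
#' @param base_id Identifier string.
#' @param symmetry_order In-plane rotational symmetry order of the view
#'   (integer >= 1), or the string `"circular"` for full rotational symmetry
#'   (e.g. a top view down a symmetry axis).
#' @return An object of class `base_projection`.
#' @export
base_projection <- function(image, mask, base_id,
                            symmetry_order = 1L) {
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop("base projection image must be a square matrix")
  if (!identical(dim(image), dim(mask)))
    stop("image and mask shapes differ")
  if (!all(mask %in% c(0, 1))) stop("mask values must be exactly 0 or 1")
  circular <- identical(symmetry_order, "circular")
  if (!circular &&
      (length(symmetry_order) != 1L || symmetry_order < 1 ||
       symmetry_order != round(symmetry_order)))
    stop("'symmetry_order' must be an integer >= 1 or \"circular\"")
  structure(
    list(image = image, mask = mask, base_id = as.character(base_id),
         symmetry_order = if (circular) "circular" else as.integer(symmetry_order)),
    class = "base_projection")
}

#' Construct a template with its mask
#'
#' Bundles one search image with its binary mask and the mask statistics
#' needed by the masked-correlation normalization: the mask pixel count P,
#' and the template mean and (population) variance over mask pixels.
#'
#' @param image Numeric matrix, the search image.
#' @param mask Binary matrix (exactly 0/1), same shape.
#' @param k Integer template index (>= 0) within its template set.
#' @param base_id,angle_deg Provenance: base view and rotation angle.
#' @return An object of class `template_with_mask`. Construction fails for a
#'   flat template (zero intensity variance under the mask) or a mask with
#'   fewer than 2 pixels, since neither can be normalized.
#' @export
template_with_mask <- function(image, mask, k = 0L, base_id = "base",
                               angle_deg = 0) {
  if (!identical(dim(image), dim(mask)))
    stop("template image and mask shapes differ")
  if (!all(mask %in% c(0, 1))) stop("mask values must be exactly 0 or 1")
  P <- sum(mask)
  if (P < 2) stop("mask must contain at least 2 pixels")
  mu <- sum(image * mask) / P
  v <- sum(image^2 * mask) / P - mu^2
  if (v <= 0) stop("flat template: zero variance under the mask")
  structure(
    list(image = image, mask = mask, k = as.integer(k),
         base_id = as.character(base_id), angle_deg = angle_deg,
         mask_area = as.integer(P),
         template_mean_in_mask = mu, template_var_in_mask = v),
    class = "template_with_mask")
}

#' Rotate a square image about its center
#'
#' Inverse-mapping rotation about the geometric center `(n+1)/2` of an
#' `n x n` frame. Intensity images use bilinear interpolation; masks are
#' interpolated the same way and then re-binarized at 0.5 so they stay
#' strictly 0/1. Sample points falling outside the original frame are filled
#' with 0. Angles that are exact multiples of 90 degrees reduce to exact
#' index permutations (no interpolation error), because `cospi`/`sinpi`
#' return exact 0 and 1 there.
#'
#' @param image Square numeric matrix.
#' @param angle_deg Rotation angle in degrees (counter-clockwise in
#'   (row, col) index space).
#' @param is_mask If TRUE, re-binarize the interpolated values at 0.5.
#' @return Rotated matrix, same shape.
#' @export
rotate_image <- function(image, angle_deg, is_mask = FALSE) {
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop("rotation requires a square image")
  if (angle_deg %% 360 == 0) return(image)
  n <- nrow(image)
  ctr <- (n + 1) / 2
  cth <- cospi(angle_deg / 180)
  sth <- sinpi(angle_deg / 180)
  d <- seq_len(n) - ctr
  ## source coordinates for every output pixel (inverse rotation)
  sr <- ctr + outer(d * cth, d * sth, "+")       # n x n source rows
  sc <- ctr + outer(-d * sth, d * cth, "+")      # n x n source cols
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  at <- function(R, C) {
    ok <- R >= 1 & R <= n & C >= 1 & C <= n
    v <- numeric(length(R))
    v[ok] <- image[cbind(R[ok], C[ok])]
    v
  }
  out <- (1 - fr) * (1 - fc) * at(r0, c0) +
         (1 - fr) * fc       * at(r0, c0 + 1) +
         fr       * (1 - fc) * at(r0 + 1, c0) +
         fr       * fc       * at(r0 + 1, c0 + 1)
  out <- matrix(out, n, n)
  if (is_mask) out <- (out >= 0.5) * 1
  out
}

#' Build the rotation series of templates and masks
#'
#' Rotates each base projection (and its mask) through its unique angular
#' range in steps of `step_deg`, yielding the template set searched against
#' every micrograph. Without symmetry each base contributes `360/step_deg`
#' templates. With `exploit_symmetry`, a base of symmetry order `s` only
#' needs angles in `[0, 360/s)`, and a `"circular"` base contributes a
#' single template: rotating it changes nothing.
#'
#' @param bases Non-empty list of [base_projection] objects (all one shape).
#' @param step_deg Angular step in degrees; must divide 360 evenly.
#' @param exploit_symmetry Use each base's symmetry to shrink its range.
#' @return An object of class `template_set`: list with `templates` (list of
#'   [template_with_mask], indices `k = 0..N-1` in (base, angle) order),
#'   `step_deg`, and `provenance` (data.frame of k, base_id, angle_deg).
#' @examples
#' b <- synthetic_bases(48)
#' length(build_rotation_series(b, 4)$templates)                      # 180
#' length(build_rotation_series(b, 4, exploit_symmetry = TRUE)$templates) # 46
#' @export
build_rotation_series <- function(bases, step_deg = 4,
                                  exploit_symmetry = FALSE) {
  if (!length(bases)) stop("'bases' must be a non-empty list")
  if (!all(vapply(bases, inherits, logical(1), "base_projection")))
    stop("'bases' must contain base_projection objects")
  if (step_deg <= 0 || 360 %% step_deg != 0) {
    near <- divisors_of_360()
    stop(sprintf(
      "step_deg = %g does not divide 360 evenly; nearest valid steps: %g and %g",
      step_deg, max(near[near <= step_deg], 1),
      min(near[near >= step_deg], 360)))
  }
  shapes <- vapply(bases, function(b) dim(b$image), integer(2))
  if (any(shapes != shapes[, 1])) stop("all bases must share one shape")
  templates <- list()
  prov <- list()
  k <- 0L
  for (b in bases) {
    rng <- if (!exploit_symmetry) 360
           else if (identical(b$symmetry_order, "circular")) step_deg
           else 360 / b$symmetry_order
    angles <- seq(0, rng - step_deg, by = step_deg)
    for (a in angles) {
      img <- rotate_image(b$image, a)
      msk <- rotate_image(b$mask, a, is_mask = TRUE)
      templates[[k + 1L]] <- template_with_mask(img, msk, k = k,
                                                base_id = b$base_id,
                                                angle_deg = a)
      prov[[k + 1L]] <- data.frame(k = k, base_id = b$base_id, angle_deg = a)
      k <- k + 1L
    }
  }
  structure(
    list(templates = templates, step_deg = step_deg,
         provenance = do.call(rbind, prov)),
    class = "template_set")
}

divisors_of_360 <- function() {
  d <- 1:360
  d[360 %% d == 0]
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> %d templates, step %g deg, bases: %s\n",
              length(x$templates), x$step_deg,
              paste(unique(x$provenance$base_id), collapse = ", ")))
  invisible(x)
}

#' Write a template set as MRC stacks plus a provenance TSV
#'
#' Writes `<prefix>_templates.mrcs` and `<prefix>_masks.mrcs` (MRC stacks,
#' one section per template in index order) and `<prefix>_provenance.tsv`
#' with columns k, base_id, angle_deg.
#'
#' @param tset A `template_set`.
#' @param prefix Output path prefix.
#' @return Character vector of the three paths written, invisibly.
#' @export
write_template_set <- function(tset, prefix) {
  stopifnot(inherits(tset, "template_set"))
  p1 <- paste0(prefix, "_templates.mrcs")
  p2 <- paste0(prefix, "_masks.mrcs")
  p3 <- paste0(prefix, "_provenance.tsv")
  write_mrc(lapply(tset$templates, `[[`, "image"), p1)
  write_mrc(lapply(tset$templates, `[[`, "mask"), p2)
  utils::write.table(tset$provenance, p3, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(p1, p2, p3))
}

#' Read a template set written by [write_template_set()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `template_set` object.
#' @export
read_template_set <- function(prefix) {
  imgs <- read_mrc(paste0(prefix, "_templates.mrcs"))
  msks <- read_mrc(paste0(prefix, "_masks.mrcs"))
  prov <- utils::read.table(paste0(prefix, "_provenance.tsv"),
                            sep = "\t", header = TRUE)
  if (is.matrix(imgs)) { imgs <- list(imgs); msks <- list(msks) }
  templates <- lapply(seq_along(imgs), function(i)
    template_with_mask(imgs[[i]], round(msks[[i]]), k = prov$k[i],
                       base_id = prov$base_id[i], angle_deg = prov$angle_deg[i]))
  steps <- diff(sort(unique(prov$angle_deg)))
  structure(
    list(templates = templates,
         step_deg = if (length(steps)) min(steps) else 360,
         provenance = prov),
    class = "template_set")
}
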