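## Synthetic KLH-like fixtures.
##
## Keyhole limpet hemocyanin (KLH) is the classic particle-picking benchmark:
## a barrel-shaped oligomer that projects as a rectangular side view (with
## internal band texture from the stacked subunit rings) or a circular top
## view (with ring texture). The generator fabricates both base projections
## with matching binary masks, plants rotated copies at known positions in
## Gaussian noise, and emits an exact ground-truth table, so the whole
## picking pipeline can be exercised and scored with no external data.

#' Fabricate side-view and top-view base projections
#'
#' The side view is a centered `h x w` rectangle with transverse band
#' texture and a rectangular mask (area exactly `h * w`); it is built
#' 2-fold symmetric, matching the in-plane symmetry of a barrel side view.
#' The top view is a centered disk of radius `r` with purely radial ring
#' texture and a disk mask, and is marked `"circular"` (fully rotationally
#' symmetric). Intensities taper smoothly to 0 at the mask boundary and are
#' 0 outside the mask; each view is scaled to unit variance under its mask,
#' so a planted amplitude `a` over noise of s.d. `sigma` gives peak
#' signal-to-noise ratio `a^2 / sigma^2`.
#'
#' @param side_dims Integer `c(h, w)` of the rectangular side view; for an
#'   exactly symmetric placement `canvas - h` and `canvas - w` must be even.
#' @param top_radius Disk radius of the top view in pixels.
#' @param canvas Square frame size `n`; both views must fit.
#' @return List of two [base_projection] objects (`side`, `top`).
#' @export
make_base_projections <- function(side_dims = c(38, 16), top_radius = 16,
                                  canvas = 48) {
  n <- as.integer(canvas)
  h <- as.integer(side_dims[1]); w <- as.integer(side_dims[2])
  if (h > n || w > n || 2 * top_radius + 1 > n)
    stop("view dimensions exceed the canvas")
  ctr <- (n + 1) / 2
  ## side view: rectangle with bands across the long axis
  r0 <- (n - h) %/% 2L
  c0 <- (n - w) %/% 2L
  mask_s <- matrix(0, n, n)
  mask_s[r0 + seq_len(h), c0 + seq_len(w)] <- 1
  dr <- matrix(seq_len(n) - ctr, n, n)
  dc <- matrix(seq_len(n) - ctr, n, n, byrow = TRUE)
  edge_r <- pmax(h / 2 - abs(dr), 0)
  edge_c <- pmax(w / 2 - abs(dc), 0)
  taper <- pmin(edge_r / 3, 1) * pmin(edge_c / 3, 1)
  img_s <- mask_s * taper * (0.6 + 0.4 * cos(2 * pi * dr / 6.5))
  img_s <- normalize_under_mask(img_s, mask_s)
  side <- base_projection(img_s, mask_s, "side", symmetry_order = 2L)
  ## top view: disk with radial rings
  rho <- sqrt(dr^2 + dc^2)
  mask_t <- (rho <= top_radius) * 1
  taper_t <- pmin(pmax(top_radius - rho, 0) / 3, 1)
  img_t <- mask_t * taper_t * (0.6 + 0.4 * cos(2 * pi * rho / 6.5))
  img_t <- normalize_under_mask(img_t, mask_t)
  top <- base_projection(img_t, mask_t, "top", symmetry_order = "circular")
  list(side = side, top = top)
}

## scale so the population variance under the mask is 1
normalize_under_mask <- function(img, mask) {
  P <- sum(mask)
  mu <- sum(img * mask) / P
  v <- sum(img^2 * mask) / P - mu^2
  img / sqrt(v)
}

#' Default synthetic bases
#'
#' Convenience wrapper around [make_base_projections()] with KLH-like
#' proportions scaled to the frame: side view `0.8n x 0.4n`, top radius
#' `n/3`. The default frame of 160 px gives mask areas of order 10^4
#' pixels, the scale at which a 4 x 4 prefilter and a correlation threshold
#' of 0.3 sit well clear of the correlation noise floor (which grows as
#' `4 / sqrt(mask area)` on 4 x 4 filtered data).
#'
#' @param canvas Frame size (even integer).
#' @return List of two [base_projection]s.
#' @export
synthetic_bases <- function(canvas = 160) {
  n <- as.integer(canvas)
  h <- 2L * as.integer(0.4 * n); w <- 2L * as.integer(n / 5)
  make_base_projections(c(h, w), top_radius = n %/% 3, canvas = n)
}

#' Specify a planting scenario
#'
#' @param n_particles Number of particles to plant.
#' @param base_mix Fraction of side views (the rest are top views).
#' @param angle_sampling `"grid"` (multiples of `angle_step`) or
#'   `"uniform"` (continuous over `[0, 360)`).
#' @param angle_step Grid step in degrees when `angle_sampling = "grid"`.
#' @param amplitude Particle intensity scale; negative values emulate the
#'   usual cryo-EM contrast (particles darker than background), which makes
#'   correlation peaks negative and calls for `polarity = "min"` picking.
#' @param noise_sigma Standard deviation of the additive white Gaussian
#'   background noise. With unit-variance bases the peak signal-to-noise
#'   ratio is `amplitude^2 / noise_sigma^2` (the default 1/0.2^2 = 25).
#' @param min_separation Minimum pairwise center distance in pixels;
#'   default: 0.9 x the base frame size (enough that no two particle masks
#'   overlap), set at planting time.
#' @param seed RNG seed; fixed seed gives bit-reproducible output.
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(n_particles = 6, base_mix = 0.5,
                       angle_sampling = c("grid", "uniform"),
                       angle_step = 4, amplitude = -1, noise_sigma = 0.2,
                       min_separation = NULL, seed = 1) {
  angle_sampling <- match.arg(angle_sampling)
  if (n_particles < 0) stop("'n_particles' must be >= 0")
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  structure(list(n_particles = as.integer(n_particles), base_mix = base_mix,
                 angle_sampling = angle_sampling, angle_step = angle_step,
                 amplitude = amplitude, noise_sigma = noise_sigma,
                 min_separation = min_separation, seed = as.integer(seed)),
            class = "plant_spec")
}

#' Plant particles into a synthetic micrograph
#'
#' Builds `background 0 + sum_i amplitude * rotate(base_i, theta_i)` at
#' rejection-sampled centers at least `min_separation` apart, then adds
#' `N(0, noise_sigma^2)` noise. A fixed seed makes the output
#' bit-reproducible.
#'
#' @param canvas_shape Micrograph shape `c(rows, cols)`.
#' @param bases List of [base_projection]s (as from
#'   [make_base_projections()]); sampled with probability `base_mix` for the
#'   first base.
#' @param spec A [plant_spec].
#' @param source_id Micrograph identifier.
#' @return List with `micrograph` (a [micrograph]) and `truth` (data.frame
#'   of `center_row`, `center_col` (0-based), `base_id`, `angle_deg`,
#'   `amplitude`), one row per planted particle.
#' @export
plant_particles <- function(canvas_shape, bases, spec = plant_spec(),
                            source_id = "synthetic") {
  stopifnot(inherits(spec, "plant_spec"))
  nr <- as.integer(canvas_shape[1]); nc <- as.integer(canvas_shape[2])
  tdim <- nrow(bases[[1]]$image)
  min_sep <- if (is.null(spec$min_separation)) ceiling(0.9 * tdim)
             else spec$min_separation
  margin <- tdim %/% 2L        # keep the full footprint inside the frame
  if (nr - tdim < 0 || nc - tdim < 0)
    stop("canvas too small for the base projections")
  set.seed(spec$seed)
  ## rejection-sample centers (0-based)
  centers <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  max_attempts <- 1000L * max(spec$n_particles, 1L)
  lo_r <- margin; hi_r <- nr - 1L - (tdim - 1L - margin)
  lo_c <- margin; hi_c <- nc - 1L - (tdim - 1L - margin)
  while (nrow(centers) < spec$n_particles) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(
        "could not place %d particles with min_separation = %g in a %d x %d frame",
        spec$n_particles, min_sep, nr, nc))
    cand <- c(sample(lo_r:hi_r, 1L), sample(lo_c:hi_c, 1L))
    if (nrow(centers)) {
      dd <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)
      if (any(dd < min_sep)) next
    }
    centers <- rbind(centers, cand)
  }
  np <- spec$n_particles
  which_base <- if (np) ifelse(stats::runif(np) < spec$base_mix, 1L, 2L) else integer(0)
  if (length(bases) == 1L) which_base[] <- 1L
  angles <- if (!np) numeric(0)
            else if (spec$angle_sampling == "grid")
              spec$angle_step * sample(0:(360 / spec$angle_step - 1L), np,
                                       replace = TRUE)
            else stats::runif(np, 0, 360)
  px <- matrix(0, nr, nc)
  for (i in seq_len(np)) {
    b <- bases[[which_base[i]]]
    rot <- rotate_image(b$image, angles[i])
    r0 <- centers[i, 1] - tdim %/% 2L   # 0-based top-left
    c0 <- centers[i, 2] - tdim %/% 2L
    rows <- (r0 + 1):(r0 + tdim); cols <- (c0 + 1):(c0 + tdim)
    px[rows, cols] <- px[rows, cols] + spec$amplitude * rot
  }
  if (spec$noise_sigma > 0)
    px <- px + matrix(stats::rnorm(nr * nc, 0, spec$noise_sigma), nr, nc)
  truth <- data.frame(
    center_row = as.integer(centers[, 1]),
    center_col = as.integer(centers[, 2]),
    base_id = vapply(which_base, function(i) bases[[i]]$base_id, character(1)),
    angle_deg = angles,
    amplitude = rep(spec$amplitude, np))
  list(micrograph = micrograph(px, source_id = source_id), truth = truth)
}

#' Generate a synthetic picking dataset on disk
#'
#' Writes `n_micrographs` MRC micrographs with one ground-truth TSV each,
#' the base projection/mask stacks, and a JSON manifest recording the spec,
#' per-micrograph seeds and file checksums. Micrograph `i` uses seed
#' `spec$seed + i - 1`; re-running with the same spec reproduces identical
#' files.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_micrographs Number of micrographs.
#' @param spec A [plant_spec].
#' @param canvas_shape Micrograph shape, default 768 x 768.
#' @param bases Base projections; default [synthetic_bases()].
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
generate_dataset <- function(out_dir, n_micrographs, spec = plant_spec(),
                             canvas_shape = c(768, 768),
                             bases = synthetic_bases()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  write_mrc(lapply(bases, `[[`, "image"), file.path(out_dir, "bases.mrcs"))
  write_mrc(lapply(bases, `[[`, "mask"), file.path(out_dir, "base_masks.mrcs"))
  entries <- vector("list", n_micrographs)
  for (i in seq_len(n_micrographs)) {
    spec_i <- spec
    spec_i$seed <- spec$seed + i - 1L
    id <- sprintf("mic_%03d", i)
    res <- plant_particles(canvas_shape, bases, spec_i, source_id = id)
    mrc_path <- file.path(out_dir, paste0(id, ".mrc"))
    tsv_path <- file.path(out_dir, paste0(id, "_truth.tsv"))
    write_mrc(res$micrograph$pixels, mrc_path)
    utils::write.table(res$truth, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    entries[[i]] <- list(
      id = id, seed = spec_i$seed,
      micrograph = basename(mrc_path), truth = basename(tsv_path),
      n_particles = nrow(res$truth),
      md5_micrograph = unname(tools::md5sum(mrc_path)),
      md5_truth = unname(tools::md5sum(tsv_path)))
  }
  manifest <- list(
    spec = unclass(spec),
    canvas_shape = canvas_shape,
    base_ids = vapply(bases, `[[`, character(1), "base_id"),
    micrographs = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
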