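test_that("base projections have exact masks and masked intensities", {
  b <- make_base_projections(c(38, 16), top_radius = 16, canvas = 48)
  expect_equal(sum(b$side$mask), 38 * 16)          # rectangle area exact
  disk_area <- sum(b$top$mask)
  expect_lt(abs(disk_area - pi * 16^2) / (pi * 16^2), 0.03)
  expect_true(all(b$side$image[b$side$mask == 0] == 0))
  expect_true(all(b$top$image[b$top$mask == 0] == 0))
  expect_identical(b$side$symmetry_order, 2L)
  expect_identical(b$top$symmetry_order, "circular")
  expect_error(make_base_projections(c(50, 10), 16, 48), "canvas")
})

test_that("side views are built 2-fold symmetric and top views circular", {
  b <- synthetic_bases(48)
  expect_equal(rotate_image(b$side$image, 180), b$side$image)
  expect_identical(rotate_image(b$side$mask, 180, is_mask = TRUE), b$side$mask)
  ## radial texture: a rotated top view stays almost perfectly correlated
  ## with the unrotated one under the mask (interpolation error only)
  r <- rotate_image(b$top$image, 77)
  m <- b$top$mask == 1
  expect_gt(cor(r[m], b$top$image[m]), 0.99)
})

test_that("planting honors counts, spacing, the angle grid, and the seed", {
  b <- synthetic_bases(48)
  sp <- plant_spec(n_particles = 5, min_separation = 60, angle_step = 4,
                   seed = 7)
  res <- plant_particles(c(256, 256), b, sp)
  expect_identical(nrow(res$truth), 5L)
  d <- as.matrix(dist(res$truth[, c("center_row", "center_col")]))
  expect_gte(min(d[upper.tri(d)]), 60)
  expect_true(all(res$truth$angle_deg %% 4 == 0))
  expect_false(any(duplicated(res$truth[, c("center_row", "center_col")])))
  res2 <- plant_particles(c(256, 256), b, sp)
  expect_identical(res$micrograph$pixels, res2$micrograph$pixels)
  expect_identical(res$truth, res2$truth)
  expect_error(
    plant_particles(c(128, 128), b,
                    plant_spec(n_particles = 40, min_separation = 60)),
    "could not place")
})

test_that("noise-free plants correlate to +/-1 at the planted centers", {
  b <- synthetic_bases(48)
  ts <- build_rotation_series(b, 4)
  for (amp in c(1, -1)) {
    res <- plant_particles(
      c(224, 224), b,
      plant_spec(n_particles = 3, noise_sigma = 0, amplitude = amp, seed = 19))
    sp <- micrograph_spectra(res$micrograph, c(48, 48))
    for (i in seq_len(3)) {
      tr <- res$truth[i, ]
      k <- ts$provenance$k[ts$provenance$base_id == tr$base_id &
                           ts$provenance$angle_deg == tr$angle_deg]
      nm <- masked_ncc(sp, ts$templates[[k + 1]])
      off <- c(tr$center_row, tr$center_col) - 24 + 1
      expect_equal(nm$scores[off[1], off[2]], amp, tolerance = 1e-3)
    }
  }
})

test_that("dataset generation is complete and bit-reproducible", {
  b <- synthetic_bases(48)
  sp <- plant_spec(n_particles = 2, min_separation = 60, seed = 5)
  d1 <- file.path(tempdir(), "synth1"); d2 <- file.path(tempdir(), "synth2")
  m1 <- generate_dataset(d1, 3, sp, canvas_shape = c(192, 192), bases = b)
  expect_length(m1$micrographs, 3)
  expect_identical(sort(list.files(d1, pattern = "\\.mrc$")),
                   c("mic_001.mrc", "mic_002.mrc", "mic_003.mrc"))
  expect_length(list.files(d1, pattern = "_truth\\.tsv$"), 3L)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  m2 <- generate_dataset(d2, 3, sp, canvas_shape = c(192, 192), bases = b)
  for (i in 1:3) {
    expect_identical(m1$micrographs[[i]]$md5_micrograph,
                     m2$micrographs[[i]]$md5_micrograph)
    expect_identical(m1$micrographs[[i]]$md5_truth,
                     m2$micrographs[[i]]$md5_truth)
  }
  ## seeds differ per micrograph, so contents do too
  expect_false(m1$micrographs[[1]]$md5_micrograph ==
               m1$micrographs[[2]]$md5_micrograph)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("recall does not improve as noise grows", {
  b <- synthetic_bases(48)
  ts <- build_rotation_series(b, 30, exploit_symmetry = TRUE)
  recall_at <- function(noise) {
    rec <- vapply(1:5, function(s) {
      res <- plant_particles(
        c(224, 224), b,
        plant_spec(n_particles = 4, noise_sigma = noise, angle_step = 30,
                   seed = 100 + s))
      cfg <- run_config(list(res$micrograph), ts, filter_k = 1)
      out <- pick_micrograph(res$micrograph, ts, cfg)
      match_picks(out$picks, res$truth, tol = 5)$recall
    }, numeric(1))
    mean(rec)
  }
  r <- c(recall_at(0.1), recall_at(1.5), recall_at(4))
  expect_true(all(diff(r) <= 1e-9))
  expect_gt(r[1], 0.9)
})
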