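test_that("rotation is exact at axis-aligned angles", {
  set.seed(21)
  img <- matrix(rnorm(15 * 15), 15, 15)
  expect_identical(rotate_image(img, 0), img)
  expect_identical(rotate_image(img, 360), img)
  n <- 15
  r90 <- matrix(NA_real_, n, n)
  for (r in 1:n) for (c in 1:n) r90[r, c] <- img[c, n + 1 - r]
  expect_equal(rotate_image(img, 90), r90)
  expect_equal(rotate_image(img, 180), img[n:1, n:1])
  expect_error(rotate_image(matrix(0, 3, 4), 10), "square")
})

test_that("rotations compose: 180 + a equals a applied to the flipped image", {
  set.seed(22)
  img <- matrix(rnorm(24 * 24), 24, 24)
  for (a in c(23, 57.5, 121))
    expect_equal(rotate_image(img, 180 + a),
                 rotate_image(img[24:1, 24:1], a), tolerance = 1e-12)
})

test_that("rotated masks stay binary with near-preserved area", {
  n <- 48; ctr <- (n + 1) / 2
  disk <- (outer((1:n - ctr)^2, (1:n - ctr)^2, "+") <= 14^2) * 1
  for (a in c(13, 37, 101, 233)) {
    r <- rotate_image(disk, a, is_mask = TRUE)
    expect_true(all(r %in% c(0, 1)))
    expect_lt(abs(sum(r) - sum(disk)) / sum(disk), 0.05)
    ## any flipped pixels sit in the 1.5-px boundary band of the disk
    flipped <- which(r != disk, arr.ind = TRUE)
    if (nrow(flipped)) {
      rho <- sqrt((flipped[, 1] - ctr)^2 + (flipped[, 2] - ctr)^2)
      expect_true(all(abs(rho - 14) < 1.5))
    }
  }
  set.seed(23)
  bases <- synthetic_bases(48)
  for (a in runif(8, 0, 360)) {
    m <- rotate_image(bases$side$mask, a, is_mask = TRUE)
    expect_gte(sum(m), 2)
    expect_lt(abs(sum(m) - sum(bases$side$mask)) / sum(bases$side$mask), 0.05)
  }
})

test_that("rotation series counts follow the step and the symmetry", {
  bases <- synthetic_bases(48)
  full <- build_rotation_series(bases, 4)
  expect_length(full$templates, 180)
  sym <- build_rotation_series(bases, 4, exploit_symmetry = TRUE)
  expect_length(sym$templates, 46)     # 45 side (2-fold) + 1 circular top
  one <- build_rotation_series(bases[1], 90)
  expect_length(one$templates, 4)
  expect_equal(one$provenance$angle_deg, c(0, 90, 180, 270))
  expect_error(build_rotation_series(bases, 7), "nearest valid")
})

test_that("template indices and provenance are stable and duplicate-free", {
  bases <- synthetic_bases(48)
  ts <- build_rotation_series(bases, 24, exploit_symmetry = TRUE)
  expect_identical(ts$provenance$k, seq_len(length(ts$templates)) - 1L)
  expect_false(any(duplicated(ts$provenance[c("base_id", "angle_deg")])))
  side_angles <- ts$provenance$angle_deg[ts$provenance$base_id == "side"]
  expect_equal(side_angles, seq(0, 156, by = 24))
  expect_identical(vapply(ts$templates, `[[`, integer(1), "k"),
                   ts$provenance$k)
})

test_that("template sets round trip through MRC stacks and TSV", {
  ts <- build_rotation_series(synthetic_bases(48)[1], 120)
  prefix <- tempfile()
  write_template_set(ts, prefix)
  back <- read_template_set(prefix)
  expect_length(back$templates, 3)
  expect_equal(back$provenance$angle_deg, ts$provenance$angle_deg)
  expect_equal(back$templates[[2]]$mask, ts$templates[[2]]$mask)
  expect_equal(back$templates[[2]]$image, ts$templates[[2]]$image,
               tolerance = 1e-6)
})
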