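make_template <- function(tr, tc, n_zero = 0, seed = 1) {
  set.seed(seed)
  img <- matrix(rnorm(tr * tc), tr, tc)
  mask <- matrix(1, tr, tc)
  if (n_zero > 0) mask[sample(tr * tc, n_zero)] <- 0
  template_with_mask(img, mask)
}

test_that("shared spectra use smooth padding and hold the DC term", {
  set.seed(4)
  img <- matrix(rnorm(30 * 20), 30, 20)
  sp <- micrograph_spectra(micrograph(img), c(8, 5))
  expect_identical(sp$padded_shape, c(smooth_size(37), smooth_size(24)))
  expect_equal(Re(sp$spectrum_I[1, 1]), sum(img))
  expect_identical(sp$fft_count, 2L)
  z <- micrograph_spectra(matrix(0, 10, 10), c(3, 3))
  expect_true(all(Mod(z$spectrum_I) == 0) && all(Mod(z$spectrum_I2) == 0))
  expect_error(micrograph_spectra(matrix(0, 4, 4), c(5, 2)), "larger")
})

test_that("masked NCC equals the spatial-domain oracle on seeded cases", {
  for (s in 1:10) {
    set.seed(s)
    nr <- sample(10:32, 1); nc <- sample(10:32, 1)
    tr <- sample(3:8, 1); tc <- sample(3:8, 1)
    I <- matrix(rnorm(nr * nc), nr, nc)
    tm <- make_template(tr, tc, n_zero = sample(0:(tr * tc - 6), 1), seed = s + 100)
    res <- masked_ncc(micrograph_spectra(micrograph(I), c(tr, tc)), tm)
    expect_identical(res$valid_shape, c(nr - tr + 1L, nc - tc + 1L))
    expect_lt(max(abs(res$scores -
                      oracle_masked_ncc(I, tm$image, tm$mask))), 1e-6)
  }
})

test_that("an exact planted copy scores 1 and affine shifts leave scores alone", {
  set.seed(9)
  tm <- make_template(6, 6, n_zero = 5, seed = 9)
  I <- matrix(0.1 * rnorm(24 * 24), 24, 24)
  I[9:14, 11:16] <- tm$image
  sc <- masked_ncc(micrograph_spectra(micrograph(I), c(6, 6)), tm)$scores
  expect_equal(sc[9, 11], 1, tolerance = 1e-4)
  expect_true(all(sc >= -1 - 1e-4 & sc <= 1 + 1e-4))
  sc2 <- masked_ncc(micrograph_spectra(micrograph(3.2 * I + 7), c(6, 6)), tm)$scores
  expect_lt(max(abs(sc - sc2)), 1e-5)
})

test_that("translating the particle translates the peak (shift equivariance)", {
  tm <- make_template(5, 5, seed = 11)
  base <- matrix(0.05 * rnorm(30 * 30), 30, 30)
  peak_at <- function(dr, dc) {
    I <- base
    I[(5 + dr):(9 + dr), (7 + dc):(11 + dc)] <- tm$image
    which(masked_ncc(micrograph_spectra(micrograph(I), c(5, 5)),
                     tm)$scores >= 1 - 1e-6, arr.ind = TRUE)[1, ]
  }
  p0 <- peak_at(0, 0)
  for (d in list(c(3, 0), c(0, 4), c(7, 9)))
    expect_equal(unname(peak_at(d[1], d[2]) - p0), d)
})

test_that("any larger smooth padding yields identical correlation maps", {
  set.seed(12)
  I <- matrix(rnorm(20 * 20), 20, 20)
  tm <- make_template(6, 6, n_zero = 4, seed = 12)
  minimal <- micrograph_spectra(micrograph(I), c(6, 6))
  sc1 <- masked_ncc(minimal, tm)$scores
  bigger <- c(smooth_size(minimal$padded_shape[1] + 1),
              smooth_size(minimal$padded_shape[2] + 5))
  sc2 <- masked_ncc(micrograph_spectra(micrograph(I), c(6, 6),
                                       padded_shape = bigger), tm)$scores
  expect_lt(max(abs(sc1 - sc2)), 1e-6)
})

test_that("flat windows score 0 and flat templates are rejected", {
  I <- matrix(0, 16, 16); I[1:4, 1:4] <- matrix(rnorm(16), 4, 4)
  tm <- make_template(3, 3, seed = 13)
  sc <- masked_ncc(micrograph_spectra(micrograph(I), c(3, 3)), tm)$scores
  expect_true(all(sc[10:14, 10:14] == 0))      # deep inside the flat region
  expect_error(template_with_mask(matrix(1, 4, 4), matrix(1, 4, 4)), "flat")
  expect_error(template_with_mask(matrix(rnorm(16), 4, 4), matrix(0, 4, 4)),
               "at least 2")
})

test_that("the FFT counter matches the published accounting", {
  expect_identical(fft_op_count(0), 0L)
  expect_identical(fft_op_count(1), 7L)          # 2 shared + 5 per template
  expect_identical(fft_op_count(14630), 73152L)
  sched <- fft_schedule(2)
  expect_identical(nrow(sched), 12L)
  expect_identical(sum(is.na(sched$template)), 2L)
  expect_error(fft_op_count(-1), "non-negative")

  set.seed(14)
  I <- matrix(rnorm(40 * 40), 40, 40)
  fft_count_reset()
  sp <- micrograph_spectra(micrograph(I), c(7, 7))
  for (s in 1:3) masked_ncc(sp, make_template(7, 7, n_zero = 3, seed = s))
  expect_identical(fft_count(), fft_op_count(3))
})
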