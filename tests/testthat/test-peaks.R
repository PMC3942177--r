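## small handmade score map with isolated extrema
peak_map <- function(vals, at, shape = c(40, 40)) {
  m <- matrix(0, shape[1], shape[2])
  for (i in seq_along(vals)) m[at[[i]][1], at[[i]][2]] <- vals[i]
  m
}

test_that("isolated extrema are picked on the right side of the threshold", {
  ## two minima: only the one below -0.3 is called in polarity \"min\"
  m <- peak_map(c(-0.5, -0.2), list(c(10, 10), c(30, 30)))
  picks <- extract_peaks(m, threshold = -0.3, polarity = "min",
                         min_distance = 3, template_shape = c(1, 1))
  expect_identical(nrow(picks), 1L)
  expect_equal(picks$score, -0.5)
  expect_equal(c(picks$center_row, picks$center_col), c(9, 9))  # 0-based
  ## centers include the template half-shape shift
  picks2 <- extract_peaks(m, threshold = -0.3, polarity = "min",
                          min_distance = 3, template_shape = c(8, 8))
  expect_equal(c(picks2$center_row, picks2$center_col), c(9 + 4, 9 + 4))
})

test_that("suppression keeps only the strongest of nearby candidates", {
  m <- peak_map(c(0.8, 0.9), list(c(20, 20), c(20, 23)))
  picks <- extract_peaks(m, threshold = 0.5, polarity = "max",
                         min_distance = 10, template_shape = c(1, 1))
  expect_identical(nrow(picks), 1L)
  expect_equal(picks$score, 0.9)
})

test_that("polarity is a pure sign flip and thresholds are sign-checked", {
  set.seed(91)
  m <- matrix(rnorm(50 * 50, sd = 0.2), 50, 50)
  p_max <- extract_peaks(m, 0.25, "max", min_distance = 4,
                         template_shape = c(3, 3))
  p_min <- extract_peaks(-m, -0.25, "min", min_distance = 4,
                         template_shape = c(3, 3))
  expect_equal(p_max$center_row, p_min$center_row)
  expect_equal(p_max$center_col, p_min$center_col)
  expect_equal(p_max$score, -p_min$score)
  expect_error(extract_peaks(m, -0.2, "max", 3, c(3, 3)), "polarity")
  expect_error(extract_peaks(m, 0.2, "min", 3, c(3, 3)), "polarity")
})

test_that("raising the threshold never adds picks; pick spacing is enforced", {
  set.seed(92)
  m <- matrix(rnorm(60 * 60, sd = 0.3), 60, 60)
  prev <- Inf
  for (thr in c(0.2, 0.4, 0.6, 0.8)) {
    p <- extract_peaks(m, thr, "max", min_distance = 5,
                       template_shape = c(5, 5))
    expect_lte(nrow(p), prev)
    prev <- nrow(p)
    if (nrow(p) > 1) {
      d <- as.matrix(dist(cbind(p$center_row, p$center_col)))
      expect_gt(min(d[upper.tri(d)]), 5)
    }
    if (nrow(p)) expect_gte(min(p$score), thr)
  }
})

test_that("pick/reference matching yields the declared metrics", {
  ref <- data.frame(center_row = c(10, 30), center_col = c(10, 30))
  exact <- match_picks(ref, ref, tol = 3)
  expect_equal(exact$precision, 1)
  expect_equal(exact$recall, 1)
  expect_equal(exact$mean_match_distance, 0)

  none <- match_picks(ref[0, ], ref, tol = 3)
  expect_equal(none$recall, 0)
  expect_equal(none$precision, 0)
  expect_equal(none$f_measure, 0)

  ## 3 picks, 2 refs, one pair within tolerance
  picks <- data.frame(center_row = c(10, 100, 200),
                      center_col = c(11, 100, 200))
  m <- match_picks(picks, ref, tol = 3)
  expect_equal(m$true_positives, 1L)
  expect_equal(m$precision, 1 / 3)
  expect_equal(m$recall, 1 / 2)
  expect_equal(m$f_measure, 0.4)
  expect_equal(m$mean_match_distance, 1)
})

test_that("matching is one-to-one, nearest-first, and metric algebra holds", {
  ## two picks near one reference: only the closer matches
  picks <- data.frame(center_row = c(10, 12), center_col = c(10, 10))
  ref <- data.frame(center_row = 11, center_col = 10)
  m <- match_picks(picks, ref, tol = 5)
  expect_equal(m$true_positives, 1L)
  expect_equal(m$mean_match_distance, 1)
  set.seed(93)
  for (i in 1:20) {
    pk <- data.frame(center_row = runif(7, 0, 50), center_col = runif(7, 0, 50))
    rf <- data.frame(center_row = runif(5, 0, 50), center_col = runif(5, 0, 50))
    mm <- match_picks(pk, rf, tol = 10)
    expect_equal(mm$fdr + mm$precision, 1)
    pr <- mm$precision + mm$recall
    expect_equal(mm$f_measure,
                 if (pr > 0) 2 * mm$precision * mm$recall / pr else 0)
    expect_lte(mm$true_positives, min(mm$n_picks, mm$n_reference))
  }
})

test_that("the ranking curve counts cumulative true positives per prefix", {
  ref <- data.frame(center_row = c(5, 15, 25), center_col = c(5, 15, 25))
  all_true <- data.frame(center_row = c(5, 15, 25), center_col = c(5, 15, 25),
                         score = c(0.9, 0.8, 0.7))
  rc <- roc_points(all_true, ref, tol = 2)
  expect_equal(rc$true_positive_count, 1:3)
  all_false <- data.frame(center_row = c(40, 45), center_col = c(40, 45),
                          score = c(0.9, 0.8))
  expect_equal(roc_points(all_false, ref, tol = 2)$true_positive_count, c(0, 0))
  expect_error(roc_points(data.frame(center_row = 1:2, center_col = 1:2,
                                     score = c(0.1, 0.9)), ref, tol = 2),
               "sorted")
})

test_that("the ranking curve matches a brute-force prefix oracle", {
  set.seed(94)
  truth <- data.frame(center_row = runif(6, 0, 100),
                      center_col = runif(6, 0, 100))
  picks <- data.frame(
    center_row = c(truth$center_row + rnorm(6, 0, 1), runif(4, 0, 100)),
    center_col = c(truth$center_col + rnorm(6, 0, 1), runif(4, 0, 100)),
    score = seq(1, 0.1, length.out = 10))
  rc <- roc_points(picks, truth, tol = 4)
  ## oracle: replay the incremental nearest-available matching per prefix
  ## with an independent O(n^2) implementation
  for (depth in 1:10) {
    avail <- rep(TRUE, 6)
    tp <- 0
    for (i in 1:depth) {
      best <- NA; bestd <- Inf
      for (j in 1:6) {
        dd <- sqrt((picks$center_row[i] - truth$center_row[j])^2 +
                   (picks$center_col[i] - truth$center_col[j])^2)
        if (avail[j] && dd < bestd) { bestd <- dd; best <- j }
      }
      if (!is.na(best) && bestd <= 4) { avail[best] <- FALSE; tp <- tp + 1 }
    }
    expect_equal(rc$true_positive_count[depth], tp)
  }
})
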