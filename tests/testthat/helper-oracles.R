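# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: plain loops and direct formulas.

# brute-force next 7-smooth integer >= n
oracle_smooth <- function(n) {
  m <- ceiling(n)
  repeat {
    r <- m
    for (p in c(7, 5, 3, 2)) while (r %% p == 0) r <- r / p
    if (r == 1) return(m)
    m <- m + 1
  }
}

# spatial-domain masked Pearson correlation at every valid offset
oracle_masked_ncc <- function(I, Tm, M) {
  tr <- nrow(Tm); tc <- ncol(Tm)
  vr <- nrow(I) - tr + 1; vc <- ncol(I) - tc + 1
  P <- sum(M)
  tv <- Tm[M == 1]
  out <- matrix(0, vr, vc)
  for (i in seq_len(vr)) for (j in seq_len(vc)) {
    w <- I[i:(i + tr - 1), j:(j + tc - 1)][M == 1]
    num <- sum(w * tv) - sum(w) * sum(tv) / P
    den <- sqrt(sum(w^2) - sum(w)^2 / P) * sqrt(sum(tv^2) - sum(tv)^2 / P)
    out[i, j] <- num / den
  }
  out
}

# naive mean filter with edge-mirroring boundary (anchor floor((k-1)/2))
oracle_mean_filter <- function(img, k) {
  a <- (k - 1) %/% 2
  nr <- nrow(img); nc <- ncol(img)
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (di in 0:(k - 1)) for (dj in 0:(k - 1))
      s <- s + img[reflect(i - a + di, nr), reflect(j - a + dj, nc)]
    out[i, j] <- s / k^2
  }
  out
}

# random score/index map pair for reduction tests
random_maps <- function(shape, k, seed) {
  set.seed(seed)
  score_index_maps(matrix(round(rnorm(prod(shape)), 3), shape[1], shape[2]),
                   matrix(k, shape[1], shape[2]), 1L)
}

# sequential left fold of merge_pair, the reduction oracle
fold_maps <- function(parts) Reduce(merge_pair, parts)

# toy picking scenario shared by several tests: small bases, coarse angular
# step, planted particles on the matching angle grid
toy_scene <- function(n_particles = 4, noise_sigma = 0.1, seed = 42,
                      canvas = c(224, 224), amplitude = -1,
                      step_deg = 30) {
  bases <- synthetic_bases(48)
  tset <- build_rotation_series(bases, step_deg, exploit_symmetry = TRUE)
  sc <- plant_particles(
    canvas, bases,
    plant_spec(n_particles = n_particles, noise_sigma = noise_sigma,
               amplitude = amplitude, angle_step = step_deg, seed = seed))
  list(bases = bases, tset = tset, micrograph = sc$micrograph,
       truth = sc$truth)
}

# angular distance between a picked and a planted angle, respecting the
# base view's symmetry (side views repeat every 180 degrees; circular top
# views match at any angle)
angle_error <- function(picked, planted, base_id) {
  if (base_id == "top") return(0)
  period <- if (base_id == "side") 180 else 360
  d <- (picked - planted) %% period
  min(d, period - d)
}
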