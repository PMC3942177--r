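## Peak extraction and pick-versus-reference evaluation.

#' Extract particle picks from global score/index maps
#'
#' Candidates are local maxima of the score map in a
#' `(2*min_distance + 1)^2` neighborhood that reach the threshold; they are
#' then accepted greedily in order of decreasing score (ties broken by
#' (row, col)), suppressing any later candidate within Euclidean distance
#' `min_distance` of an accepted pick.
#'
#' In cryo-EM the particles are often darker than the background, so a
#' positive-density template correlates *negatively* at true particle
#' positions. With `polarity = "min"` the map is negated internally and the
#' threshold sign flipped, so picking is always "maxima above a positive
#' threshold"; reported scores keep their original sign.
#'
#' Pick centers are reported as `offset + floor(template_shape / 2)` in
#' 0-based (row, col) coordinates. Offsets index the template's top-left
#' corner, so every reported pick's template footprint lies fully inside the
#' micrograph by construction.
#'
#' @param maps A [score_index_maps] (or a bare numeric matrix, in which case
#'   all template indices are reported as `NA`).
#' @param threshold Score cut: with `polarity = "max"` picks must score at
#'   least `threshold` (> 0); with `"min"` at most `threshold` (< 0).
#' @param polarity `"max"` or `"min"`.
#' @param min_distance Suppression radius in pixels (>= 1). Default: half
#'   the template width.
#' @param template_shape Integer `c(rows, cols)` of the templates that
#'   produced the maps; fixes the offset-to-center shift.
#' @param provenance Optional provenance data.frame (columns `k`,
#'   `angle_deg`, as in a `template_set`) used to annotate picks with angles.
#' @param micrograph_id Identifier copied into every pick row.
#' @return A data.frame of class `picks` with columns `center_row`,
#'   `center_col` (0-based), `score`, `k`, `angle_deg`, `micrograph_id`,
#'   ordered by decreasing score strength.
#' @export
extract_peaks <- function(maps, threshold, polarity = c("max", "min"),
                          min_distance = floor(template_shape[2] / 2),
                          template_shape, provenance = NULL,
                          micrograph_id = "micrograph") {
  polarity <- match.arg(polarity)
  if (inherits(maps, "score_index_maps")) {
    sc <- maps$ncc; ind <- maps$ind
  } else if (is.matrix(maps)) {
    sc <- maps; ind <- matrix(NA_integer_, nrow(sc), ncol(sc))
  } else stop("'maps' must be score_index_maps or a matrix")
  if (polarity == "max" && threshold <= 0)
    stop("polarity \"max\" picks high scores: 'threshold' must be > 0 ",
         "(use polarity = \"min\" for negative-going peaks)")
  if (polarity == "min" && threshold >= 0)
    stop("polarity \"min\" picks low scores: 'threshold' must be < 0 ",
         "(use polarity = \"max\" for positive-going peaks)")
  if (min_distance < 1) stop("'min_distance' must be >= 1")
  template_shape <- as.integer(template_shape)
  work <- if (polarity == "min") -sc else sc
  thr <- if (polarity == "min") -threshold else threshold
  work[!is.finite(work)] <- -Inf
  d <- as.integer(ceiling(min_distance))
  loc_max <- work >= neighborhood_max(work, d)
  cand <- which(loc_max & work >= thr, arr.ind = TRUE)
  out <- data.frame(center_row = integer(0), center_col = integer(0),
                    score = numeric(0), k = integer(0),
                    angle_deg = numeric(0),
                    micrograph_id = character(0))
  if (nrow(cand)) {
    v <- work[cand]
    o <- order(-v, cand[, 1], cand[, 2])
    cand <- cand[o, , drop = FALSE]
    v <- v[o]
    keep <- logical(nrow(cand))
    acc_r <- numeric(0); acc_c <- numeric(0)
    for (i in seq_len(nrow(cand))) {
      if (length(acc_r)) {
        dd <- sqrt((acc_r - cand[i, 1])^2 + (acc_c - cand[i, 2])^2)
        if (any(dd <= min_distance)) next
      }
      keep[i] <- TRUE
      acc_r <- c(acc_r, cand[i, 1]); acc_c <- c(acc_c, cand[i, 2])
    }
    cand <- cand[keep, , drop = FALSE]
    kk <- ind[cand]
    out <- data.frame(
      center_row = cand[, 1] - 1L + template_shape[1] %/% 2L,
      center_col = cand[, 2] - 1L + template_shape[2] %/% 2L,
      score = sc[cand],
      k = kk,
      angle_deg = if (!is.null(provenance))
        provenance$angle_deg[match(kk, provenance$k)] else NA_real_,
      micrograph_id = micrograph_id)
  }
  class(out) <- c("picks", "data.frame")
  out
}

## square-neighborhood running max (radius d), separable by rows then cols
neighborhood_max <- function(m, d) {
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (s in seq_len(d)) {           # vertical shifts
    out[seq_len(nr - s), ] <- pmax(out[seq_len(nr - s), , drop = FALSE],
                                   m[(s + 1):nr, , drop = FALSE])
    out[(s + 1):nr, ] <- pmax(out[(s + 1):nr, , drop = FALSE],
                              m[seq_len(nr - s), , drop = FALSE])
  }
  m2 <- out
  for (s in seq_len(d)) {           # horizontal shifts
    out[, seq_len(nc - s)] <- pmax(out[, seq_len(nc - s), drop = FALSE],
                                   m2[, (s + 1):nc, drop = FALSE])
    out[, (s + 1):nc] <- pmax(out[, (s + 1):nc, drop = FALSE],
                              m2[, seq_len(nc - s), drop = FALSE])
  }
  out
}

#' Match picks against reference coordinates and score the picking
#'
#' Greedy one-to-one matching by ascending distance: the closest
#' (pick, reference) pair within `tol` is matched first, both are removed,
#' and so on. From the matching it computes precision, recall, false
#' discovery rate, F-measure and the mean pick-to-reference distance over
#' matched pairs.
#'
#' @param picks A `picks` data.frame (or any data.frame with `center_row`,
#'   `center_col`).
#' @param reference Reference centers: a data.frame/matrix with
#'   `center_row`, `center_col` columns (or two unnamed columns taken as
#'   row, col).
#' @param tol Match tolerance in pixels (> 0).
#' @return An object of class `picking_metrics`: `n_picks`, `n_reference`,
#'   `true_positives`, `precision`, `recall`, `fdr`, `f_measure`,
#'   `mean_match_distance` (NaN when nothing matched). Precision and recall
#'   are defined as 0 when their denominators are 0.
#' @export
match_picks <- function(picks, reference, tol) {
  if (tol <= 0) stop("'tol' must be > 0")
  pk <- coords_of(picks); rf <- coords_of(reference)
  np <- nrow(pk); nr <- nrow(rf)
  matched <- match_greedy(pk, rf, tol)
  tp <- nrow(matched)
  precision <- if (np > 0) tp / np else 0
  recall <- if (nr > 0) tp / nr else 0
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(
    list(n_picks = np, n_reference = nr, true_positives = tp,
         precision = precision, recall = recall, fdr = 1 - precision,
         f_measure = f,
         mean_match_distance = if (tp > 0) mean(matched$dist) else NaN,
         matches = matched),
    class = "picking_metrics")
}

## greedy ascending-distance one-to-one matching within tol;
## returns data.frame(pick, ref, dist)
match_greedy <- function(pk, rf, tol) {
  if (!nrow(pk) || !nrow(rf))
    return(data.frame(pick = integer(0), ref = integer(0), dist = numeric(0)))
  dmat <- outer(pk[, 1], rf[, 1], "-")^2 + outer(pk[, 2], rf[, 2], "-")^2
  idx <- which(dmat <= tol^2, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(pick = integer(0), ref = integer(0), dist = numeric(0)))
  dd <- sqrt(dmat[idx])
  o <- order(dd, idx[, 1], idx[, 2])
  idx <- idx[o, , drop = FALSE]; dd <- dd[o]
  used_p <- logical(nrow(pk)); used_r <- logical(nrow(rf))
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    p <- idx[i, 1]; r <- idx[i, 2]
    if (!used_p[p] && !used_r[r]) {
      keep[i] <- TRUE; used_p[p] <- TRUE; used_r[r] <- TRUE
    }
  }
  data.frame(pick = idx[keep, 1], ref = idx[keep, 2], dist = dd[keep])
}

coords_of <- function(x) {
  if (is.null(x) || !NROW(x))
    return(matrix(numeric(0), 0, 2))
  if (is.matrix(x)) return(x[, 1:2, drop = FALSE])
  if (all(c("center_row", "center_col") %in% names(x)))
    return(cbind(x$center_row, x$center_col))
  as.matrix(x[, 1:2])
}

#' @export
print.picking_metrics <- function(x, ...) {
  cat(sprintf(
    "<picking_metrics> %d picks vs %d reference: TP %d\n  precision %.1f%%  recall %.1f%%  FDR %.1f%%  F-measure %.1f%%  mean dist %.2f px\n",
    x$n_picks, x$n_reference, x$true_positives, 100 * x$precision,
    100 * x$recall, 100 * x$fdr, 100 * x$f_measure, x$mean_match_distance))
  invisible(x)
}

#' ROC-style ranking curve for a scored pick list
#'
#' Walks the ranked pick list from strongest to weakest and reports the
#' cumulative number of true positives among the top `n` picks, for every
#' prefix depth `n`. Matching is incremental and never retracted: each pick,
#' in rank order, is matched to the nearest still-unmatched reference within
#' `tol`.
#'
#' @param ranked_picks A `picks` data.frame sorted by decreasing score
#'   strength in the configured polarity (an unsorted list is an error).
#' @param reference Reference centers (as in [match_picks()]).
#' @param tol Match tolerance in pixels.
#' @param polarity `"max"` (strength = score) or `"min"`
#'   (strength = -score).
#' @return A data.frame with columns `n_considered` (1..n picks) and
#'   `true_positive_count`.
#' @export
roc_points <- function(ranked_picks, reference, tol,
                       polarity = c("max", "min")) {
  polarity <- match.arg(polarity)
  pk <- coords_of(ranked_picks)
  n <- nrow(pk)
  if (n > 0 && !is.null(ranked_picks$score)) {
    strength <- if (polarity == "min") -ranked_picks$score else ranked_picks$score
    if (any(diff(strength) > 0))
      stop("'ranked_picks' must be sorted by decreasing score strength")
  }
  rf <- coords_of(reference)
  used_r <- logical(nrow(rf))
  tp <- integer(n)
  run <- 0L
  for (i in seq_len(n)) {
    if (nrow(rf)) {
      dd <- sqrt((rf[, 1] - pk[i, 1])^2 + (rf[, 2] - pk[i, 2])^2)
      dd[used_r] <- Inf
      j <- which.min(dd)
      if (length(j) && dd[j] <= tol) {
        used_r[j] <- TRUE
        run <- run + 1L
      }
    }
    tp[i] <- run
  }
  data.frame(n_considered = seq_len(n), true_positive_count = tp)
}

#' Write picks as an EMAN-style .box file
#'
#' Each line is `x - boxsize/2, y - boxsize/2, boxsize, boxsize`
#' (tab-separated), with `x = center_col` and `y = center_row` (0-based).
#'
#' @param picks A `picks` data.frame.
#' @param path Output path.
#' @param boxsize Box edge length in pixels.
#' @return `path`, invisibly.
#' @export
write_box <- function(picks, path, boxsize) {
  df <- data.frame(x = picks$center_col - boxsize %/% 2L,
                   y = picks$center_row - boxsize %/% 2L,
                   w = boxsize, h = boxsize)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read picks as TSV
#'
#' Column order `micrograph_id, center_col, center_row, score, k,
#' angle_deg`.
#'
#' @param picks A `picks` data.frame.
#' @param path File path.
#' @return `write_picks_tsv`: `path` invisibly; `read_picks_tsv`: a `picks`
#'   data.frame.
#' @export
write_picks_tsv <- function(picks, path) {
  df <- data.frame(micrograph_id = picks$micrograph_id,
                   center_col = picks$center_col,
                   center_row = picks$center_row,
                   score = sprintf("%.8g", picks$score),
                   k = picks$k, angle_deg = picks$angle_deg)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_picks_tsv
#' @export
read_picks_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  out <- data.frame(center_row = df$center_row, center_col = df$center_col,
                    score = df$score, k = df$k, angle_deg = df$angle_deg,
                    micrograph_id = df$micrograph_id)
  class(out) <- c("picks", "data.frame")
  out
}

#' Read reference coordinates from TSV or two-column x/y text
#'
#' Accepts the pick TSV dialect of [write_picks_tsv()] or a headerless
#' two-column `x y` file (columns interpreted as col, row).
#'
#' @param path Coordinate file.
#' @return Data.frame with `center_row`, `center_col`.
#' @export
read_coords <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("center_row", first, fixed = TRUE)) {
    df <- utils::read.table(path, sep = "\t", header = TRUE)
    return(data.frame(center_row = df$center_row, center_col = df$center_col))
  }
  df <- utils::read.table(path, header = FALSE)
  data.frame(center_row = df[[2]], center_col = df[[1]])
}
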