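## Max/argmax reduction of per-template correlation maps.
##
## The global correlation map keeps, at every offset v, the best score over
## all templates, NCC(v) = max_k NCC_k(v), and the index map records which
## template achieved it, IND(v) = argmax_k NCC_k(v). Ties are broken toward
## the smaller template index, which makes the pairwise merge associative
## and commutative — so any reduction topology (sequential, binary tree, or
## any permutation of the parts) produces bit-identical results, the
## property that lets worker partitions be reduced in any order.

#' Construct a score/index map pair
#'
#' @param ncc Numeric matrix of best-so-far correlation scores per offset.
#' @param ind Integer matrix of the template index achieving each score;
#'   `-1` is the sentinel for "no contribution" (paired with `-Inf` score).
#' @param n_templates_merged Number of templates merged in.
#' @return An object of class `score_index_maps`.
#' @export
score_index_maps <- function(ncc, ind, n_templates_merged = 0L) {
  if (!is.matrix(ncc) || !is.matrix(ind) || !identical(dim(ncc), dim(ind)))
    stop("'ncc' and 'ind' must be matrices of one shape")
  storage.mode(ind) <- "integer"
  if (any(ind < -1L)) stop("index values must be >= -1")
  structure(list(ncc = ncc, ind = ind,
                 n_templates_merged = as.integer(n_templates_merged)),
            class = "score_index_maps")
}

#' Identity element for map reduction
#'
#' All scores `-Inf`, all indices `-1`; merging it into any map leaves the
#' map unchanged.
#'
#' @param shape Integer vector `c(rows, cols)`.
#' @return A `score_index_maps` object.
#' @export
empty_maps <- function(shape) {
  score_index_maps(matrix(-Inf, shape[1], shape[2]),
                   matrix(-1L, shape[1], shape[2]), 0L)
}

#' Convert one correlation map into a single-template score/index pair
#'
#' @param m An [ncc_map].
#' @return A `score_index_maps` with `ind` equal to `m$k` everywhere.
#' @export
as_score_index_maps <- function(m) {
  stopifnot(inherits(m, "ncc_map"))
  score_index_maps(m$scores,
                   matrix(m$k, nrow(m$scores), ncol(m$scores)), 1L)
}

#' Merge two score/index map pairs elementwise
#'
#' Keeps the larger score and its template index at every offset. On an
#' exact score tie the smaller template index wins; the sentinel index `-1`
#' loses to any real contribution.
#'
#' @param a,b `score_index_maps` of equal shape.
#' @return The merged `score_index_maps`.
#' @export
merge_pair <- function(a, b) {
  stopifnot(inherits(a, "score_index_maps"), inherits(b, "score_index_maps"))
  if (!identical(dim(a$ncc), dim(b$ncc)))
    stop("cannot merge maps of different shapes")
  ## b wins on strictly larger score, or on a tie where its real index is
  ## smaller (or a's is the sentinel)
  tie <- b$ncc == a$ncc
  b_wins <- b$ncc > a$ncc |
    (tie & b$ind != -1L & (a$ind == -1L | b$ind < a$ind))
  ncc <- a$ncc; ind <- a$ind
  ncc[b_wins] <- b$ncc[b_wins]
  ind[b_wins] <- b$ind[b_wins]
  score_index_maps(ncc, ind, a$n_templates_merged + b$n_templates_merged)
}

#' Plan a reduction topology
#'
#' Builds the merge schedule that combines `n_parts` partial maps into one.
#' `direct` merges every part into a single accumulator one after another
#' (`P - 1` transfers and `P - 1` sequential merge rounds). `tree` merges
#' pairs in parallel rounds (for `P = 2^n` exactly `n` rounds); each part is
#' still merged once, but the sequential depth is only `ceiling(log2(P))`.
#'
#' @param topology `"direct"` or `"tree"`.
#' @param n_parts Number of partial maps `P >= 1`.
#' @return An object of class `reduction_plan`: the topology, `n_parts`,
#'   the `schedule` (data.frame of merge steps: round, destination part,
#'   source part), and the `transfers` and `rounds` counts.
#' @export
reduction_plan <- function(topology = c("direct", "tree"), n_parts) {
  topology <- match.arg(topology)
  if (length(n_parts) != 1L || n_parts < 1 || n_parts != round(n_parts))
    stop("'n_parts' must be an integer >= 1")
  P <- as.integer(n_parts)
  steps <- list()
  if (topology == "direct") {
    if (P > 1L)
      steps <- list(data.frame(round = seq_len(P - 1L), dst = 1L,
                               src = 2:P))
    rounds <- P - 1L
  } else {
    stride <- 1L
    round <- 0L
    while (stride < P) {
      round <- round + 1L
      dst <- seq(1L, P, by = 2L * stride)
      src <- dst + stride
      keep <- src <= P
      steps[[round]] <- data.frame(round = round, dst = dst[keep],
                                   src = src[keep])
      stride <- 2L * stride
    }
    rounds <- round
  }
  schedule <- if (length(steps)) do.call(rbind, steps)
              else data.frame(round = integer(0), dst = integer(0),
                              src = integer(0))
  structure(list(topology = topology, n_parts = P, schedule = schedule,
                 transfers = nrow(schedule), rounds = rounds),
            class = "reduction_plan")
}

#' Reduce partial score/index maps into the global maps
#'
#' Executes the plan's merge schedule. Because [merge_pair()] is associative
#' and commutative, the result equals the sequential left fold of the parts
#' for every topology, bit for bit.
#'
#' @param parts Non-empty list of `score_index_maps` of one shape.
#' @param plan A [reduction_plan] for `length(parts)` parts; defaults to
#'   direct reduction.
#' @return The global `score_index_maps`, with attributes `n_merges` (total
#'   pairwise merges executed, always `P - 1`) and `n_rounds`.
#' @export
reduce_maps <- function(parts, plan = reduction_plan("direct", length(parts))) {
  if (!length(parts)) stop("'parts' must be a non-empty list")
  stopifnot(inherits(plan, "reduction_plan"),
            plan$n_parts == length(parts))
  slots <- parts
  n_merges <- 0L
  sched <- plan$schedule
  if (nrow(sched)) {
    for (i in seq_len(nrow(sched))) {
      d <- sched$dst[i]; s <- sched$src[i]
      slots[[d]] <- merge_pair(slots[[d]], slots[[s]])
      n_merges <- n_merges + 1L
    }
  }
  out <- slots[[1L]]
  attr(out, "n_merges") <- n_merges
  attr(out, "n_rounds") <- plan$rounds
  out
}

#' Transfer and round costs of a reduction topology
#'
#' For `P` partial maps: direct reduction needs `P - 1` data transfers and
#' `P - 1` sequential reduce operations; tree reduction needs only
#' `ceiling(log2(P))` rounds of transfers/reduces (its total pairwise merge
#' count is still `P - 1`, but merges within a round are independent).
#'
#' @param P Number of parts (integer >= 1).
#' @param topology `"direct"` or `"tree"`.
#' @return List with integer `transfers` and `rounds`.
#' @examples
#' topology_cost(8, "direct")  # 7 transfers
#' topology_cost(8, "tree")    # 3 rounds
#' @export
topology_cost <- function(P, topology = c("direct", "tree")) {
  topology <- match.arg(topology)
  if (length(P) != 1L || P < 1 || P != round(P))
    stop("'P' must be an integer >= 1")
  P <- as.integer(P)
  if (topology == "direct")
    list(transfers = P - 1L, rounds = P - 1L)
  else {
    r <- as.integer(ceiling(log2(P)))
    list(transfers = r, rounds = r)
  }
}

#' @export
print.score_index_maps <- function(x, ...) {
  fin <- x$ncc[is.finite(x$ncc)]
  cat(sprintf("<score_index_maps> %d x %d, %d templates merged, score range [%.4f, %.4f]\n",
              nrow(x$ncc), ncol(x$ncc), x$n_templates_merged,
              if (length(fin)) min(fin) else NA, if (length(fin)) max(fin) else NA))
  invisible(x)
}

#' Plot the global correlation map
#'
#' @param x A `score_index_maps` object.
#' @param which `"ncc"` (scores) or `"ind"` (winning template index).
#' @param ... Passed to [graphics::image()].
#' @export
plot.score_index_maps <- function(x, which = c("ncc", "ind"), ...) {
  which <- match.arg(which)
  m <- x[[which]]
  m[!is.finite(m)] <- NA
  graphics::image(t(m)[, nrow(m):1, drop = FALSE], useRaster = TRUE,
                  axes = FALSE, main = paste("global", toupper(which)), ...)
  invisible(x)
}

#' Serialize score/index maps as MRC images plus a JSON sidecar
#'
#' Writes `<prefix>_ncc.mrc` (float32 scores; `-Inf` stored as the smallest
#' finite float), `<prefix>_ind.mrc` (indices as float32 values, exact for
#' any realistic template count) and `<prefix>_maps.json`.
#'
#' @param maps A `score_index_maps`.
#' @param prefix Output path prefix.
#' @return Paths written, invisibly.
#' @export
write_score_maps <- function(maps, prefix) {
  stopifnot(inherits(maps, "score_index_maps"))
  ncc <- maps$ncc
  ncc[!is.finite(ncc)] <- -3e38          # representable in float32
  p1 <- paste0(prefix, "_ncc.mrc"); p2 <- paste0(prefix, "_ind.mrc")
  p3 <- paste0(prefix, "_maps.json")
  write_mrc(ncc, p1)
  write_mrc(maps$ind + 0, p2)
  jsonlite::write_json(
    list(n_templates_merged = maps$n_templates_merged,
         shape = dim(maps$ncc)),
    p3, auto_unbox = TRUE)
  invisible(c(p1, p2, p3))
}
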