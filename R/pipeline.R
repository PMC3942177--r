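## Run orchestration: partitioning, the producer-consumer queue contract,
## and the per-micrograph pick pipeline
## (filter -> shared spectra -> per-template NCC -> partial max/argmax maps
##  -> topology reduction -> peak extraction -> pick files).
##
## "Workers" here are simulated in-process execution units: each worker owns
## a disjoint slice of the workload and produces a partial score/index map;
## the partials are combined by the reduction module. Because the merge
## operator is order-independent (ties resolve to the smaller template
## index), the final maps and picks are bit-identical for any worker count
## and either partition mode — the pipeline's central reproducibility
## contract.

#' Build a run configuration
#'
#' @param micrographs Character vector of micrograph paths, or a list of
#'   [micrograph] objects.
#' @param templates A `template_set`, or a prefix accepted by
#'   [read_template_set()].
#' @param filter_k Pre-filter window (k x k mean filter); 1 disables.
#' @param threshold Peak-calling threshold (sign must match `polarity`).
#' @param polarity `"min"` (default: dark particles, negative peaks) or
#'   `"max"`.
#' @param min_distance Non-maximum-suppression radius in pixels; default
#'   half the template width.
#' @param n_workers Number of simulated workers (>= 1).
#' @param partition_mode `"per_micrograph"` (each worker handles whole
#'   micrographs) or `"per_template"` (workers split the template set for
#'   every micrograph).
#' @param topology Reduction topology, `"direct"` or `"tree"`.
#' @param queue_capacity Bounded queue capacity for the producer-consumer
#'   simulation; default `2 * n_workers`.
#' @param out_dir Output directory for pick files and the run manifest;
#'   `NULL` keeps everything in memory.
#' @param save_maps Also write the global score/index maps as MRC.
#' @param seed RNG seed recorded in the manifest (picking itself is
#'   deterministic).
#' @return An object of class `run_config`.
#' @export
run_config <- function(micrographs, templates, filter_k = 4,
                       threshold = -0.3, polarity = c("min", "max"),
                       min_distance = NULL, n_workers = 1L,
                       partition_mode = c("per_micrograph", "per_template"),
                       topology = c("direct", "tree"),
                       queue_capacity = NULL,
                       out_dir = NULL, save_maps = FALSE, seed = 1L) {
  polarity <- match.arg(polarity)
  partition_mode <- match.arg(partition_mode)
  topology <- match.arg(topology)
  if (n_workers < 1) stop("'n_workers' must be >= 1")
  if (polarity == "min" && threshold >= 0)
    stop("polarity \"min\" requires a negative threshold")
  if (polarity == "max" && threshold <= 0)
    stop("polarity \"max\" requires a positive threshold")
  if (is.character(micrographs)) {
    missing <- micrographs[!file.exists(micrographs)]
    if (length(missing))
      stop("micrograph path(s) not found: ", paste(missing, collapse = ", "))
  }
  if (is.character(templates)) templates <- read_template_set(templates)
  stopifnot(inherits(templates, "template_set"))
  structure(
    list(micrographs = micrographs, templates = templates,
         filter_k = filter_k, threshold = threshold, polarity = polarity,
         min_distance = min_distance, n_workers = as.integer(n_workers),
         partition_mode = partition_mode, topology = topology,
         queue_capacity = if (is.null(queue_capacity)) 2L * as.integer(n_workers)
                          else as.integer(queue_capacity),
         out_dir = out_dir, save_maps = isTRUE(save_maps),
         seed = as.integer(seed)),
    class = "run_config")
}

#' Partition the workload over workers
#'
#' `per_micrograph`: micrographs are dealt round-robin over workers and each
#' worker runs all templates for its micrographs. `per_template`: for every
#' micrograph the template indices are split into `n_workers` contiguous
#' chunks, balanced to within one template, whose union is complete and
#' disjoint.
#'
#' @param n_micrographs,n_templates,n_workers Positive integers.
#' @param mode `"per_micrograph"` or `"per_template"`.
#' @return A data.frame with one row per (micrograph, worker) assignment:
#'   `micrograph`, `worker`, `t_from`, `t_to` (1-based template positions,
#'   `t_to < t_from` for an empty chunk).
#' @examples
#' p <- plan_partition(1, 180, 8, "per_template")
#' p$t_to - p$t_from + 1  # chunk sizes 23,23,23,23,22,22,22,22
#' @export
plan_partition <- function(n_micrographs, n_templates, n_workers,
                           mode = c("per_micrograph", "per_template")) {
  mode <- match.arg(mode)
  if (n_micrographs < 1 || n_templates < 1 || n_workers < 1)
    stop("all counts must be >= 1")
  M <- as.integer(n_micrographs); K <- as.integer(n_templates)
  W <- as.integer(n_workers)
  if (mode == "per_micrograph") {
    data.frame(micrograph = seq_len(M),
               worker = ((seq_len(M) - 1L) %% W) + 1L,
               t_from = 1L, t_to = K)
  } else {
    sizes <- rep(K %/% W, W)
    extra <- K %% W
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    do.call(rbind, lapply(seq_len(M), function(m)
      data.frame(micrograph = m, worker = seq_len(W),
                 t_from = starts, t_to = ends)))
  }
}

#' Simulate the bounded producer-consumer queue
#'
#' One producer enqueues work items (template indices) into a queue of
#' bounded capacity; `n_consumers` consumers take turns removing one item
#' each. The producer only refills when there is room (it "blocks" when the
#' queue is full) and consumers idle when the queue is empty. The
#' deterministic trace lets tests assert the queue contract: every item is
#' consumed exactly once and occupancy never exceeds the capacity.
#'
#' @param n_items Number of work items.
#' @param capacity Queue capacity (>= 1).
#' @param n_consumers Number of consumers (>= 1).
#' @return List with `trace` (data.frame `item`, `consumer`, in consumption
#'   order) and `max_occupancy`.
#' @export
simulate_work_queue <- function(n_items, capacity, n_consumers) {
  if (capacity < 1 || n_consumers < 1 || n_items < 0)
    stop("invalid queue parameters")
  queue <- integer(0)
  next_item <- 1L
  consumed_item <- integer(n_items)
  consumed_by <- integer(n_items)
  n_done <- 0L
  turn <- 0L
  max_occ <- 0L
  while (n_done < n_items) {
    ## producer fills while there is room and work remains
    while (length(queue) < capacity && next_item <= n_items) {
      queue <- c(queue, next_item)
      next_item <- next_item + 1L
    }
    max_occ <- max(max_occ, length(queue))
    if (!length(queue)) break        # consumers idle; nothing left
    consumer <- (turn %% n_consumers) + 1L
    turn <- turn + 1L
    n_done <- n_done + 1L
    consumed_item[n_done] <- queue[1L]
    consumed_by[n_done] <- consumer
    queue <- queue[-1L]
  }
  list(trace = data.frame(item = consumed_item, consumer = consumed_by),
       max_occupancy = max_occ)
}

#' Pick particles in one micrograph
#'
#' The single-micrograph pipeline: optional mean filter, shared spectra,
#' per-template masked NCC on the configured worker partition, partial
#' max/argmax maps per worker, topology reduction, peak extraction.
#'
#' @param mic A [micrograph] (or matrix).
#' @param tset A `template_set`.
#' @param config A [run_config] (its `micrographs` field is ignored here).
#' @param worker_chunks Optional data.frame of `t_from`/`t_to` rows (one per
#'   worker) overriding the per-template split; used by [run_pick()].
#' @return List: `picks`, `maps` (global [score_index_maps]), `fft_count`,
#'   `n_merges`, `n_rounds`.
#' @export
pick_micrograph <- function(mic, tset, config, worker_chunks = NULL) {
  px <- if (inherits(mic, "micrograph")) mic else micrograph(mic)
  fft_count_reset()
  if (config$filter_k > 1) px <- mean_filter(px, config$filter_k)
  K <- length(tset$templates)
  tshape <- dim(tset$templates[[1]]$image)
  spectra <- micrograph_spectra(px, tshape)
  if (is.null(worker_chunks))
    worker_chunks <- data.frame(t_from = 1L, t_to = K)
  ## reduction keeps the strongest score in the picking polarity: for
  ## polarity "min" (dark particles, negative peaks) the per-template maps
  ## are negated before the max/argmax merge and the global map is negated
  ## back, so maps$ncc holds the extremal correlation in the signed domain
  sgn <- if (config$polarity == "min") -1 else 1
  parts <- vector("list", nrow(worker_chunks))
  vshape <- c(nrow(px$pixels) - tshape[1] + 1L,
              ncol(px$pixels) - tshape[2] + 1L)
  for (w in seq_len(nrow(worker_chunks))) {
    acc <- empty_maps(vshape)
    rng <- worker_chunks$t_from[w]:worker_chunks$t_to[w]
    if (worker_chunks$t_to[w] >= worker_chunks$t_from[w])
      for (j in rng) {
        nm <- masked_ncc(spectra, tset$templates[[j]])
        nm$scores <- sgn * nm$scores
        acc <- merge_pair(acc, as_score_index_maps(nm))
      }
    parts[[w]] <- acc
  }
  plan <- reduction_plan(config$topology, length(parts))
  maps <- reduce_maps(parts, plan)
  maps$ncc <- sgn * maps$ncc
  min_dist <- if (is.null(config$min_distance)) tshape[2] %/% 2L
              else config$min_distance
  picks <- extract_peaks(maps, config$threshold, config$polarity,
                         min_distance = min_dist, template_shape = tshape,
                         provenance = tset$provenance,
                         micrograph_id = px$source_id)
  list(picks = picks, maps = maps, fft_count = fft_count(),
       n_merges = attr(maps, "n_merges"), n_rounds = attr(maps, "n_rounds"))
}

#' Run the full picking pipeline over a batch of micrographs
#'
#' Processes every configured micrograph (filter, shared spectra,
#' per-template correlation on the worker partition, reduction, peak
#' extraction) and, when `out_dir` is set, writes per-micrograph pick TSVs,
#' EMAN-style .box files, optional score/index maps, and a JSON run
#' manifest. A micrograph that fails to load is skipped and logged; the run
#' continues and the failure is recorded in the manifest.
#'
#' @param config A [run_config].
#' @param verbose Print one progress line per micrograph.
#' @return An object of class `pick_run`: list with `manifest` (config echo
#'   plus per-micrograph pick counts, FFT counts, merge counts, status) and
#'   `results` (per-micrograph pick data.frames). `all_ok` attribute is TRUE
#'   only if every micrograph processed.
#' @export
run_pick <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  tset <- config$templates
  K <- length(tset$templates)
  mics <- config$micrographs
  M <- length(mics)
  tshape <- dim(tset$templates[[1]]$image)
  for (t in tset$templates)
    if (!all(dim(t$image) == tshape))
      stop("template/mask shape mismatch in the template set")
  part <- plan_partition(M, K, config$n_workers, config$partition_mode)
  if (!is.null(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", M)
  results <- vector("list", M)
  for (i in seq_len(M)) {
    id <- if (is.character(mics)) basename(mics[[i]])
          else if (inherits(mics[[i]], "micrograph")) mics[[i]]$source_id
          else sprintf("micrograph_%03d", i)
    res <- tryCatch({
      mic <- if (is.character(mics))
               read_micrograph(mics[[i]])
             else if (inherits(mics[[i]], "micrograph")) mics[[i]]
             else micrograph(mics[[i]], source_id = id)
      chunks <- if (config$partition_mode == "per_template")
                  part[part$micrograph == i, c("t_from", "t_to")]
                else data.frame(t_from = 1L, t_to = K)
      pick_micrograph(mic, tset, config, worker_chunks = chunks)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (verbose) message(sprintf("[%d/%d] %s: FAILED (%s)",
                                   i, M, id, conditionMessage(res)))
      entries[[i]] <- list(id = id, status = "error",
                           message = conditionMessage(res))
      next
    }
    if (verbose)
      message(sprintf("[%d/%d] %s: %d picks, %d FFTs", i, M, id,
                      nrow(res$picks), res$fft_count))
    if (!is.null(config$out_dir)) {
      stem <- file.path(config$out_dir, tools::file_path_sans_ext(id))
      write_picks_tsv(res$picks, paste0(stem, "_picks.tsv"))
      write_box(res$picks, paste0(stem, ".box"), boxsize = tshape[2])
      if (config$save_maps) write_score_maps(res$maps, stem)
    }
    entries[[i]] <- list(id = id, status = "ok", n_picks = nrow(res$picks),
                         fft_count = res$fft_count,
                         n_merges = res$n_merges, n_rounds = res$n_rounds)
    results[[i]] <- res$picks
  }
  manifest <- list(
    config = list(
      n_micrographs = M, n_templates = K, filter_k = config$filter_k,
      threshold = config$threshold, polarity = config$polarity,
      n_workers = config$n_workers, partition_mode = config$partition_mode,
      topology = config$topology, seed = config$seed,
      template_shape = tshape),
    micrographs = entries,
    n_failed = sum(vapply(entries, function(e) e$status != "ok", logical(1))))
  if (!is.null(config$out_dir))
    jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(manifest = manifest, results = results),
            class = "pick_run",
            all_ok = manifest$n_failed == 0L)
}

#' @export
print.pick_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<pick_run> %d micrograph(s), %d template(s), %s/%s, %d worker(s)\n",
              m$config$n_micrographs, m$config$n_templates,
              m$config$partition_mode, m$config$topology,
              m$config$n_workers))
  for (e in m$micrographs)
    cat(sprintf("  %s: %s%s\n", e$id, e$status,
                if (identical(e$status, "ok"))
                  sprintf(", %d picks, %d FFTs", e$n_picks, e$fft_count)
                else paste0(" (", e$message, ")")))
  invisible(x)
}

#' @export
summary.pick_run <- function(object, ...) {
  ok <- vapply(object$manifest$micrographs, function(e)
    identical(e$status, "ok"), logical(1))
  cat(sprintf("pick_run: %d/%d micrographs ok, %d picks total\n",
              sum(ok), length(ok),
              sum(vapply(object$results[ok], NROW, integer(1)))))
  invisible(object)
}
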