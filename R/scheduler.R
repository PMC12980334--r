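#' Run configuration for whole-genome alignment
#'
#' Bundles all pipeline parameters. Results are identical for every
#' `workers` and `batch_bases` value; those settings trade memory and
#' wall-clock time only.
#'
#' @param workers Worker count (default 1).
#' @param seed RNG seed for any randomized component (default 11; the
#'   pipeline itself is deterministic).
#' @param index An [index_params()] object.
#' @param chain A [chain_params()] object.
#' @param align An [align_params()] object.
#' @param mask_level Overlap-fraction threshold for secondary marking
#'   (default 0.5).
#' @param no_secondary Drop secondary records from the output (default
#'   FALSE).
#' @param batch_bases Cap on total query bases per batch (default 5e8).
#' @return An object of class `run_config`.
#' @export
run_config <- function(workers = 1L, seed = 11L, index = index_params(),
                       chain = chain_params(), align = align_params(),
                       mask_level = 0.5, no_secondary = FALSE,
                       batch_bases = 5e8) {
  workers <- as.integer(workers)
  if (workers < 1) abort("workers must be >= 1")
  structure(list(workers = workers, seed = as.integer(seed), index = index,
                 chain = chain, align = align, mask_level = mask_level,
                 no_secondary = no_secondary, batch_bases = batch_bases),
            class = "run_config")
}

#' Plan query batches
#'
#' Greedy in input order: the current batch is extended while its total
#' bases stay within `batch_bases`; a single sequence larger than the cap
#' forms its own batch. Batches partition the query indices preserving
#' input order. Batching bounds memory; it never changes results.
#'
#' @param queries Query genome tibble.
#' @param batch_bases Per-batch base cap.
#' @return A list of integer index vectors, one per batch.
#' @export
plan_batches <- function(queries, batch_bases) {
  n <- nrow(queries)
  if (n == 0) return(list())
  batches <- list()
  cur <- integer(0); cur_bases <- 0
  for (i in seq_len(n)) {
    li <- queries$length[i]
    if (length(cur) > 0 && cur_bases + li > batch_bases) {
      batches[[length(batches) + 1L]] <- cur
      cur <- integer(0); cur_bases <- 0
    }
    cur <- c(cur, i); cur_bases <- cur_bases + li
    if (cur_bases > batch_bases) {       # oversize singleton
      batches[[length(batches) + 1L]] <- cur
      cur <- integer(0); cur_bases <- 0
    }
  }
  if (length(cur) > 0) batches[[length(batches) + 1L]] <- cur
  batches
}

#' Deterministic worker pool
#'
#' Dispatches tasks to workers largest-first (longest-processing-time
#' static assignment over `workers` forked processes) and reassembles the
#' results in original task order regardless of completion order, so the
#' result is identical to a sequential `lapply` for every worker count.
#' `worker_fn` must be pure (no shared mutable state); workers communicate
#' with the parent only by returning values.
#'
#' @param tasks List of work units.
#' @param worker_fn Function applied to each task.
#' @param workers Worker count (>= 1).
#' @param sizes Numeric size hints, one per task (default: equal sizes).
#' @return A list of results in task order.
#' @export
run_pool <- function(tasks, worker_fn, workers = 1L, sizes = NULL) {
  workers <- as.integer(workers)
  if (workers < 1) abort("workers must be >= 1")
  nt <- length(tasks)
  if (nt == 0) return(list())
  sizes <- sizes %||% rep(1, nt)
  disp <- order(-as.numeric(sizes), seq_len(nt), method = "radix")
  if (workers == 1L || nt == 1L) {
    out <- vector("list", nt)
    for (i in disp) {
      out[[i]] <- tryCatch(worker_fn(tasks[[i]]), error = function(e) {
        abort(sprintf("worker failure on task %d: %s", i, conditionMessage(e)),
              class = "seedchain_worker_error")
      })
    }
    return(out)
  }
  # LPT static assignment: largest task to the least-loaded worker bin
  load <- numeric(workers)
  bins <- vector("list", workers)
  for (i in disp) {
    b <- which.min(load)
    bins[[b]] <- c(bins[[b]], i)
    load[b] <- load[b] + sizes[i]
  }
  bins <- bins[lengths(bins) > 0]
  res <- parallel::mclapply(bins, function(idx) {
    lapply(idx, function(i) tryCatch(list(ok = TRUE, value = worker_fn(tasks[[i]])),
                                     error = function(e) list(ok = FALSE, msg = conditionMessage(e), task = i)))
  }, mc.cores = workers, mc.preschedule = FALSE)
  out <- vector("list", nt)
  for (b in seq_along(bins)) {
    rb <- res[[b]]
    if (inherits(rb, "try-error")) {
      abort(sprintf("worker failure: %s", as.character(rb)),
            class = "seedchain_worker_error")
    }
    for (j in seq_along(bins[[b]])) {
      r <- rb[[j]]
      if (!r$ok) {
        abort(sprintf("worker failure on task %d: %s", r$task, r$msg),
              class = "seedchain_worker_error")
      }
      out[[bins[[b]][j]]] <- r$value
    }
  }
  out
}

# run the full per-query pipeline given precomputed per-partition chains
finish_query <- function(query, chains, index, config) {
  if (nrow(chains) == 0) return(paf_tibble())
  chains <- sort_chains(chains)
  chains$flag <- mark_primary_fast(chains, config$mask_level)
  if (config$no_secondary) chains <- chains[chains$flag == "P", , drop = FALSE]
  if (nrow(chains) == 0) return(paf_tibble())
  records <- dplyr::bind_rows(lapply(seq_len(nrow(chains)), function(i) {
    extend_chain(chains[i, , drop = FALSE], query,
                 index$seqs[chains$seqid[i], , drop = FALSE], config$align)
  }))
  # mapq: per primary, the best secondary score among secondaries whose
  # query interval overlaps it above mask_level; secondaries get 0
  prim <- which(chains$flag == "P")
  sec <- which(chains$flag == "S")
  mapq <- integer(nrow(chains))
  for (i in prim) {
    comp <- sec[overlap_fraction(chains$qs[sec], chains$qe[sec],
                                 chains$qs[i], chains$qe[i]) > config$mask_level]
    best <- if (length(comp) > 0) max(chains$score[comp]) else NULL
    mapq[i] <- compute_mapq(chains$score[i], best)
  }
  records$mapq <- mapq
  records
}

#' Align a query genome to a reference genome
#'
#' Runs the full seed-chain-extend pipeline: the reference is indexed once;
#' query sequences are processed in batches; within a batch the unit of
#' parallel work is a (query sequence, anchor partition) pair, pooled
#' across all sequences of the batch and dispatched largest-first, so
#' chaining of a single long query sequence spreads over many workers.
#' Marking and extension run per query. Records are emitted grouped by
#' query in input order and, within a query, in descending chain-score
#' order with the fixed tie-break. Output is byte-identical for every
#' `workers` and `batch_bases` value.
#'
#' @param ref,query Paths to FASTA files (plain or gzip), or genome tibbles
#'   as returned by [read_fasta()].
#' @param config A [run_config()] object.
#' @return A PAF tibble of class `genome_alignment`.
#' @export
align_genomes <- function(ref, query, config = run_config()) {
  if (!is.data.frame(ref)) ref <- read_fasta(ref)
  if (!is.data.frame(query)) query <- read_fasta(query)
  index <- build_index(ref, config$index)
  batches <- plan_batches(query, config$batch_bases)
  out <- list()
  for (batch in batches) {
    # seed every query of the batch, then pool (query, partition) tasks
    parts <- list(); owner <- integer(0); sizes <- numeric(0)
    for (qi in batch) {
      anchors <- collect_anchors(query[qi, , drop = FALSE], index,
                                 workers = config$workers)
      p <- partition_anchors(anchors, index$n_seqs)
      if (nrow(p) > 0) {
        parts <- c(parts, p$anchors)
        owner <- c(owner, rep(qi, nrow(p)))
        sizes <- c(sizes, p$n)
      }
    }
    chain_res <- run_pool(parts, function(p) chain_partition(p, config$chain),
                          workers = config$workers, sizes = sizes)
    for (qi in batch) {
      mine <- which(owner == qi)
      chains <- if (length(mine) > 0) dplyr::bind_rows(chain_res[mine])
      else empty_chains()
      out[[length(out) + 1L]] <- finish_query(query[qi, , drop = FALSE],
                                              chains, index, config)
    }
  }
  records <- if (length(out) > 0) dplyr::bind_rows(out) else paf_tibble()
  class(records) <- c("genome_alignment", class(records))
  records
}
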