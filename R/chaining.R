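#' Chaining parameters
#'
#' @param max_gap Maximum query/target gap (bases) between chainable anchors
#'   (default 5000).
#' @param max_skew_bandwidth Maximum `|dq - dt|` between chainable anchors
#'   (default 500).
#' @param min_chain_score Minimum chain score to report (default 40).
#' @param min_anchors Minimum anchors per reported chain (default 3).
#' @param gap_open_scale Linear gap-penalty coefficient (default 0.01).
#' @param lookback Maximum number of predecessor candidates examined per
#'   anchor in the DP (default 50).
#' @return An object of class `chain_params`.
#' @export
chain_params <- function(max_gap = 5000, max_skew_bandwidth = 500,
                         min_chain_score = 40, min_anchors = 3L,
                         gap_open_scale = 0.01, lookback = 50L) {
  p <- list(max_gap = max_gap, max_skew_bandwidth = max_skew_bandwidth,
            min_chain_score = min_chain_score,
            min_anchors = as.integer(min_anchors),
            gap_open_scale = gap_open_scale, lookback = as.integer(lookback))
  if (any(unlist(p) <= 0)) abort("all chaining parameters must be positive")
  structure(p, class = "chain_params")
}

empty_chains <- function() {
  tibble(seqid = integer(), strand = integer(), score = numeric(),
         qs = integer(), qe = integer(), ts = integer(), te = integer(),
         n_anchors = integer(), flag = character(), anchors = list())
}

anchors_sorted <- function(anchors) {
  ord <- order(anchors$seqid, anchors$strand, anchors$tpos, anchors$qpos,
               method = "radix")
  identical(ord, seq_len(nrow(anchors)))
}

#' Partition sorted anchors by (reference sequence, strand)
#'
#' Anchors from two different reference sequences (or opposite strands)
#' can never belong to the same chain, so partitions can be chained
#' independently — and in parallel — without altering the chaining output.
#' There are at most `2 * n_seqs` non-empty partitions.
#'
#' @param anchors Anchor tibble sorted by `(seqid, strand, tpos, qpos)` (as
#'   produced by [collect_anchors()]). Unsorted input is an error.
#' @param n_seqs Number of reference sequences.
#' @return A tibble with one row per non-empty partition: `seqid`, `strand`,
#'   `n` (anchor count) and `anchors` (list-column of anchor tibbles).
#'   Concatenating the partitions in row order reproduces the input.
#' @export
partition_anchors <- function(anchors, n_seqs) {
  if (nrow(anchors) == 0) {
    return(tibble(seqid = integer(), strand = integer(), n = integer(),
                  anchors = list()))
  }
  if (!anchors_sorted(anchors)) {
    abort("anchors must be sorted by (seqid, strand, tpos, qpos)",
          class = "seedchain_precondition_error")
  }
  grp <- anchors$seqid * 2L + anchors$strand
  runs <- rle(grp)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- tibble(
    seqid = anchors$seqid[starts],
    strand = anchors$strand[starts],
    n = runs$lengths,
    anchors = lapply(seq_along(starts),
                     function(i) anchors[starts[i]:ends[i], , drop = FALSE]))
  stopifnot(nrow(out) <= 2L * n_seqs)
  out
}

#' Gap cost between two anchors
#'
#' For anchors in the same partition, with `dt = cur.tpos - prev.tpos` and
#' `dq` the query advance in the direction given by the strand, the pair is
#' infeasible (cost `Inf`) when `dt <= 0`, `dq <= 0`, either exceeds
#' `max_gap`, or `|dq - dt|` exceeds `max_skew_bandwidth`. Otherwise the
#' cost is `gap_open_scale * span * g + 0.5 * log2(g + 1)` with
#' `g = |dq - dt|` (0 for perfectly co-linear anchors).
#'
#' @param prev,cur Anchors: lists or one-row tibbles with `qpos`, `tpos`,
#'   `span`, `strand`.
#' @param params A [chain_params()] object.
#' @return The gap cost, or `Inf` if the pair is infeasible.
#' @export
gap_cost <- function(prev, cur, params = chain_params()) {
  dt <- cur$tpos - prev$tpos
  dq <- if (cur$strand == 0) cur$qpos - prev$qpos else prev$qpos - cur$qpos
  if (dt <= 0 || dq <= 0 || dq > params$max_gap || dt > params$max_gap) {
    return(Inf)
  }
  g <- abs(dq - dt)
  if (g > params$max_skew_bandwidth) return(Inf)
  params$gap_open_scale * cur$span * g + 0.5 * log2(g + 1)
}

# extract chains best-first from DP scores/predecessors; anchors may join at
# most one chain; chains below score/size thresholds consume their anchors
# but are not reported
extract_chains <- function(anchors, f, pred, params) {
  n <- length(f)
  ord <- order(-f, seq_len(n), method = "radix")
  used <- logical(n)
  buf <- integer(n)
  out <- list()
  for (i in ord) {
    if (used[i]) next
    m <- 0L
    j <- i
    while (j > 0L && !used[j]) {
      m <- m + 1L
      buf[m] <- j
      used[j] <- TRUE
      j <- pred[j]
    }
    idx <- rev(buf[seq_len(m)])
    if (f[i] >= params$min_chain_score && m >= params$min_anchors) {
      a <- anchors[idx, , drop = FALSE]
      out[[length(out) + 1L]] <- tibble(
        seqid = a$seqid[1], strand = a$strand[1], score = f[i],
        qs = min(a$qpos), qe = max(a$qpos + a$span),
        ts = a$tpos[1], te = a$tpos[m] + a$span[m],
        n_anchors = m, flag = "U", anchors = list(a))
    }
  }
  if (length(out) == 0) empty_chains() else dplyr::bind_rows(out)
}

#' Chain the anchors of one partition
#'
#' Dynamic programming over anchors in `(tpos, qpos)` order:
#' `f(i) = max(span_i, max_j f(j) + min(dq, dt, span_i) - gap_cost(j, i))`
#' with `j` restricted to the last `lookback` candidates. Predecessor ties
#' go to the largest `j` (the closest predecessor); a tie with the
#' single-anchor base score keeps the base. Chains are then extracted
#' best-first: repeatedly take the unused anchor with maximal `f`, backtrack
#' through unused anchors, and mark all members used. Chains with
#' `score >= min_chain_score` and at least `min_anchors` anchors are
#' reported; each anchor belongs to at most one chain.
#'
#' @param partition Anchor tibble of a single `(seqid, strand)` partition,
#'   sorted by `(tpos, qpos)`.
#' @param params A [chain_params()] object.
#' @return A chain tibble: `seqid`, `strand`, `score`, query interval
#'   `qs`/`qe`, target interval `ts`/`te`, `n_anchors`, `flag` (`"U"`,
#'   unset), and `anchors` (list-column of anchor tibbles).
#' @export
chain_partition <- function(partition, params = chain_params()) {
  if (nrow(partition) == 0) return(empty_chains())
  dp <- chain_dp_cpp(partition$qpos, partition$tpos, partition$span,
                     partition$strand[1], params$max_gap,
                     params$max_skew_bandwidth, params$gap_open_scale,
                     params$lookback)
  extract_chains(partition, dp$f, dp$pred, params)
}

#' Chain all anchors, partition-parallel
#'
#' Partitions the sorted anchor array by (reference sequence, strand),
#' chains every partition independently (dispatched to workers
#' largest-first), and merges the per-partition chains into a single list
#' sorted by descending score with the fixed tie-break ascending
#' `(qs, seqid, ts, strand)`. The result is identical for every `workers`
#' value and identical to the sequential (`workers = 1`) run.
#'
#' @param anchors Anchor tibble sorted by `(seqid, strand, tpos, qpos)`.
#' @param n_seqs Number of reference sequences.
#' @param params A [chain_params()] object.
#' @param workers Worker count (default 1).
#' @return A chain tibble (see [chain_partition()]).
#' @export
chain_all <- function(anchors, n_seqs, params = chain_params(), workers = 1L) {
  parts <- partition_anchors(anchors, n_seqs)
  if (nrow(parts) == 0) return(empty_chains())
  res <- run_pool(parts$anchors, function(p) chain_partition(p, params),
                  workers = workers, sizes = parts$n)
  chains <- dplyr::bind_rows(res)
  sort_chains(chains)
}

# fixed deterministic chain order: descending score, then ascending
# (qs, seqid, ts, strand); dplyr::arrange is stable
sort_chains <- function(chains) {
  dplyr::arrange(chains, dplyr::desc(.data$score), .data$qs, .data$seqid,
                 .data$ts, .data$strand)
}
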