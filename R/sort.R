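#' Stable parallel sort
#'
#' Chunked sort with stable pairwise merging: the input is split into
#' contiguous chunks (one per worker), each chunk is sorted with a stable
#' radix sort (in parallel via forked workers when `workers > 1`), and the
#' sorted runs are merged with a stable k-way merge in which key ties keep
#' the element from the earlier chunk. The output is element-for-element
#' identical to a sequential stable sort — relative order of key ties is
#' input order — for every `workers` value.
#'
#' @param x A data frame to sort, or an atomic vector.
#' @param keys For a data frame: character vector of key column names, in
#'   lexicographic priority order. Ignored for vectors (the vector itself is
#'   the key).
#' @param workers Number of chunks/workers (>= 1).
#' @return `x` sorted stably by the keys.
#' @export
#' @examples
#' df <- data.frame(k = c(2, 1, 2, 1), payload = 1:4)
#' stable_parallel_sort(df, "k", workers = 2)
stable_parallel_sort <- function(x, keys = NULL, workers = 1L) {
  workers <- as.integer(workers)
  if (workers < 1) abort("workers must be >= 1")
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  if (n <= 1) return(x)
  keycols <- if (is.data.frame(x)) {
    if (is.null(keys)) abort("keys must name the sort columns for a data frame")
    lapply(x[keys], xtfrm)
  } else {
    list(xtfrm(x))
  }
  keymat <- do.call(cbind, lapply(keycols, as.numeric))

  nchunk <- min(workers, n)
  bounds <- floor(seq(0, n, length.out = nchunk + 1))
  chunk_idx <- lapply(seq_len(nchunk), function(i) (bounds[i] + 1):bounds[i + 1])
  sort_chunk <- function(idx) {
    local <- do.call(order, c(lapply(keycols, function(k) k[idx]),
                              list(method = "radix")))
    idx[local]
  }
  runs <- if (workers > 1 && nchunk > 1) {
    res <- parallel::mclapply(chunk_idx, sort_chunk, mc.cores = workers,
                              mc.preschedule = TRUE)
    err <- vapply(res, inherits, logical(1), "try-error")
    if (any(err)) abort("worker failure in stable_parallel_sort")
    res
  } else {
    lapply(chunk_idx, sort_chunk)
  }
  perm <- merge_sorted_runs_cpp(keymat, unlist(runs), lengths(runs))
  if (is.data.frame(x)) x[perm, , drop = FALSE] else x[perm]
}
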