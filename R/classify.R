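#' Overlap fraction of two query intervals
#'
#' The ratio of the overlap length, `max(0, min(e1, e2) - max(s1, s2))`, to
#' the length of the shorter interval, `min(e1 - s1, e2 - s2)`. Intervals
#' are half-open, so adjacent intervals have fraction 0; a contained
#' interval has fraction 1.
#'
#' @param s1,e1,s2,e2 Interval endpoints (vectorized).
#' @return Numeric overlap fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' overlap_fraction(0, 100, 50, 150)  # 0.5
#' overlap_fraction(0, 100, 20, 40)   # 1 (containment)
overlap_fraction <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2)) / pmin(e1 - s1, e2 - s2)
}

#' Interval tree for query-interval stabbing queries
#'
#' An augmented balanced search tree (treap keyed by interval start, with
#' max-end augmentation) supporting insertion in O(log m) and retrieval of
#' all stored intervals overlapping a half-open query interval in
#' O(log m + k).
#'
#' @return An empty `interval_tree` object.
#' @export
interval_tree <- function() {
  structure(list(ptr = it_new_cpp()), class = "interval_tree")
}

#' @export
print.interval_tree <- function(x, ...) {
  cat("<interval_tree:", it_size_cpp(x$ptr), "intervals>\n")
  invisible(x)
}

#' Insert intervals into an interval tree
#'
#' @param tree An [interval_tree()].
#' @param s,e Half-open interval endpoints (`s < e`), vectorized.
#' @param payload Integer payload per interval (e.g. a chain index).
#' @return The tree, invisibly (insertion is by reference).
#' @export
it_insert <- function(tree, s, e, payload = seq_along(s)) {
  if (any(s >= e)) abort("intervals must satisfy s < e")
  it_insert_cpp(tree$ptr, as.integer(s), as.integer(e), as.integer(payload))
  invisible(tree)
}

#' Query all intervals overlapping `[s, e)`
#'
#' @param tree An [interval_tree()].
#' @param s,e Query interval, `s < e` (half-open).
#' @return A tibble of the stored intervals with positive overlap against
#'   `[s, e)`: columns `s`, `e`, `payload`. Row order is unspecified.
#' @export
it_query <- function(tree, s, e) {
  if (s >= e) abort("invalid query: s must be < e",
                    class = "seedchain_invalid_query")
  res <- it_query_cpp(tree$ptr, as.integer(s), as.integer(e))
  tibble(s = res$s, e = res$e, payload = res$payload)
}

check_score_sorted <- function(chains) {
  if (is.unsorted(-chains$score)) {
    abort("chains must be sorted by descending score",
          class = "seedchain_precondition_error")
  }
}

#' Mark chains primary/secondary — quadratic reference algorithm
#'
#' The highest-scoring chain is primary and enters the primary set Q. Each
#' subsequent chain is secondary if some chain already in Q has a
#' query-interval overlap fraction strictly above `mask_level` with it;
#' otherwise it is primary and joins Q. Each step scans Q linearly, so the
#' algorithm is O(n^2) in the worst case.
#'
#' @param chains Chain tibble sorted by descending score (the fixed order
#'   produced by [chain_all()]). Unsorted input is an error.
#' @param mask_level Overlap-fraction threshold (default 0.5; "above" is
#'   strict, so a fraction of exactly `mask_level` does not mask).
#' @return Character vector of flags in input order: `"P"` or `"S"`.
#' @export
mark_primary_quadratic <- function(chains, mask_level = 0.5) {
  n <- nrow(chains)
  if (n == 0) return(character())
  check_score_sorted(chains)
  flags <- character(n)
  qs <- chains$qs; qe <- chains$qe
  Qs <- numeric(0); Qe <- numeric(0)
  for (i in seq_len(n)) {
    sec <- length(Qs) > 0 &&
      any(overlap_fraction(Qs, Qe, qs[i], qe[i]) > mask_level)
    if (sec) {
      flags[i] <- "S"
    } else {
      flags[i] <- "P"
      Qs <- c(Qs, qs[i]); Qe <- c(Qe, qe[i])
    }
  }
  flags
}

#' Mark chains primary/secondary — interval-tree algorithm
#'
#' Same marking semantics as [mark_primary_quadratic()] — the flags are
#' identical on every input — but the primary set Q is kept in an interval
#' tree: each chain queries the tree for overlapping primary intervals and
#' applies the overlap-fraction test only to those candidates, taking
#' O(log |Q| + k) per chain instead of a linear scan.
#'
#' @inheritParams mark_primary_quadratic
#' @return Character vector of flags in input order: `"P"` or `"S"`.
#' @export
mark_primary_fast <- function(chains, mask_level = 0.5) {
  n <- nrow(chains)
  if (n == 0) return(character())
  check_score_sorted(chains)
  flags <- character(n)
  qs <- as.integer(chains$qs); qe <- as.integer(chains$qe)
  tree <- it_new_cpp()
  for (i in seq_len(n)) {
    cand <- it_query_cpp(tree, qs[i], qe[i])
    sec <- length(cand$s) > 0 &&
      any(overlap_fraction(cand$s, cand$e, qs[i], qe[i]) > mask_level)
    if (sec) {
      flags[i] <- "S"
    } else {
      flags[i] <- "P"
      it_insert_cpp(tree, qs[i], qe[i], i)
    }
  }
  flags
}
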