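#' Minimizer index parameters
#'
#' @param k k-mer length (1–28, default 15).
#' @param w Minimizer window: number of consecutive k-mer starts per window
#'   (default 10).
#' @param max_occ Occurrence cutoff: keys occurring more than this many times
#'   across the reference are dropped from the index entirely (default 100).
#' @return An object of class `index_params`.
#' @export
index_params <- function(k = 15L, w = 10L, max_occ = 100L) {
  k <- as.integer(k); w <- as.integer(w); max_occ <- as.integer(max_occ)
  if (k < 1 || k > 28) abort("k must be in [1, 28]")
  if (w < 1) abort("w must be >= 1")
  if (max_occ < 1) abort("max_occ must be >= 1")
  structure(list(k = k, w = w, max_occ = max_occ), class = "index_params")
}

#' Canonical k-mer key
#'
#' Hashes the forward and reverse-complement 2-bit encodings of a k-mer with
#' a fixed integer mixing hash and returns the smaller of the two, together
#' with which orientation produced it. Palindromic k-mers (equal hashes) get
#' strand 0. Windows containing `N` have no key.
#'
#' @param window A k-length DNA string.
#' @return `NULL` if the window contains `N`; otherwise a list with `key`
#'   (numeric, an exact 52-bit integer) and `strand` (0 forward-canonical,
#'   1 reverse-canonical).
#' @export
canonical_kmer <- function(window) {
  canonical_kmer_cpp(window)
}

#' Compute closed-window minimizers of a sequence
#'
#' For every window of `w` consecutive k-mer start positions wholly inside
#' the sequence, the position(s) achieving the minimum canonical key among
#' N-free k-mers are selected; duplicates across overlapping windows are
#' removed. Sequences shorter than `k + w - 1` use a single window over
#' whatever full k-mers exist. A window with no valid k-mer emits nothing.
#'
#' @param seq A DNA string.
#' @param params An [index_params()] object.
#' @return A tibble sorted by `pos` with columns `key` (numeric), `pos`
#'   (0-based k-mer start, integer) and `strand` (0/1).
#' @export
minimizers <- function(seq, params = index_params()) {
  res <- minimizers_cpp(seq, params$k, params$w)
  tibble(key = res$key, pos = res$pos, strand = res$strand)
}

#' Build a minimizer index over a reference genome
#'
#' @param ref A genome tibble (columns `name`, `seq`, `length`), e.g. from
#'   [read_fasta()].
#' @param params An [index_params()] object.
#' @return An object of class `minimizer_index`: a list with `params`, the
#'   reference tibble `seqs`, the number of reference sequences `n_seqs`,
#'   and `table`, a tibble of postings (`key`, `seqid`, `tpos`, `strand`)
#'   sorted by `(key, seqid, tpos)`. `seqid` is the 1-based index into
#'   `seqs`. Keys whose total occurrence count exceeds `max_occ` are
#'   removed.
#' @export
build_index <- function(ref, params = index_params()) {
  if (!is.data.frame(ref) || nrow(ref) == 0 || any(!nzchar(ref$seq))) {
    abort("reference must contain at least one non-empty sequence",
          class = "seedchain_invalid_input")
  }
  per_seq <- lapply(seq_len(nrow(ref)), function(i) {
    m <- minimizers_cpp(ref$seq[i], params$k, params$w)
    tibble(key = m$key, seqid = i, tpos = m$pos, strand = m$strand)
  })
  table <- dplyr::bind_rows(per_seq)
  if (nrow(table) > 0) {
    counts <- table(table$key)
    drop_keys <- as.numeric(names(counts)[counts > params$max_occ])
    if (length(drop_keys) > 0) table <- table[!(table$key %in% drop_keys), ]
    table <- table[order(table$key, table$seqid, table$tpos, method = "radix"), ]
  }
  structure(list(params = params, seqs = ref, n_seqs = nrow(ref), table = table),
            class = "minimizer_index")
}

#' Collect anchors between one query sequence and an indexed reference
#'
#' Each query minimizer whose key is present in the index yields one anchor
#' per posting. The anchor strand is the XOR of the query-minimizer strand
#' and the target-occurrence strand (0 = same strand, 1 = opposite). The
#' result is stably sorted by `(seqid, strand, tpos, qpos)` so that
#' partitions form contiguous runs.
#'
#' @param query A one-row genome tibble (or a list with `name` and `seq`).
#' @param index A [build_index()] result built with the same parameters.
#' @param workers Worker count for the stable parallel sort (default 1).
#' @return A tibble of anchors with columns `qpos`, `seqid`, `tpos`,
#'   `strand`, `span` (= k). Coordinates are 0-based.
#' @export
collect_anchors <- function(query, index, workers = 1L) {
  qm <- minimizers(query$seq[[1]], index$params)
  empty <- tibble(qpos = integer(), seqid = integer(), tpos = integer(),
                  strand = integer(), span = integer())
  if (nrow(qm) == 0 || nrow(index$table) == 0) return(empty)
  hits <- dplyr::inner_join(
    dplyr::rename(qm, qpos = "pos", qstrand = "strand"),
    index$table, by = "key", relationship = "many-to-many")
  if (nrow(hits) == 0) return(empty)
  anchors <- tibble(qpos = hits$qpos, seqid = hits$seqid, tpos = hits$tpos,
                    strand = bitwXor(hits$qstrand, hits$strand),
                    span = index$params$k)
  stable_parallel_sort(anchors, c("seqid", "strand", "tpos", "qpos"),
                       workers = workers)
}
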