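#' Base-level alignment parameters
#'
#' Affine-gap scoring: a gap of length `len` costs
#' `gap_open + gap_extend * len`.
#'
#' @param match Match reward (default 2).
#' @param mismatch Mismatch penalty, applied as its negative (default 4).
#' @param gap_open Gap-open penalty (default 4).
#' @param gap_extend Per-base gap-extension penalty (default 2).
#' @param band Maximum DP band half-width (default 500).
#' @return An object of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = 4, gap_open = 4,
                         gap_extend = 2, band = 500L) {
  p <- list(match = match, mismatch = mismatch, gap_open = gap_open,
            gap_extend = gap_extend, band = as.integer(band))
  if (any(unlist(p) < 0) || p$band < 1) abort("invalid alignment parameters")
  structure(p, class = "align_params")
}

op_chars <- c("M", "I", "D")

#' Affine-gap global alignment (Gotoh)
#'
#' Optimal global alignment of `a` (query side) against `b` (target side)
#' under match/mismatch scoring with affine gaps, computed by a banded
#' three-state DP. Traceback is deterministic with tie order
#' diagonal > deletion > insertion. CIGAR ops: `M` consumes both sequences,
#' `I` consumes the query, `D` consumes the target.
#'
#' @param a,b DNA strings (either may be empty).
#' @param params An [align_params()] object.
#' @return A list with `score` (numeric) and `cigar`, a tibble of run-length
#'   encoded operations (`op`, `len`) with adjacent ops distinct.
#' @export
#' @examples
#' affine_align("ACGT", "ACGT")$score  # 8
affine_align <- function(a, b, params = align_params()) {
  if (abs(nchar(a) - nchar(b)) > params$band) {
    abort("length difference exceeds the band",
          class = "seedchain_banded_infeasible")
  }
  res <- affine_align_cpp(a, b, params$match, params$mismatch,
                          params$gap_open, params$gap_extend, params$band)
  list(score = res$score,
       cigar = tibble(op = op_chars[res$ops + 1L], len = res$lens))
}

#' Mapping quality rule
#'
#' `60` when a primary alignment has no competing secondary; otherwise
#' `round(60 * (1 - s2/s1))` clamped to `[0, 60]`. Secondary records always
#' receive mapq 0 (applied by the caller).
#'
#' @param primary_score Score of the primary chain (nonnegative).
#' @param best_secondary_score Best competing secondary score, or `NULL`.
#' @return Integer mapq in `[0, 60]`.
#' @export
compute_mapq <- function(primary_score, best_secondary_score = NULL) {
  if (is.null(best_secondary_score)) return(60L)
  as.integer(max(0, min(60, round(60 * (1 - best_secondary_score / primary_score)))))
}

# merge adjacent equal ops of a run-length encoded cigar
merge_cigar <- function(ops, lens) {
  keep <- lens > 0L
  ops <- ops[keep]; lens <- lens[keep]
  if (length(ops) == 0) return(list(op = character(), len = integer()))
  r <- rle(ops)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  list(op = r$values,
       len = vapply(seq_along(starts),
                    function(i) sum(lens[starts[i]:ends[i]]), integer(1)))
}

cigar_string <- function(op, len) paste0(paste0(len, op), collapse = "")

#' Extend one chain into a base-level PAF record
#'
#' The CIGAR is the concatenation, along the chain, of k-length `M` runs
#' for anchors and affine-gap alignments of the inter-anchor gap sequences.
#' Consecutive anchors overlapping on query or target have the later
#' anchor's `M` run shortened by the larger of the two overlaps; anchors
#' trimmed to nothing are dropped. For reverse-strand chains the query is
#' reverse-complemented once and anchor coordinates mapped so anchors are
#' co-linear; the record's query interval is reported in original query
#' orientation. Gap pairs whose length difference exceeds the band are
#' emitted as a `D` block then an `I` block. No extension occurs beyond the
#' chain's terminal anchors.
#'
#' @param chain A one-row chain tibble (from [chain_all()]), with its flag
#'   set by marking.
#' @param query,ref One-row genome tibbles for the query sequence and the
#'   chain's target reference sequence.
#' @param params An [align_params()] object.
#' @param mapq Mapping quality to record (default 0; set by the caller).
#' @return A one-row PAF tibble with tags `tp:A:`, `cm:i:` (anchor count),
#'   `s1:i:` (floored chain score) and `cg:Z:` (CIGAR, ops M/I/D).
#' @export
extend_chain <- function(chain, query, ref, params = align_params(),
                         mapq = 0L) {
  a <- chain$anchors[[1]]
  strand <- chain$strand[1]
  qlen <- nchar(query$seq[[1]])
  tlen <- nchar(ref$seq[[1]])
  wq <- if (strand == 1L) revcomp_cpp(query$seq[[1]]) else query$seq[[1]]
  # anchor query starts in working (aligned) orientation
  q <- if (strand == 1L) qlen - a$qpos - a$span else a$qpos
  t <- a$tpos
  s <- a$span
  n <- length(q)
  # verify anchors are exact matches after orientation mapping
  if (!identical(substring(wq, q + 1L, q + s),
                 substring(ref$seq[[1]], t + 1L, t + s))) {
    abort(sprintf("anchor inconsistent with sequences in chain on '%s'",
                  ref$name[[1]]),
          class = "seedchain_internal_error")
  }

  pieces <- vector("list", n)            # per-anchor cigar fragments
  prev_q <- q[1]; prev_t <- t[1]
  for (i in seq_len(n)) {
    oq <- max(0L, prev_q - q[i])
    ot <- max(0L, prev_t - t[i])
    trim <- if (i == 1L) 0L else max(oq, ot)
    if (s[i] - trim <= 0L) next          # anchor fully absorbed: drop
    gq <- q[i] + trim - prev_q
    gt <- t[i] + trim - prev_t
    frag_op <- character(0); frag_len <- integer(0)
    if (gq > 0L && gt > 0L) {
      if (abs(gq - gt) > params$band) {
        frag_op <- c("D", "I"); frag_len <- c(gt, gq)
      } else {
        sub <- affine_align_cpp(substring(wq, prev_q + 1L, q[i] + trim),
                                substring(ref$seq[[1]], prev_t + 1L, t[i] + trim),
                                params$match, params$mismatch,
                                params$gap_open, params$gap_extend,
                                params$band)
        frag_op <- op_chars[sub$ops + 1L]; frag_len <- sub$lens
      }
    } else if (gq > 0L) {
      frag_op <- "I"; frag_len <- gq
    } else if (gt > 0L) {
      frag_op <- "D"; frag_len <- gt
    }
    pieces[[i]] <- list(op = c(frag_op, "M"), len = c(frag_len, s[i] - trim))
    prev_q <- q[i] + s[i]
    prev_t <- t[i] + s[i]
  }
  cg <- merge_cigar(unlist(lapply(pieces, `[[`, "op")),
                    as.integer(unlist(lapply(pieces, `[[`, "len"))))

  # count matching residues over M columns
  qraw <- charToRaw(wq); traw <- charToRaw(ref$seq[[1]])
  qc <- if (strand == 1L) qlen - chain$qe[1] else chain$qs[1]
  tc <- chain$ts[1]
  nmatch <- 0L
  for (i in seq_along(cg$op)) {
    L <- cg$len[i]
    if (cg$op[i] == "M") {
      nmatch <- nmatch + sum(qraw[(qc + 1L):(qc + L)] == traw[(tc + 1L):(tc + L)])
      qc <- qc + L; tc <- tc + L
    } else if (cg$op[i] == "I") {
      qc <- qc + L
    } else {
      tc <- tc + L
    }
  }
  stopifnot(qc == (if (strand == 1L) qlen - chain$qs[1] else chain$qe[1]),
            tc == chain$te[1])

  flag <- chain$flag[1]
  tp <- if (identical(flag, "S")) "S" else "P"
  paf_tibble(
    qname = query$name[[1]], qlen = qlen,
    qstart = chain$qs[1], qend = chain$qe[1],
    strand = if (strand == 1L) "-" else "+",
    tname = ref$name[[1]], tlen = tlen,
    tstart = chain$ts[1], tend = chain$te[1],
    nmatch = nmatch, alnlen = sum(cg$len), mapq = as.integer(mapq),
    tags = list(c(paste0("tp:A:", tp),
                  paste0("cm:i:", chain$n_anchors[1]),
                  paste0("s1:i:", floor(chain$score[1])),
                  paste0("cg:Z:", cigar_string(cg$op, cg$len)))))
}
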