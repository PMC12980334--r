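#' Generate a random genome
#'
#' I.i.d. uniform A/C/G/T sequences, fully reproducible from the seed.
#' Sequence names are `chr1 .. chrN`.
#'
#' @param n_seqs Number of sequences.
#' @param lengths Integer vector of sequence lengths (recycled to
#'   `n_seqs`).
#' @param seed RNG seed.
#' @return A genome tibble (`name`, `seq`, `length`).
#' @export
random_genome <- function(n_seqs, lengths, seed = 1L) {
  lengths <- as.integer(rep_len(lengths, n_seqs))
  if (any(lengths <= 0)) abort("lengths must be positive")
  with_seed(seed, {
    seqs <- vapply(lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    tibble(name = paste0("chr", seq_len(n_seqs)), seq = seqs, length = lengths)
  })
}

#' Mutation specification
#'
#' Structural events are given in reference coordinates (0-based,
#' half-open) and must be pairwise non-overlapping per sequence; insertion
#' points must not fall strictly inside another event's interval. Point
#' mutations (SNPs and short indels) are applied outside all event
#' footprints.
#'
#' @param snp_rate Per-base substitution probability.
#' @param indel_rate Per-base indel-start probability.
#' @param indel_max Maximum indel length (default 10).
#' @param inversions Data frame with columns `seqid`, `start`, `len`
#'   (or NULL).
#' @param duplications Data frame with columns `seqid`, `start`, `len`,
#'   `insert_at`: the reference segment is copied and the copy inserted
#'   into the query at reference coordinate `insert_at` of the same
#'   sequence.
#' @param translocations Data frame with columns `src_seqid`, `start`,
#'   `len`, `dst_seqid`, `insert_at`: cut-and-paste across sequences.
#' @param seed RNG seed for the point mutations.
#' @return An object of class `mutation_spec`.
#' @export
mutation_spec <- function(snp_rate = 0, indel_rate = 0, indel_max = 10L,
                          inversions = NULL, duplications = NULL,
                          translocations = NULL, seed = 1L) {
  if (snp_rate < 0 || snp_rate > 1 || indel_rate < 0 || indel_rate > 1) {
    abort("rates must be in [0, 1]")
  }
  as_tbl <- function(x, cols) {
    if (is.null(x)) return(as_tibble(stats::setNames(rep(list(integer()), length(cols)), cols)))
    x <- as_tibble(x)
    stopifnot(all(cols %in% names(x)))
    x[cols]
  }
  structure(list(
    snp_rate = snp_rate, indel_rate = indel_rate,
    indel_max = as.integer(indel_max),
    inversions = as_tbl(inversions, c("seqid", "start", "len")),
    duplications = as_tbl(duplications, c("seqid", "start", "len", "insert_at")),
    translocations = as_tbl(translocations,
                            c("src_seqid", "start", "len", "dst_seqid", "insert_at")),
    seed = as.integer(seed)), class = "mutation_spec")
}

BASES <- c("A", "C", "G", "T")

# validate event geometry against the reference; returns per-sequence
# interval/insertion bookkeeping
check_spec_events <- function(ref, spec) {
  L <- ref$length
  iv <- dplyr::bind_rows(
    tibble(seqid = as.integer(spec$inversions$seqid),
           start = as.integer(spec$inversions$start),
           end = as.integer(spec$inversions$start + spec$inversions$len),
           kind = rep("INV", nrow(spec$inversions))),
    tibble(seqid = as.integer(spec$duplications$seqid),
           start = as.integer(spec$duplications$start),
           end = as.integer(spec$duplications$start + spec$duplications$len),
           kind = rep("DUPSRC", nrow(spec$duplications))),
    tibble(seqid = as.integer(spec$translocations$src_seqid),
           start = as.integer(spec$translocations$start),
           end = as.integer(spec$translocations$start + spec$translocations$len),
           kind = rep("CUT", nrow(spec$translocations))))
  if (nrow(iv) > 0) {
    if (any(iv$seqid < 1 | iv$seqid > nrow(ref)) ||
        any(iv$start < 0 | iv$end > L[iv$seqid] | iv$start >= iv$end)) {
      abort("event interval out of sequence bounds", class = "seedchain_invalid_spec")
    }
    for (d in unique(iv$seqid)) {
      x <- iv[iv$seqid == d, ]
      x <- x[order(x$start), ]
      if (nrow(x) > 1 && any(x$start[-1] < x$end[-nrow(x)])) {
        abort("overlapping events on one sequence", class = "seedchain_invalid_spec")
      }
    }
  }
  ins <- dplyr::bind_rows(
    tibble(seqid = as.integer(spec$duplications$seqid),
           at = as.integer(spec$duplications$insert_at),
           kind = rep("DUP", nrow(spec$duplications)),
           src_seqid = as.integer(spec$duplications$seqid),
           src_start = as.integer(spec$duplications$start),
           src_end = as.integer(spec$duplications$start + spec$duplications$len)),
    tibble(seqid = as.integer(spec$translocations$dst_seqid),
           at = as.integer(spec$translocations$insert_at),
           kind = rep("TRA", nrow(spec$translocations)),
           src_seqid = as.integer(spec$translocations$src_seqid),
           src_start = as.integer(spec$translocations$start),
           src_end = as.integer(spec$translocations$start + spec$translocations$len)))
  if (nrow(ins) > 0) {
    if (any(ins$seqid < 1 | ins$seqid > nrow(ref)) ||
        any(ins$at < 0 | ins$at > L[ins$seqid])) {
      abort("insertion point out of bounds", class = "seedchain_invalid_spec")
    }
    for (j in seq_len(nrow(ins))) {
      inside <- iv$seqid == ins$seqid[j] & iv$start < ins$at[j] & iv$end > ins$at[j]
      if (any(inside)) {
        abort("insertion point inside another event's interval",
              class = "seedchain_invalid_spec")
      }
    }
  }
  list(iv = iv, ins = ins)
}

#' Apply a mutation specification to a reference genome
#'
#' Structural events are applied first on a segment representation —
#' inversion reverse-complements a segment in place, duplication inserts a
#' copy of a reference segment, translocation cuts a segment from one
#' sequence and pastes it into another — then SNPs and short indels are
#' drawn uniformly outside all event footprints. Every event is recorded
#' in both coordinate systems (reference and final query), and the truth
#' is also serialized as BED text in reference coordinates with the event
#' kind as the name field.
#'
#' @param ref A genome tibble.
#' @param spec A [mutation_spec()].
#' @return A list with `query` (mutated genome tibble), `truth` (tibble:
#'   `kind` SNP/INS/DEL/INV/DUP/TRA, `ref_seqid`, `ref_start`, `ref_end`,
#'   `query_seqid`, `query_start`, `query_end`, `detail`) and `bed`
#'   (character vector of BED lines). All coordinates 0-based half-open;
#'   seqids are 1-based row indices.
#' @export
mutate_genome <- function(ref, spec) {
  ev <- check_spec_events(ref, spec)
  n <- nrow(ref)
  truth <- list()
  query_seqs <- character(n)
  qlens <- integer(n)

  with_seed(spec$seed, {
    for (d in seq_len(n)) {
      # ---- piece list: in-place intervals + plain gaps, then insertions ----
      iv_d <- ev$iv[ev$iv$seqid == d, , drop = FALSE]
      iv_d <- iv_d[order(iv_d$start), , drop = FALSE]
      pieces <- list()
      pos <- 0L
      add <- function(p) pieces[[length(pieces) + 1L]] <<- p
      for (j in seq_len(nrow(iv_d))) {
        if (iv_d$start[j] > pos) {
          add(list(kind = "plain", src = d, rs = pos, re = iv_d$start[j], strand = 0L))
        }
        if (iv_d$kind[j] == "INV") {
          add(list(kind = "INV", src = d, rs = iv_d$start[j], re = iv_d$end[j], strand = 1L))
        } else if (iv_d$kind[j] == "DUPSRC") {
          add(list(kind = "DUPSRC", src = d, rs = iv_d$start[j], re = iv_d$end[j], strand = 0L))
        }                                 # CUT: omitted from the query
        pos <- iv_d$end[j]
      }
      if (pos < ref$length[d]) {
        add(list(kind = "plain", src = d, rs = pos, re = ref$length[d], strand = 0L))
      }
      # insertions at reference coordinate `at`, splitting plain pieces
      ins_d <- ev$ins[ev$ins$seqid == d, , drop = FALSE]
      for (j in seq_len(nrow(ins_d))) {
        at <- ins_d$at[j]
        payload <- list(kind = ins_d$kind[j], src = ins_d$src_seqid[j],
                        rs = ins_d$src_start[j], re = ins_d$src_end[j], strand = 0L)
        placed <- FALSE
        k <- 1L
        while (k <= length(pieces)) {
          p <- pieces[[k]]
          inplace <- p$kind %in% c("plain", "INV", "DUPSRC")
          if (inplace && at < p$re && at > p$rs) {      # split a plain piece
            stopifnot(p$kind == "plain")
            left <- p; left$re <- at
            right <- p; right$rs <- at
            pieces <- append(pieces[-k], list(left, payload, right), after = k - 1L)
            placed <- TRUE; break
          }
          if (inplace && at <= p$rs) {                  # insert before piece k
            pieces <- append(pieces, list(payload), after = k - 1L)
            placed <- TRUE; break
          }
          k <- k + 1L
        }
        if (!placed) pieces <- append(pieces, list(payload))
      }
      # ---- preliminary query: concatenated piece texts ----
      texts <- vapply(pieces, function(p) {
        s <- substring(ref$seq[p$src], p$rs + 1L, p$re)
        if (p$strand == 1L) revcomp_cpp(s) else s
      }, character(1))
      plens <- nchar(texts)
      qoff <- cumsum(c(0L, plens))        # prelim query offset of each piece
      for (k in seq_along(pieces)) {
        p <- pieces[[k]]
        if (p$kind %in% c("INV", "DUP", "TRA")) {
          truth[[length(truth) + 1L]] <- tibble(
            kind = p$kind, ref_seqid = p$src, ref_start = p$rs, ref_end = p$re,
            query_seqid = d, query_start = qoff[k], query_end = qoff[k + 1L],
            detail = "", .prelim = TRUE)
        }
      }
      # ---- point mutations on plain pieces ----
      edits <- list()                     # prelim-coord edits, ascending
      for (k in seq_along(pieces)) {
        p <- pieces[[k]]
        if (p$kind != "plain") next
        plen <- plens[k]
        if (plen == 0L) next
        snp_pos <- if (spec$snp_rate > 0) which(runif(plen) < spec$snp_rate) - 1L else integer()
        ind_pos <- if (spec$indel_rate > 0) which(runif(plen) < spec$indel_rate) - 1L else integer()
        ind_keep <- list()
        blocked_to <- -1L
        for (ip in ind_pos) {
          if (ip <= blocked_to) next
          len <- sample.int(spec$indel_max, 1L)
          del <- runif(1) < 0.5
          if (del) {
            len <- min(len, plen - ip)
            if (len == 0L) next
            blocked_to <- ip + len - 1L
            ind_keep[[length(ind_keep) + 1L]] <- list(pos = ip, type = "DEL", len = len)
          } else {
            blocked_to <- ip
            ind_keep[[length(ind_keep) + 1L]] <-
              list(pos = ip, type = "INS", len = len,
                   repl = paste(sample(BASES, len, replace = TRUE), collapse = ""))
          }
        }
        del_mask <- rep(FALSE, plen)
        for (e in ind_keep) {
          if (e$type == "DEL") del_mask[(e$pos + 1L):(e$pos + e$len)] <- TRUE
          else del_mask[e$pos + 1L] <- TRUE
        }
        snp_pos <- snp_pos[!del_mask[snp_pos + 1L]]
        for (sp in snp_pos) {
          orig <- substring(texts[k], sp + 1L, sp + 1L)
          repl <- sample(setdiff(BASES, orig), 1L)
          edits[[length(edits) + 1L]] <- list(
            q = qoff[k] + sp, ref_pos = p$rs + sp, type = "SNP", len = 1L,
            delta = 0L, repl = repl, detail = paste0(orig, ">", repl))
        }
        for (e in ind_keep) {
          edits[[length(edits) + 1L]] <- list(
            q = qoff[k] + e$pos, ref_pos = p$rs + e$pos, type = e$type,
            len = e$len, delta = if (e$type == "INS") e$len else -e$len,
            repl = if (e$type == "INS") e$repl else "",
            detail = paste0(e$type, ":", e$len))
        }
      }
      # ---- apply edits left-to-right, tracking coordinate shift ----
      prelim <- paste(texts, collapse = "")
      if (length(edits) > 0) {
        eq <- vapply(edits, `[[`, numeric(1), "q")
        edits <- edits[order(eq)]
        eq <- sort(eq)
        chunks <- character(0)
        prev <- 0L
        shift <- 0L
        for (e in edits) {
          if (e$q > prev) chunks <- c(chunks, substring(prelim, prev + 1L, e$q))
          qfinal <- e$q + shift
          if (e$type == "SNP") {
            chunks <- c(chunks, e$repl)
            prev <- e$q + 1L
            tq <- c(qfinal, qfinal + 1L); tr <- c(e$ref_pos, e$ref_pos + 1L)
          } else if (e$type == "INS") {
            chunks <- c(chunks, e$repl)
            prev <- e$q
            shift <- shift + e$len
            tq <- c(qfinal, qfinal + e$len); tr <- c(e$ref_pos, e$ref_pos)
          } else {                        # DEL
            prev <- e$q + e$len
            shift <- shift - e$len
            tq <- c(qfinal, qfinal); tr <- c(e$ref_pos, e$ref_pos + e$len)
          }
          truth[[length(truth) + 1L]] <- tibble(
            kind = e$type, ref_seqid = d, ref_start = tr[1], ref_end = tr[2],
            query_seqid = d, query_start = tq[1], query_end = tq[2],
            detail = e$detail, .prelim = FALSE)
        }
        if (prev < nchar(prelim)) chunks <- c(chunks, substring(prelim, prev + 1L))
        query_seqs[d] <- paste(chunks, collapse = "")
        # adjust structural-event query coords for indel shift before them
        deltas <- vapply(edits, `[[`, numeric(1), "delta")
        cum <- cumsum(deltas)
        shift_at <- function(x) {
          i <- findInterval(x, eq + 1e-9)  # edits strictly before x
          if (i == 0) 0 else cum[i]
        }
        for (ti in seq_along(truth)) {
          tr <- truth[[ti]]
          if (tr$.prelim[1] && tr$query_seqid[1] == d) {
            s0 <- shift_at(tr$query_start[1])
            truth[[ti]]$query_start <- tr$query_start + s0
            truth[[ti]]$query_end <- tr$query_end + s0
            truth[[ti]]$.prelim <- FALSE
          }
        }
      } else {
        query_seqs[d] <- prelim
      }
      qlens[d] <- nchar(query_seqs[d])
    }
  })

  truth <- if (length(truth) > 0) dplyr::bind_rows(truth) else
    tibble(kind = character(), ref_seqid = integer(), ref_start = integer(),
           ref_end = integer(), query_seqid = integer(),
           query_start = integer(), query_end = integer(),
           detail = character(), .prelim = logical())
  truth$.prelim <- NULL
  truth <- dplyr::arrange(truth, .data$ref_seqid, .data$ref_start, .data$kind)
  bed <- sprintf("%s\t%d\t%d\t%s", ref$name[truth$ref_seqid],
                 truth$ref_start, truth$ref_end, truth$kind)
  list(query = tibble(name = ref$name, seq = query_seqs, length = qlens),
       truth = truth, bed = bed)
}
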