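# Independent reference implementations ("oracles") used to verify the
# package's optimized paths, plus small random-fixture generators. These are
# deliberately naive: brute-force scans, exhaustive enumeration, and plain-R
# dynamic programming kept free of the code paths they check.

with_seed <- seedchain:::with_seed

# ---- seeding ---------------------------------------------------------------

# brute-force minimizers: min over each window computed independently
brute_minimizers <- function(seq, k, w) {
  nk <- nchar(seq) - k + 1
  out <- list()
  if (nk < 1) {
    return(tibble::tibble(key = numeric(), pos = integer(), strand = integer()))
  }
  kmers <- lapply(0:(nk - 1), function(p) canonical_kmer(substring(seq, p + 1, p + k)))
  wlen <- min(w, nk)
  emitted <- logical(nk)
  for (i in 0:(nk - wlen)) {
    idx <- (i + 1):(i + wlen)
    keys <- vapply(idx, function(j) {
      if (is.null(kmers[[j]])) Inf else kmers[[j]]$key
    }, numeric(1))
    if (all(is.infinite(keys))) next
    emitted[idx[keys == min(keys)]] <- TRUE
  }
  pos <- which(emitted) - 1L
  tibble::tibble(
    key = vapply(pos, function(p) kmers[[p + 1]]$key, numeric(1)),
    pos = pos,
    strand = vapply(pos, function(p) kmers[[p + 1]]$strand, integer(1)))
}

random_dna <- function(n, with_n = FALSE, seed = NULL) {
  gen <- function() {
    alph <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
    prob <- if (with_n) c(rep(0.24, 4), 0.04) else NULL
    paste(sample(alph, n, replace = TRUE, prob = prob), collapse = "")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# ---- chaining --------------------------------------------------------------

# gap feasibility/cost recomputed from the documented formula, written
# independently of gap_cost()
oracle_cost <- function(dq, dt, span, params) {
  if (dt <= 0 || dq <= 0 || dq > params$max_gap || dt > params$max_gap) {
    return(Inf)
  }
  g <- abs(dq - dt)
  if (g > params$max_skew_bandwidth) return(Inf)
  params$gap_open_scale * span * g + 0.5 * log2(g + 1)
}

# exhaustive enumeration of all feasible ordered anchor subsets of one
# partition; returns the best chain score
best_chain_bruteforce <- function(anchors, params) {
  n <- nrow(anchors)
  strand <- anchors$strand[1]
  best <- -Inf
  dfs <- function(i, sc) {
    best <<- max(best, sc)
    if (i < n) {
      for (j in (i + 1):n) {
        dt <- anchors$tpos[j] - anchors$tpos[i]
        dq <- if (strand == 0) anchors$qpos[j] - anchors$qpos[i]
        else anchors$qpos[i] - anchors$qpos[j]
        cst <- oracle_cost(dq, dt, anchors$span[j], params)
        if (is.finite(cst)) {
          dfs(j, sc + min(dq, dt, anchors$span[j]) - cst)
        }
      }
    }
  }
  for (i in seq_len(n)) dfs(i, anchors$span[i])
  best
}

# plain-R sequential chaining over the *unpartitioned* anchor array: the DP
# runs over all anchors in global (seqid, strand, tpos, qpos) order with
# cross-(seqid, strand) pairs infeasible. Exactly equivalent to partitioned
# chaining when lookback >= partition sizes.
ref_chain_all_sequential <- function(anchors, params) {
  n <- nrow(anchors)
  if (n == 0) return(seedchain:::empty_chains())
  f <- numeric(n)
  pred <- integer(n)
  for (i in seq_len(n)) {
    best <- anchors$span[i]
    bp <- 0L
    lo <- max(1L, i - params$lookback)
    j <- i - 1L
    while (j >= lo) {
      if (anchors$seqid[j] == anchors$seqid[i] &&
          anchors$strand[j] == anchors$strand[i]) {
        dt <- anchors$tpos[i] - anchors$tpos[j]
        dq <- if (anchors$strand[i] == 0) anchors$qpos[i] - anchors$qpos[j]
        else anchors$qpos[j] - anchors$qpos[i]
        cst <- oracle_cost(dq, dt, anchors$span[i], params)
        if (is.finite(cst)) {
          cand <- f[j] + min(dq, dt, anchors$span[i]) - cst
          if (cand > best) { best <- cand; bp <- j }
        }
      }
      j <- j - 1L
    }
    f[i] <- best
    pred[i] <- bp
  }
  used <- logical(n)
  rows <- list()
  for (i in order(-f, seq_len(n))) {
    if (used[i]) next
    idx <- integer(0)
    j <- i
    while (j > 0L && !used[j]) {
      idx <- c(j, idx)
      used[j] <- TRUE
      j <- pred[j]
    }
    if (f[i] >= params$min_chain_score && length(idx) >= params$min_anchors) {
      a <- anchors[idx, , drop = FALSE]
      m <- length(idx)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        seqid = a$seqid[1], strand = a$strand[1], score = f[i],
        qs = min(a$qpos), qe = max(a$qpos + a$span),
        ts = a$tpos[1], te = a$tpos[m] + a$span[m],
        n_anchors = m, flag = "U", anchors = list(a))
    }
  }
  ch <- if (length(rows) == 0) seedchain:::empty_chains() else dplyr::bind_rows(rows)
  dplyr::arrange(ch, dplyr::desc(score), qs, seqid, ts, strand)
}

# random sorted anchor sets spread over several reference sequences/strands
rand_anchors <- function(n, n_seqs, seed, coord = 2000L, span = 11L) {
  with_seed(seed, {
    a <- tibble::tibble(
      qpos = sample.int(coord, n, replace = TRUE) - 1L,
      seqid = sample.int(n_seqs, n, replace = TRUE),
      tpos = sample.int(coord, n, replace = TRUE) - 1L,
      strand = sample(0:1, n, replace = TRUE),
      span = span)
    a[order(a$seqid, a$strand, a$tpos, a$qpos, method = "radix"), ]
  })
}

# ---- classification --------------------------------------------------------

# random chain sets sorted by descending score (only the columns marking uses)
rand_chains <- function(n, seed, coord = 10000L, max_len = 2000L) {
  with_seed(seed, {
    qs <- sample.int(coord, n, replace = TRUE) - 1L
    len <- sample.int(max_len, n, replace = TRUE)
    tibble::tibble(qs = qs, qe = qs + len,
                   score = sort(runif(n, 1, 1000), decreasing = TRUE))
  })
}

# linear-scan interval oracle
scan_overlaps <- function(ivs, s, e) {
  hit <- pmax(0, pmin(e, ivs$e) - pmax(s, ivs$s)) > 0
  ivs[hit, , drop = FALSE]
}

# ---- alignment -------------------------------------------------------------

# full (unbanded) three-state affine DP, score only
ref_affine_score <- function(a, b, p) {
  la <- nchar(a); lb <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  NEG <- -Inf
  M <- matrix(NEG, la + 1, lb + 1)
  I <- matrix(NEG, la + 1, lb + 1)   # consumes a
  D <- matrix(NEG, la + 1, lb + 1)   # consumes b
  M[1, 1] <- 0
  for (j in seq_len(lb)) D[1, j + 1] <- -(p$gap_open + p$gap_extend * j)
  for (i in seq_len(la)) I[i + 1, 1] <- -(p$gap_open + p$gap_extend * i)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      s <- if (av[i] == bv[j]) p$match else -p$mismatch
      M[i + 1, j + 1] <- s + max(M[i, j], I[i, j], D[i, j])
      I[i + 1, j + 1] <- max(M[i, j + 1] - p$gap_open - p$gap_extend,
                             I[i, j + 1] - p$gap_extend,
                             D[i, j + 1] - p$gap_open - p$gap_extend)
      D[i + 1, j + 1] <- max(M[i + 1, j] - p$gap_open - p$gap_extend,
                             I[i + 1, j] - p$gap_open - p$gap_extend,
                             D[i + 1, j] - p$gap_extend)
    }
  }
  max(M[la + 1, lb + 1], I[la + 1, lb + 1], D[la + 1, lb + 1])
}

# exhaustive enumeration over all alignment paths (tiny inputs only)
enum_affine_score <- function(a, b, p) {
  la <- nchar(a); lb <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i == la && j == lb) return(0)
    best <- -Inf
    if (i < la && j < lb) {
      s <- if (av[i + 1] == bv[j + 1]) p$match else -p$mismatch
      best <- max(best, s + rec(i + 1, j + 1, "M"))
    }
    if (i < la) {
      open <- if (prev == "I") 0 else p$gap_open
      best <- max(best, -open - p$gap_extend + rec(i + 1, j, "I"))
    }
    if (j < lb) {
      open <- if (prev == "D") 0 else p$gap_open
      best <- max(best, -open - p$gap_extend + rec(i, j + 1, "D"))
    }
    best
  }
  rec(0, 0, "M")
}

# ---- PAF / CIGAR -----------------------------------------------------------

parse_cigar <- function(cg) {
  m <- gregexpr("[0-9]+[MID]", cg)[[1]]
  runs <- regmatches(cg, gregexpr("[0-9]+[MID]", cg))[[1]]
  tibble::tibble(op = substring(runs, nchar(runs)),
                 len = as.integer(substring(runs, 1, nchar(runs) - 1)))
}

get_tag <- function(tags, prefix) {
  hit <- grep(paste0("^", prefix), tags, value = TRUE)
  if (length(hit) == 0) NA_character_ else sub(paste0("^", prefix), "", hit[1])
}

# every record's CIGAR must tile its query and target intervals
expect_cigar_consistent <- function(records) {
  for (i in seq_len(nrow(records))) {
    cg <- parse_cigar(get_tag(records$tags[[i]], "cg:Z:"))
    expect_equal(sum(cg$len[cg$op != "D"]),
                 records$qend[i] - records$qstart[i])
    expect_equal(sum(cg$len[cg$op != "I"]),
                 records$tend[i] - records$tstart[i])
    expect_equal(sum(cg$len), records$alnlen[i])
    expect_true(all(cg$len > 0))
    expect_true(all(cg$op[-1] != cg$op[-nrow(cg)]))
  }
  invisible(records)
}

rand_paf_records <- function(n, seed) {
  with_seed(seed, {
    qlen <- sample(50:500, n, replace = TRUE)
    qstart <- vapply(qlen, function(L) sample.int(L - 1, 1) - 1L, integer(1))
    qend <- vapply(seq_len(n), function(i) sample(qstart[i]:(qlen[i] - 1), 1) + 1L,
                   integer(1))
    tlen <- sample(50:500, n, replace = TRUE)
    tstart <- vapply(tlen, function(L) sample.int(L - 1, 1) - 1L, integer(1))
    tend <- vapply(seq_len(n), function(i) sample(tstart[i]:(tlen[i] - 1), 1) + 1L,
                   integer(1))
    alnlen <- pmax(qend - qstart, tend - tstart)
    paf_tibble(
      qname = paste0("q", sample.int(99, n, replace = TRUE)),
      qlen = qlen, qstart = qstart, qend = qend,
      strand = sample(c("+", "-"), n, replace = TRUE),
      tname = paste0("t", sample.int(99, n, replace = TRUE)),
      tlen = tlen, tstart = tstart, tend = tend,
      nmatch = pmin(qend - qstart, tend - tstart),
      alnlen = alnlen,
      mapq = sample(0:60, n, replace = TRUE),
      tags = lapply(seq_len(n), function(i) {
        c(sample(c("tp:A:P", "tp:A:S"), 1),
          paste0("cm:i:", sample.int(50, 1)),
          paste0("xx:i:", sample.int(1000, 1)))
      }))
  })
}
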