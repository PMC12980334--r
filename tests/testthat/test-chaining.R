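mk_anchors <- function(qpos, tpos, seqid = 1L, strand = 0L, span = 15L) {
  a <- tibble::tibble(qpos = as.integer(qpos), seqid = as.integer(seqid),
                      tpos = as.integer(tpos), strand = as.integer(strand),
                      span = as.integer(span))
  a[order(a$seqid, a$strand, a$tpos, a$qpos, method = "radix"), ]
}

test_that("partition_anchors: one partition per (seqid, strand) run", {
  a <- rand_anchors(120, 3, seed = 1)
  # force all six groups to be present
  a <- dplyr::bind_rows(a, mk_anchors(0, 0, seqid = rep(1:3, each = 2),
                                      strand = rep(0:1, 3)))
  a <- a[order(a$seqid, a$strand, a$tpos, a$qpos, method = "radix"), ]
  p <- partition_anchors(a, 3)
  expect_equal(nrow(p), 6L)
  expect_identical(dplyr::bind_rows(p$anchors), a)

  expect_equal(nrow(partition_anchors(a[0, ], 3)), 0L)
  one <- mk_anchors(c(5, 30, 60), c(5, 30, 60))
  p1 <- partition_anchors(one, 1)
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$n, 3L)

  expect_error(partition_anchors(a[rev(seq_len(nrow(a))), ], 3),
               class = "seedchain_precondition_error")
})

test_that("gap_cost: co-linear pairs are free, violations are infeasible", {
  p <- chain_params()
  mk <- function(qpos, tpos, strand = 0L, span = 15L) {
    list(qpos = qpos, tpos = tpos, strand = strand, span = span)
  }
  expect_equal(gap_cost(mk(0, 0), mk(100, 100), p), 0)
  expect_equal(gap_cost(mk(0, 0), mk(0, 100), p), Inf)    # dq == 0
  expect_equal(gap_cost(mk(0, 0), mk(100, 0), p), Inf)    # dt == 0
  expect_equal(gap_cost(mk(0, 0), mk(10, 600), p), Inf)   # skew > bandwidth
  expect_equal(gap_cost(mk(0, 0), mk(6000, 6000), p), Inf) # gap > max_gap
  # documented form: linear + logarithmic in the skew g
  expect_equal(gap_cost(mk(0, 0), mk(10, 17), p),
               0.01 * 15 * 7 + 0.5 * log2(8))
  # strand-1 chains advance with decreasing qpos
  expect_equal(gap_cost(mk(100, 0, 1L), mk(0, 100, 1L), p), 0)
})

test_that("chain_partition base cases follow the recurrence", {
  p1 <- chain_params(min_chain_score = 1, min_anchors = 1)
  one <- mk_anchors(10, 10)
  ch <- chain_partition(one, p1)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$score, 15)              # f = span

  two <- mk_anchors(c(0, 20), c(0, 20))
  ch2 <- chain_partition(two, p1)
  expect_equal(nrow(ch2), 1L)
  expect_equal(ch2$score, 15 + 15)        # span + min(20, 20, 15) - 0
  expect_equal(ch2$n_anchors, 2L)
  expect_equal(c(ch2$qs, ch2$qe, ch2$ts, ch2$te), c(0, 35, 0, 35))
})

test_that("DP score equals brute-force enumeration on small instances", {
  p <- chain_params(max_gap = 500, max_skew_bandwidth = 100,
                    min_chain_score = 1, min_anchors = 1, lookback = 50)
  for (seed in 1:60) {
    n <- with_seed(seed * 7, sample(2:10, 1))
    a <- rand_anchors(n, 1, seed = seed, coord = 300L)
    a <- a[a$strand == a$strand[1], ]     # single partition
    ch <- chain_partition(a, p)
    expect_gt(nrow(ch), 0)
    expect_equal(max(ch$score), best_chain_bruteforce(a, p),
                 info = paste("seed", seed))
  }
})

test_that("reported chains respect thresholds and anchor disjointness", {
  p <- chain_params(min_chain_score = 30, min_anchors = 2)
  for (seed in 1:10) {
    a <- rand_anchors(150, 2, seed = seed + 100, coord = 1500L)
    ch <- chain_all(a, 2, p)
    if (nrow(ch) == 0) next
    expect_true(all(ch$score >= 30))
    expect_true(all(ch$n_anchors >= 2))
    expect_true(all(ch$score >= ch$anchors[[1]]$span[1]))
    # anchors belong to at most one chain
    keys <- unlist(lapply(ch$anchors, function(x) {
      paste(x$seqid, x$strand, x$tpos, x$qpos)
    }))
    expect_equal(anyDuplicated(keys), 0L)
    # chains never mix (seqid, strand)
    for (i in seq_len(nrow(ch))) {
      expect_equal(length(unique(ch$anchors[[i]]$seqid)), 1L)
      expect_equal(length(unique(ch$anchors[[i]]$strand)), 1L)
    }
  }
})

test_that("partition-parallel chaining equals the sequential reference", {
  p <- chain_params(min_chain_score = 20, min_anchors = 2, lookback = 500)
  for (seed in 1:15) {
    a <- rand_anchors(100, 3, seed = seed + 200, coord = 1200L)
    seq_ref <- ref_chain_all_sequential(a, p)
    par1 <- chain_all(a, 3, p, workers = 1)
    expect_equal(nrow(par1), nrow(seq_ref))
    expect_equal(par1$score, seq_ref$score)
    expect_equal(par1$qs, seq_ref$qs)
    expect_equal(par1$ts, seq_ref$ts)
    expect_identical(lapply(par1$anchors, as.data.frame),
                     lapply(seq_ref$anchors, as.data.frame))
    for (wk in c(2, 4)) {
      expect_identical(chain_all(a, 3, p, workers = wk), par1)
    }
  }
})

test_that("anchors duplicated onto a second seqid give per-seqid chains", {
  p <- chain_params(min_chain_score = 1, min_anchors = 1)
  base <- mk_anchors(c(0, 20, 40), c(0, 20, 40))
  dup <- base; dup$seqid <- 2L
  a <- dplyr::bind_rows(base, dup)
  a <- a[order(a$seqid, a$strand, a$tpos, a$qpos, method = "radix"), ]
  ch <- chain_all(a, 2, p)
  expect_equal(nrow(ch), 2L)
  expect_equal(sort(ch$seqid), c(1L, 2L))
  expect_equal(ch$score[1], ch$score[2])
  # all anchors in one partition: chain_all equals chain_partition
  ch1 <- chain_all(base, 1, p, workers = 8)
  direct <- chain_partition(base, p)
  expect_equal(ch1$score, direct$score)
  expect_equal(ch1$n_anchors, direct$n_anchors)
})
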