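test_that("affine_align base cases under default scoring", {
  r <- affine_align("ACGT", "ACGT")
  expect_equal(r$score, 8)
  expect_equal(r$cigar, tibble::tibble(op = "M", len = 4L))

  r2 <- affine_align("", "AC")
  expect_equal(r2$score, -(4 + 2 * 2))
  expect_equal(r2$cigar, tibble::tibble(op = "D", len = 2L))

  r3 <- affine_align("AC", "")
  expect_equal(r3$cigar, tibble::tibble(op = "I", len = 2L))

  expect_error(affine_align(strrep("A", 600), "A", align_params(band = 500)),
               class = "seedchain_banded_infeasible")
})

test_that("full-DP reference matches exhaustive path enumeration (tiny)", {
  p <- align_params()
  for (seed in 1:25) {
    a <- random_dna(with_seed(seed, sample(0:5, 1)), seed = seed)
    b <- random_dna(with_seed(seed + 1, sample(0:5, 1)), seed = seed + 1)
    expect_equal(ref_affine_score(a, b, p), enum_affine_score(a, b, p),
                 info = paste("seed", seed))
  }
})

test_that("banded aligner equals the unbanded reference on random pairs", {
  p <- align_params()
  for (seed in 1:60) {
    a <- random_dna(with_seed(seed * 3, sample(0:12, 1)), seed = seed * 3)
    b <- random_dna(with_seed(seed * 3 + 1, sample(0:12, 1)), seed = seed * 3 + 1)
    got <- affine_align(a, b, p)
    expect_equal(got$score, ref_affine_score(a, b, p),
                 info = paste(a, b))
    # CIGAR tiles both strings
    expect_equal(sum(got$cigar$len[got$cigar$op != "D"]), nchar(a))
    expect_equal(sum(got$cigar$len[got$cigar$op != "I"]), nchar(b))
  }
})

test_that("alignment score is symmetric; the I/D-swapped CIGAR is optimal", {
  # replay a CIGAR against a sequence pair under affine scoring
  score_cigar <- function(a, b, cg, p) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    i <- 0L; j <- 0L; sc <- 0
    for (r in seq_len(nrow(cg))) {
      L <- cg$len[r]
      if (cg$op[r] == "M") {
        sc <- sc + sum(ifelse(av[i + 1:L] == bv[j + 1:L], p$match, -p$mismatch))
        i <- i + L; j <- j + L
      } else if (cg$op[r] == "I") {
        sc <- sc - p$gap_open - p$gap_extend * L; i <- i + L
      } else {
        sc <- sc - p$gap_open - p$gap_extend * L; j <- j + L
      }
    }
    stopifnot(i == nchar(a), j == nchar(b))
    sc
  }
  p <- align_params()
  for (seed in 1:15) {
    a <- random_dna(10, seed = seed + 40)
    b <- random_dna(8, seed = seed + 80)
    f <- affine_align(a, b, p)
    r <- affine_align(b, a, p)
    expect_equal(f$score, r$score)
    # the mirrored CIGAR is a valid optimal alignment of the swapped pair
    swapped <- f$cigar
    swapped$op <- chartr("ID", "DI", swapped$op)
    expect_equal(score_cigar(b, a, swapped, p), r$score)
  }
})

test_that("a narrow band binds; a wide band reproduces the optimum", {
  a <- paste0(strrep("A", 10), strrep("C", 10))
  b <- paste0(strrep("A", 10), strrep("G", 6), strrep("C", 10))
  wide <- affine_align(a, b, align_params(band = 100))
  expect_equal(wide$score, ref_affine_score(a, b, align_params()))
})

test_that("compute_mapq implements the linear competing-score rule", {
  expect_equal(compute_mapq(100, NULL), 60L)
  expect_equal(compute_mapq(100, 100), 0L)
  expect_equal(compute_mapq(100, 50), 30L)
  expect_equal(compute_mapq(100, 25), 45L)
})

# build a single-chain fixture through the real pipeline
chain_for <- function(query, ref, k = 11, w = 5) {
  idx <- build_index(ref, index_params(k = k, w = w, max_occ = 200))
  a <- collect_anchors(query, idx)
  ch <- chain_all(a, nrow(ref), chain_params(min_chain_score = 20, min_anchors = 2))
  ch$flag <- mark_primary_fast(ch)
  list(chains = ch, idx = idx)
}

test_that("extend_chain: exact self-alignment is one all-match M run", {
  g <- random_genome(1, 1000, seed = 51)
  fx <- chain_for(g, g)
  rec <- extend_chain(fx$chains[1, ], g, g, align_params())
  expect_equal(rec$strand, "+")
  expect_equal(rec$nmatch, rec$alnlen)
  cg <- parse_cigar(get_tag(rec$tags[[1]], "cg:Z:"))
  expect_equal(nrow(cg), 1L)
  expect_equal(cg$op, "M")
  expect_equal(cg$len, rec$qend - rec$qstart)
  expect_cigar_consistent(rec)
})

test_that("extend_chain: a planted insertion appears as one I run", {
  g <- random_genome(1, 2000, seed = 52)
  ins <- random_dna(10, seed = 99)
  qseq <- paste0(substring(g$seq, 1, 1000), ins, substring(g$seq, 1001))
  q <- tibble::tibble(name = "q", seq = qseq, length = nchar(qseq))
  fx <- chain_for(q, g)
  rec <- extend_chain(fx$chains[1, ], q, g, align_params())
  cg <- parse_cigar(get_tag(rec$tags[[1]], "cg:Z:"))
  expect_equal(sum(cg$op == "I"), 1L)
  expect_equal(cg$len[cg$op == "I"], 10L)
  expect_equal(rec$qend - rec$qstart, (rec$tend - rec$tstart) + 10L)
  expect_cigar_consistent(rec)
})

test_that("extend_chain: reverse-complement query aligns on strand '-'", {
  g <- random_genome(1, 1500, seed = 53)
  q <- tibble::tibble(name = "q", seq = revcomp(g$seq), length = g$length)
  fx <- chain_for(q, g)
  expect_true(all(fx$chains$strand == 1))
  rec <- extend_chain(fx$chains[1, ], q, g, align_params())
  expect_equal(rec$strand, "-")
  expect_equal(rec$nmatch, rec$alnlen)
  expect_cigar_consistent(rec)
})

test_that("extend_chain rejects anchors inconsistent with the sequences", {
  g <- random_genome(1, 1000, seed = 54)
  fx <- chain_for(g, g)
  other <- random_genome(1, 1000, seed = 55)
  expect_error(extend_chain(fx$chains[1, ], other, g, align_params()),
               class = "seedchain_internal_error")
})
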