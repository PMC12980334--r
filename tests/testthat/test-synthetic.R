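test_that("random_genome is seed-reproducible with requested shapes", {
  g1 <- random_genome(3, c(100, 200, 300), seed = 5)
  g2 <- random_genome(3, c(100, 200, 300), seed = 5)
  expect_identical(g1, g2)
  expect_equal(g1$length, c(100L, 200L, 300L))
  expect_equal(g1$name, c("chr1", "chr2", "chr3"))
  g3 <- random_genome(1, 100, seed = 6)
  expect_false(g3$seq == g1$seq[1])
})

test_that("zero rates and no events reproduce the reference exactly", {
  g <- random_genome(2, c(500, 400), seed = 7)
  res <- mutate_genome(g, mutation_spec())
  expect_identical(res$query$seq, g$seq)
  expect_equal(nrow(res$truth), 0L)
  expect_equal(length(res$bed), 0L)
})

test_that("an inversion reverse-complements exactly its window", {
  g <- random_genome(1, 2000, seed = 8)
  res <- mutate_genome(g, mutation_spec(
    inversions = data.frame(seqid = 1, start = 500, len = 300)))
  q <- res$query$seq
  expect_equal(substring(q, 1, 500), substring(g$seq, 1, 500))
  expect_equal(substring(q, 801), substring(g$seq, 801))
  expect_equal(substring(q, 501, 800),
               revcomp(substring(g$seq, 501, 800)))
  expect_equal(res$truth$kind, "INV")
  expect_equal(res$bed, "chr1\t500\t800\tINV")
})

test_that("SNP counts are binomial-consistent and reproducible", {
  g <- random_genome(1, 200000, seed = 9)
  spec <- mutation_spec(snp_rate = 0.001, seed = 10)
  res <- mutate_genome(g, spec)
  n_snp <- sum(res$truth$kind == "SNP")
  expectation <- 200000 * 0.001
  sigma <- sqrt(expectation * (1 - 0.001))
  expect_gt(n_snp, expectation - 3 * sigma)
  expect_lt(n_snp, expectation + 3 * sigma)
  res2 <- mutate_genome(g, spec)
  expect_identical(res, res2)
  # every SNP truth coordinate points at a real mismatch
  for (i in which(res$truth$kind == "SNP")[1:20]) {
    tr <- res$truth[i, ]
    expect_false(substring(g$seq, tr$ref_start + 1, tr$ref_end) ==
                   substring(res$query$seq, tr$query_start + 1, tr$query_end))
  }
})

test_that("indel truth coordinates are exact in both systems", {
  g <- random_genome(1, 20000, seed = 11)
  res <- mutate_genome(g, mutation_spec(indel_rate = 0.002, indel_max = 6,
                                        seed = 12))
  ins <- res$truth[res$truth$kind == "INS", ]
  del <- res$truth[res$truth$kind == "DEL", ]
  expect_gt(nrow(ins) + nrow(del), 0)
  expect_equal(nchar(res$query$seq),
               20000L + sum(ins$query_end - ins$query_start) -
                 sum(del$ref_end - del$ref_start))
  # replaying the truth events over the reference reconstructs the query
  # exactly, which validates every coordinate in both systems
  tru <- res$truth[order(res$truth$ref_start), ]
  out <- character()
  pos <- 0L
  for (i in seq_len(nrow(tru))) {
    tr <- tru[i, ]
    out <- c(out, substring(g$seq, pos + 1, tr$ref_start))
    out <- c(out, substring(res$query$seq, tr$query_start + 1, tr$query_end))
    pos <- tr$ref_end
  }
  out <- c(out, substring(g$seq, pos + 1))
  expect_equal(paste(out, collapse = ""), res$query$seq)
})

test_that("duplication and translocation copies are placed exactly", {
  g <- random_genome(2, c(5000, 4000), seed = 13)
  res <- mutate_genome(g, mutation_spec(
    duplications = data.frame(seqid = 1, start = 1000, len = 500,
                              insert_at = 3000),
    translocations = data.frame(src_seqid = 2, start = 500, len = 400,
                                dst_seqid = 1, insert_at = 4000)))
  tru <- res$truth
  dup <- tru[tru$kind == "DUP", ]
  expect_equal(substring(res$query$seq[1], dup$query_start + 1, dup$query_end),
               substring(g$seq[1], 1001, 1500))
  tra <- tru[tru$kind == "TRA", ]
  expect_equal(substring(res$query$seq[1], tra$query_start + 1, tra$query_end),
               substring(g$seq[2], 501, 900))
  # cut region absent from the source sequence
  expect_equal(nchar(res$query$seq[2]), 4000L - 400L)
  expect_equal(nchar(res$query$seq[1]), 5000L + 500L + 400L)
})

test_that("overlapping events are rejected", {
  g <- random_genome(1, 2000, seed = 14)
  expect_error(mutate_genome(g, mutation_spec(
    inversions = data.frame(seqid = 1, start = c(100, 300), len = c(400, 100)))),
    class = "seedchain_invalid_spec")
  expect_error(mutate_genome(g, mutation_spec(
    inversions = data.frame(seqid = 1, start = 1900, len = 200))),
    class = "seedchain_invalid_spec")
  expect_error(mutate_genome(g, mutation_spec(
    duplications = data.frame(seqid = 1, start = 100, len = 200,
                              insert_at = 150))),
    class = "seedchain_invalid_spec")
})
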