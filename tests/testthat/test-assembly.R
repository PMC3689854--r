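# Contig assembly by exact terminal suffix-prefix overlaps.

test_that("find_overlap reports the longest terminal overlap", {
  ov <- find_overlap("ACGUACGU", "UACGUUUU", 5L)
  expect_equal(ov$type, "overlap")
  expect_equal(ov$length, 5L)
  expect_identical(find_overlap("ACGUACGU", "ACGUACGU")$type, "contained")
  expect_identical(find_overlap("AAAAA", "CCCCC")$type, "none")
  # the reported length is the longest, not just any admissible one
  ov2 <- find_overlap("GGACGUACGU", "CGUACGUUUA", 3L)
  expect_equal(ov2$length, 7L)
})

test_that("kmp overlap equals the naive scan on random pairs", {
  set.seed(11)
  for (i in 1:300) {
    a <- rand_rna(sample(5:40, 1))
    b <- rand_rna(sample(5:40, 1))
    expect_equal(duplexmir:::kmp_overlap(a, b), oracle_overlap_len(a, b))
  }
  # adversarial periodic cases
  expect_equal(duplexmir:::kmp_overlap("ACACAC", "ACACGG"), 4L)
  expect_equal(duplexmir:::kmp_overlap("AAAA", "AAAAA"), 4L)
})

test_that("tiled reads reassemble to their source", {
  src <- "UGAGGUAGUAGGUUGUAUAGUU"
  tiles <- substring(src, c(1, 6, 11), c(12, 17, 22))
  cs <- assemble(collapse_reads(reads_table(paste0("r", 1:3), tiles)))
  expect_length(cs, 1L)
  expect_equal(cs[[1]]$sequence, src)
  expect_equal(nrow(cs[[1]]$members), 3L)
  # members recorded at their true offsets
  for (k in seq_len(3)) {
    m <- cs[[1]]$members[k, ]
    expect_equal(substr(src, m$offset + 1L, m$offset + m$length),
                 tiles[match(m$id, paste0("r", 1:3))])
  }
  expect_true(all(cs[[1]]$depth >= 1L))
})

test_that("non-overlapping and identical reads behave as expected", {
  cs <- assemble(reads_table(c("a", "b"),
                             c("AAAAAAAAAAAAGGG", "CCCCCCCCCCCCUUU")))
  expect_length(cs, 2L)
  r <- collapse_reads(reads_table(paste0("r", 1:5),
                                  rep("ACGUACGUACGUACG", 5)))
  cs2 <- assemble(r)
  expect_length(cs2, 1L)
  expect_equal(cs2[[1]]$total_count, 5)
})

test_that("assembly matches the brute-force greedy oracle on random sets", {
  set.seed(21)
  for (trial in 1:40) {
    n <- sample(3:15, 1)
    seqs <- unique(replicate(n, rand_rna(sample(15:30, 1))))
    reads <- reads_table(sprintf("r%02d", seq_along(seqs)), seqs)
    got <- vapply(assemble(reads, max_length = 10000L), `[[`, "", "sequence")
    expect_equal(got, oracle_assemble_seqs(seqs))
  }
})

test_that("assembly is invariant to input order", {
  set.seed(5)
  seqs <- unique(replicate(12, rand_rna(sample(15:25, 1))))
  reads <- reads_table(sprintf("r%02d", seq_along(seqs)), seqs)
  ref <- vapply(assemble(reads), `[[`, "", "sequence")
  for (k in 1:5) {
    perm <- reads[sample(nrow(reads)), ]
    expect_equal(vapply(assemble(perm), `[[`, "", "sequence"), ref)
  }
})

test_that("over-length contigs are flagged and counts are conserved", {
  src <- rand_rna(120)
  tiles <- substring(src, seq(1, 101, by = 10), seq(20, 120, by = 10))
  reads <- collapse_reads(reads_table(sprintf("t%02d", 1:11), tiles, 2L))
  cs <- assemble(reads, max_length = 80L)
  expect_true(any(vapply(cs, `[[`, TRUE, "flagged")))
  expect_equal(sum(vapply(cs, `[[`, 1, "total_count")), sum(reads$count))
})

test_that("contig FASTA export carries counts and member offsets", {
  src <- "UGAGGUAGUAGGUUGUAUAGUU"
  tiles <- substring(src, c(1, 6, 11), c(12, 17, 22))
  cs <- assemble(collapse_reads(reads_table(paste0("r", 1:3), tiles, 4L)))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_contigs_fasta(cs, fa)
  hdr <- readLines(fa)[1]
  expect_match(hdr, "members=3")
  expect_match(hdr, "total_count=12")
  side <- utils::read.delim(paste0(fa, ".members.tsv"))
  expect_equal(nrow(side), 3L)
})
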