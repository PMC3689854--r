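# Complementarity alignment, overhangs, and pairing-state encoding.

test_that("a perfect complement aligns flush with all-M encoding", {
  top <- "UGAGGUAGUAGGUUGUAUAGUU"
  d <- complement_align(top, rc(top))
  expect_equal(d$score, 22 * 2)
  expect_equal(d$gap_columns, 0L)
  expect_equal(d$overhang_top3, 0L)
  expect_equal(d$overhang_bottom3, 0L)
  expect_equal(encode_duplex(d), strrep("M", 22))
})

test_that("a single G:U column scores wobble and encodes M", {
  top <- "UGAGGUAGUAGGUUGUAUAGUU"
  bot_row <- strsplit(rc(top), "")[[1L]] # bottom arm 5'->3'
  # force one wobble: pair top G (position 4, 5'->3') with U instead of C
  stopifnot(substr(top, 4, 4) == "G")
  bot_row[22 - 4 + 1] <- "U"
  bot <- paste(bot_row, collapse = "")
  d <- complement_align(top, bot)
  expect_equal(d$score, 21 * 2 + 1)
  expect_equal(encode_duplex(d), strrep("M", 22))
})

test_that("a non-complementary column encodes X at its position", {
  top <- "UGAGGUAGUAGGUUGUAUAGUU"
  bot_row <- strsplit(rc(top), "")[[1L]]
  stopifnot(substr(top, 10, 10) == "A") # partner U -> make it C (no pair)
  bot_row[22 - 10 + 1] <- "C"
  d <- complement_align(top, paste(bot_row, collapse = ""))
  expect_equal(encode_duplex(d),
               paste0(strrep("M", 9), "X", strrep("M", 12)))
  expect_equal(d$score, 21 * 2 - 1)
})

test_that("3' overhangs are free and reported per strand", {
  top <- "UGAGGUAGUAGGUUGUAUAGUU"
  bot <- paste0(rc(top), "CA") # 2 extra nt at the bottom 3' end
  d <- complement_align(top, bot)
  expect_equal(d$overhang_bottom3, 2L)
  expect_equal(d$score, 22 * 2) # no gap penalty for overhang columns
  top2 <- paste0(top, "GG") # and at the top 3' end
  d2 <- complement_align(top2, rc(top))
  expect_equal(d2$overhang_top3, 2L)
  expect_equal(d2$score, 22 * 2)
})

test_that("alignment score is symmetric and errors on empty input", {
  set.seed(3)
  for (i in 1:25) {
    a <- rand_rna(sample(15:24, 1))
    b <- rand_rna(sample(15:24, 1))
    expect_equal(complement_align(a, b)$score, complement_align(b, a)$score)
  }
  expect_error(complement_align("", "ACGU"), "empty")
})

test_that("alignment equals exhaustive enumeration on short pairs", {
  sc <- scoring_scheme()
  set.seed(17)
  for (i in 1:25) {
    a <- rand_rna(sample(2:6, 1))
    b <- rand_rna(sample(2:6, 1))
    expect_equal(complement_align(a, b, sc)$score,
                 oracle_align_enum(a, b, sc),
                 info = paste(a, b))
  }
  for (i in 1:3) { # a few full 7-mers
    a <- rand_rna(7); b <- rand_rna(7)
    expect_equal(complement_align(a, b, sc)$score, oracle_align_enum(a, b, sc))
  }
})

test_that("alignment equals an independent affine-gap DP on longer pairs", {
  sc <- scoring_scheme()
  set.seed(19)
  for (i in 1:120) {
    a <- rand_rna(sample(8:30, 1))
    b <- rand_rna(sample(8:30, 1))
    expect_equal(complement_align(a, b, sc)$score, oracle_align_dp(a, b, sc),
                 info = paste(a, b))
  }
})

test_that("gap columns encode I (bottom gap) and D (top gap)", {
  # planted single-nt bulge in the top strand (extra top base => bottom gap)
  top_row <- strsplit("UGAGGUAGUAGGUUGUAUAGUU", "")[[1L]]
  bot_row <- vapply(top_row, function(b) {
    c(A = "U", C = "G", G = "C", U = "A")[[b]]
  }, "")
  top_row <- append(top_row, "A", after = 11) # insertion at column 12
  bot_row <- append(bot_row, "-", after = 11)
  top <- paste(top_row, collapse = "")
  bot <- paste(rev(bot_row[bot_row != "-"]), collapse = "")
  d <- complement_align(top, bot)
  enc <- encode_duplex(d)
  expect_equal(nchar(enc), 23L)
  expect_equal(sum(strsplit(enc, "")[[1L]] == "I"), 1L)
  # and the mirror case: gap in the top strand encodes D
  d2 <- complement_align(bot, top)
  expect_equal(sum(strsplit(encode_duplex(d2), "")[[1L]] == "D"), 1L)
})

test_that("encoding conserves paired-region column counts", {
  set.seed(23)
  spec <- duplex_spec(n_positive = 30L, n_negative = 30L, seed = 23L)
  dx <- simulate_duplexes(spec)
  for (i in seq_len(nrow(dx))) {
    d <- complement_align(dx$top[i], dx$bottom[i])
    enc <- strsplit(encode_duplex(d), "")[[1L]]
    expect_equal(length(enc), nchar(d$aligned_top))
    expect_true(all(enc %in% c("M", "X", "I", "D")))
  }
})

test_that("select_duplexes pairs mutual bests exactly once", {
  a <- "UGAGGUAGUAGGUUGUAUAGUU"
  reads <- reads_table(
    c("a", "b", "c"),
    c(a, rc(a), "ACACACACACACACACAC"),
    c(5L, 3L, 1L))
  contigs <- assemble(collapse_reads(reads))
  dl <- select_duplexes(contigs)
  expect_length(dl, 1L)
  expect_equal(sort(c(dl[[1]]$top, dl[[1]]$bottom)), sort(c(a, rc(a))))
  # higher-count contig is the top (reference) strand
  expect_equal(dl[[1]]$top, a)
  expect_length(attr(dl, "unpaired"), 1L)
  # a hard minimum score leaves everything unpaired
  dl2 <- select_duplexes(contigs, min_score = 1e6)
  expect_length(dl2, 0L)
  expect_length(attr(dl2, "unpaired"), 3L)
})

test_that("select_duplexes is invariant to contig order and ties break documented", {
  set.seed(31)
  specs <- duplex_spec(n_positive = 4L, n_negative = 2L, seed = 31L)
  dx <- simulate_duplexes(specs)
  reads <- reads_table(sprintf("r%02d", seq_len(2 * nrow(dx))),
                       c(dx$top, dx$bottom))
  contigs <- assemble(collapse_reads(reads))
  d1 <- select_duplexes(contigs)
  d2 <- select_duplexes(rev(contigs))
  key <- function(dl) sort(vapply(dl, function(d) paste(d$top, d$bottom), ""))
  expect_equal(key(d1), key(d2))
})
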