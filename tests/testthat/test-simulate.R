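# Synthetic duplex/read generators: determinism, ground-truth consistency,
# and the distributional contrasts the benchmark relies on.

test_that("generators are pure functions of (spec, seed)", {
  spec <- duplex_spec(n_positive = 15L, n_negative = 15L, seed = 81L)
  a <- simulate_duplexes(spec)
  b <- simulate_duplexes(spec)
  expect_identical(a, b)
  c <- simulate_duplexes(spec, seed = 82L)
  expect_false(identical(a, c))
})

test_that("a degenerate all-M model yields perfect complements", {
  spec <- duplex_spec(n_positive = 10L, n_negative = 1L, seed = 83L,
                      anchor_x_prob = 0, ins_pair_prob = 0, del_pair_prob = 0,
                      noise_x = 0, wobble_prob = 0,
                      overhang_probs = c(`0` = 1, `1` = 0, `2` = 0))
  dx <- simulate_duplexes(spec)
  pos <- dx[dx$label == "miRNA", ]
  expect_true(all(pos$pattern == strrep("M", nchar(pos$pattern))))
  expect_equal(pos$bottom, reverse_complement(pos$top))
})

test_that("positive realizations are self-consistent under re-alignment", {
  spec <- duplex_spec(n_positive = 25L, n_negative = 0L, seed = 85L)
  dx <- simulate_duplexes(spec)
  for (i in seq_len(nrow(dx))) {
    d <- complement_align(dx$top[i], dx$bottom[i])
    expect_equal(encode_duplex(d), dx$pattern[i])
    expect_equal(d$overhang_top3, dx$overhang_top3[i])
    expect_equal(d$overhang_bottom3, dx$overhang_bottom3[i])
  }
})

test_that("read tiling covers sources and respects depth", {
  r1 <- simulate_reads(c(s = strrep("ACGU", 8))[1], read_length = 20L,
                       min_tile_overlap = 10L, depth = 5L)
  expect_true(all(r1$count == 5L))
  expect_gte(nrow(r1), 2L)
  # short source: one full-length read
  r2 <- simulate_reads("ACGUACGUACGUACGUACGUAC", read_length = 22L)
  expect_equal(nrow(r2), 1L)
  expect_equal(nchar(r2$sequence), 22L)
  # tiles of a repeat-free source reassemble to the source
  src <- simulate_repeat_free_sources(1L, c(40L, 40L), seed = 87L)
  reads <- simulate_reads(src, read_length = 20L, min_tile_overlap = 10L)
  cs <- assemble(collapse_reads(reads))
  expect_length(cs, 1L)
  expect_equal(cs[[1]]$sequence, src)
})

test_that("repeat-free sources have no cross overlaps or containment", {
  src <- simulate_repeat_free_sources(12L, c(20L, 60L), min_overlap = 5L,
                                      seed = 89L)
  expect_length(src, 12L)
  for (i in seq_along(src)) for (j in seq_along(src)) {
    if (i == j) next
    expect_lt(oracle_overlap_len(src[i], src[j]), 5L)
    expect_false(grepl(src[i], src[j], fixed = TRUE))
  }
})

test_that("the benchmark is balanced with disjoint train/test splits", {
  bm <- make_benchmark(seed = 91L, n_positive = 40L, n_negative = 40L)
  expect_equal(sum(bm$train$label == "miRNA"), 40L)
  expect_equal(sum(bm$train$label == "non-miRNA"), 40L)
  expect_equal(nrow(bm$test), 80L)
  expect_length(intersect(paste(bm$train$top, bm$train$bottom),
                          paste(bm$test$top, bm$test$bottom)), 0L)
})

test_that("positive and negative length distributions differ as configured", {
  spec <- duplex_spec(n_positive = 500L, n_negative = 500L, seed = 93L)
  dx <- simulate_duplexes(spec)
  lp <- nchar(dx$pattern[dx$label == "miRNA"])
  ln <- nchar(dx$pattern[dx$label == "non-miRNA"])
  ks <- suppressWarnings(stats::ks.test(lp, ln))
  expect_lt(ks$p.value, 0.01)
})

test_that("the planted library is overlap-free and carries its ground truth", {
  lib <- make_planted_library(seed = 95L, n_positive = 4L, n_decoy = 4L)
  expect_equal(sum(lib$duplexes$label == "miRNA"), 4L)
  expect_length(lib$arms, 16L)
  for (i in seq_along(lib$arms)) for (j in seq_along(lib$arms)) {
    if (i != j) expect_lt(oracle_overlap_len(lib$arms[[i]], lib$arms[[j]]), 5L)
  }
  expect_true(all(table(sub("_t\\d+$", "", lib$reads$id)) >= 1L))
})
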