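# Transition-probability profiles, pattern scoring and featurization.

test_that("a single training pattern gives probability-1 cells at pc = 0", {
  pr <- build_profiles("MMXMX", pseudocount = 0, min_support = 1L)
  expect_length(pr, 1L)
  m <- pr$L5$matrices$XX
  expect_equal(m[3, 5], 1) # the only X at position 3 is followed by X at 5
  expect_true(all(is.na(m[lower.tri(m, diag = TRUE)])))
})

test_that("absent states are smoothed to the pseudocount floor", {
  pr <- build_profiles(c("MMXMXM", "MMXMMX", "MXXMMM", "MMXXMM", "MXMMXM"),
                       pseudocount = 0.5, min_support = 1L)
  ii <- pr$L6$matrices$II
  vals <- ii[upper.tri(ii)]
  expect_true(all(vals == 0.5 / (0 + 5 * 0.5))) # no insertions anywhere
  # all stored probabilities are in [0, 1]
  for (m in pr$L6$matrices) {
    expect_true(all(m[upper.tri(m)] >= 0 & m[upper.tri(m)] <= 1))
  }
})

test_that("clusters are formed by exact length and small ones merge", {
  pats <- c(rep("MMMMMXMMMM", 6), rep("MMXMMMMMMMMM", 6), "MMXMMMMMM")
  pr <- build_profiles(pats, min_support = 5L)
  expect_setequal(names(pr), c("L10", "L12"))
  # the lone 9-mer merged into the nearest cluster (L10)
  expect_equal(pr$L10$support, 7L)
})

test_that("score_pattern follows the max-over-prior-states rule", {
  # all-M patterns score zero everywhere
  pr <- build_profiles(c("MXMMX", "MXMMX"), min_support = 1L)
  s0 <- score_pattern("MMMMM", pr$L5)
  expect_equal(s0$matrix_score, 0)
  expect_equal(s0$positional, rep(0, 5))
  # position 2 has no earlier non-M state -> 0; position 5 scores cell (2,5)
  s1 <- score_pattern("MXMMX", pr$L5)
  expect_equal(s1$positional[2], 0)
  expect_equal(s1$positional[5], pr$L5$matrices$XX[2, 5])
  expect_equal(s1$matrix_score, sum(s1$positional))
  # cross-family transition X..I uses the XI matrix in either order
  pr2 <- build_profiles(c("MXMMMIM", "MXMMMIM"), min_support = 1L)
  s2 <- score_pattern("MXMMMIM", pr2$L7)
  expect_equal(s2$positional[6], pr2$L7$matrices$XI[2, 6])
  # insertion <-> deletion has no subprofile and contributes 0
  pr3 <- build_profiles(c("MIMMDMM", "MIMMDMM"), min_support = 1L)
  s3 <- score_pattern("MIMMDMM", pr3$L7)
  expect_equal(s3$positional[5], 0)
  expect_error(score_pattern("MZM", pr$L5), "states")
})

test_that("score_pattern matches the brute-force oracle on random patterns", {
  set.seed(41)
  for (L in c(12L, 20L)) {
    train <- replicate(40, rand_pattern(L))
    pr <- build_profiles(train, min_support = 1L)
    prof <- pr[[sprintf("L%d", L)]]
    for (i in 1:250) {
      p <- rand_pattern(L)
      got <- score_pattern(p, prof)
      want <- oracle_score_pattern(p, prof)
      expect_equal(got$matrix_score, want$matrix_score, info = p)
      expect_equal(got$positional, want$positional, info = p)
    }
  }
})

test_that("featurize picks the representative profile by maximal score", {
  train21 <- replicate(30, rand_pattern(21L, c(M = .6, X = .3, I = .05, D = .05)))
  train22 <- replicate(30, rand_pattern(22L, c(M = .9, X = .1, I = 0, D = 0)))
  pr <- build_profiles(c(train21, train22), min_support = 5L)
  f <- featurize(train21[1L], pr)
  ms21 <- score_pattern(train21[1L], pr$L21)$matrix_score
  ms22 <- score_pattern(train21[1L], pr$L22)$matrix_score
  expect_equal(f$cluster, if (ms21 >= ms22) "L21" else "L22")
  expect_equal(f$rscore, max(ms21, ms22))
  expect_length(f$values, pr[[f$cluster]]$length)
  # all-M pattern: zero everywhere, deterministic tie-break
  f0 <- featurize(strrep("M", 21), pr)
  expect_equal(f0$rscore, 0)
  # far-off lengths are routed to the nearest cluster and flagged
  f1 <- featurize(rand_pattern(30L), pr)
  expect_true(f1$flagged)
  expect_equal(f1$cluster, "L22")
})

test_that("positive-model patterns outscore their state-shuffled versions", {
  # the discrimination the profiles are built to capture: structured state
  # co-occurrence scores higher than the same composition at random positions
  wins <- 0L
  for (rep in 1:20) {
    set.seed(100 + rep)
    spec <- duplex_spec(seed = 100 + rep)
    train <- replicate(200, paste(duplexmir:::sample_positive_pattern(spec),
                                  collapse = ""))
    fresh <- replicate(200, paste(duplexmir:::sample_positive_pattern(spec),
                                  collapse = ""))
    shuf <- vapply(fresh, function(p) {
      paste(sample(strsplit(p, "")[[1L]]), collapse = "")
    }, "")
    pr <- build_profiles(train)
    rs <- function(ps) mean(vapply(ps, function(p) featurize(p, pr)$rscore, 1))
    if (rs(fresh) > rs(shuf)) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("profiles survive a JSON round trip", {
  train <- replicate(12, rand_pattern(18L))
  pr <- build_profiles(train)
  path <- withr::local_tempfile(fileext = ".json")
  write_profiles_json(pr, path)
  back <- read_profiles_json(path)
  expect_equal(length(back), length(pr))
  for (nm in names(pr)) {
    expect_equal(back[[nm]]$length, pr[[nm]]$length)
    expect_equal(back[[nm]]$support, pr[[nm]]$support)
    for (f in names(pr[[nm]]$matrices)) {
      expect_equal(back[[nm]]$matrices[[f]], pr[[nm]]$matrices[[f]])
    }
  }
  p <- rand_pattern(18L)
  expect_equal(featurize(p, back)$rscore, featurize(p, pr)$rscore)
})
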