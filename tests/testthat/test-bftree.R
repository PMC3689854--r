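# Best-First tree: Gini splitting, best-first expansion, CV post-pruning.

test_that("separable 1-D data gets one pure split at the midpoint", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  y <- factor(c("neg", "neg", "pos", "pos"), levels = c("neg", "pos"))
  tr <- bftree(x, y)
  expect_equal(tr$n_expansions, 1L)
  expect_equal(tr$nodes[[1L]]$threshold, 5.5)
  expect_equal(as.character(predict(tr, x)), as.character(y))
})

test_that("pure and degenerate nodes stay leaves", {
  x <- matrix(rnorm(10), ncol = 2)
  y <- factor(rep("pos", 5))
  tr <- bftree(x, y)
  expect_equal(tr$n_expansions, 0L)
  # constant features with mixed labels: single majority leaf
  x2 <- matrix(1, nrow = 6, ncol = 2)
  y2 <- factor(c(rep("neg", 4), rep("pos", 2)), levels = c("neg", "pos"))
  tr2 <- bftree(x2, y2)
  expect_equal(tr2$n_expansions, 0L)
  expect_equal(as.character(predict(tr2, x2[1, , drop = FALSE])), "neg")
})

test_that("XOR-like data is resolved by a two-level tree", {
  # slightly imbalanced so the first split has positive Gini gain
  x <- matrix(c(0, 0, 1, 1, 1,
                0, 1, 0, 1, 1), ncol = 2)
  y <- factor(c("neg", "pos", "pos", "neg", "neg"), levels = c("neg", "pos"))
  tr <- bftree(x, y, min_leaf = 1L)
  expect_gte(tr$n_expansions, 2L)
  expect_equal(as.character(predict(tr, x)), as.character(y))
  depths <- vapply(tr$nodes, `[[`, 0L, "depth")
  expect_gte(max(depths), 2L)
})

test_that("the root split matches exhaustive enumeration on tiny data", {
  set.seed(51)
  for (trial in 1:200) {
    n <- sample(4:6, 1)
    p <- sample(1:3, 1)
    x <- matrix(sample(0:4, n * p, replace = TRUE) + 0, ncol = p)
    y <- factor(sample(c("neg", "pos"), n, replace = TRUE),
                levels = c("neg", "pos"))
    w <- sample(1:3, n, replace = TRUE) + 0
    want <- oracle_best_split(x, y == "pos", w, min_leaf = 1L)
    tr <- bftree(x, y, weights = w, min_leaf = 1L, max_expansions = 1L)
    if (is.null(want) || length(unique(y)) < 2L) {
      expect_equal(tr$n_expansions, 0L)
    } else {
      expect_equal(tr$n_expansions, 1L)
      expect_equal(tr$nodes[[1L]]$feature, want$feature)
      expect_equal(tr$nodes[[1L]]$threshold, want$threshold)
    }
  }
})

test_that("noise-free separable data keeps its tree after pruning", {
  set.seed(53)
  x <- matrix(rnorm(60), ncol = 2)
  y <- factor(ifelse(x[, 1] > 0, "pos", "neg"), levels = c("neg", "pos"))
  tr <- bftree(x, y)
  pr <- prune_bftree(tr, x, y, folds = 5L, seed = 1L)
  expect_equal(as.character(predict(pr, x)), as.character(y))
  expect_gte(pr$pruned_to, 1L)
})

test_that("pure-noise labels prune to the root leaf", {
  set.seed(55)
  x <- matrix(rnorm(200), ncol = 2)
  y <- factor(sample(c("neg", "pos"), 100, replace = TRUE),
              levels = c("neg", "pos"))
  tr <- bftree(x, y, min_leaf = 1L)
  expect_gt(tr$n_expansions, 0L) # the unpruned tree memorizes noise
  pr <- prune_bftree(tr, x, y, folds = 5L, seed = 1L)
  expect_equal(pr$pruned_to, 0L)
})

test_that("pruning never grows a tree and handles tiny inputs", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  y <- factor(c("neg", "neg", "pos", "pos"), levels = c("neg", "pos"))
  tr <- bftree(x, y)
  expect_warning(pr <- prune_bftree(tr, x, y, folds = 5L, seed = 1L),
                 "too few")
  expect_identical(pr$pruned_to, tr$pruned_to)
  set.seed(57)
  x2 <- matrix(c(rnorm(10, 0), rnorm(10, 4)), ncol = 1)
  y2 <- factor(rep(c("neg", "pos"), each = 10), levels = c("neg", "pos"))
  tr2 <- bftree(x2, y2)
  pr2 <- prune_bftree(tr2, x2, y2, folds = 5L, seed = 2L)
  expect_lte(pr2$pruned_to, tr2$n_expansions)
})

test_that("weighted fitting shifts the decision toward heavy instances", {
  x <- matrix(c(0, 1, 2, 3), ncol = 1)
  y <- factor(c("neg", "neg", "pos", "pos"), levels = c("neg", "pos"))
  # huge weight on a mislabeled-looking point dominates the leaf majority
  w <- c(1, 1, 100, 1)
  tr <- bftree(x, y, weights = w, min_leaf = 1L)
  expect_equal(as.character(predict(tr, matrix(2))), "pos")
})
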