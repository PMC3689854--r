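# MultiBoost ensemble: reweighting algebra, vote aggregation, determinism,
# and the evaluation metrics.

make_sep_data <- function(n = 100, seed = 1) {
  # linearly separable with a wide margin on the first feature
  set.seed(seed)
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  x <- cbind(sgn * runif(n, 0.5, 2), rnorm(n))
  y <- factor(ifelse(sgn > 0, "miRNA", "non-miRNA"),
              levels = c("non-miRNA", "miRNA"))
  list(x = x, y = y)
}

test_that("reweighting conserves total instance weight", {
  # the x1/(2e), x1/(2(1-e)) rules are exactly mass-conserving:
  # e*n/(2e) + (1-e)*n/(2(1-e)) = n
  set.seed(61)
  n <- 120
  x <- matrix(rnorm(2 * n), ncol = 2)
  y <- factor(ifelse(x[, 1] + rnorm(n, sd = 1.2) > 0, "miRNA", "non-miRNA"),
              levels = c("non-miRNA", "miRNA"))
  mb <- multiboost(x, y, K = 40L, seed = 3L, max_expansions = 3L)
  expect_lt(mb$weight_drift_raw, 1e-9)
  expect_lt(mb$weight_drift, 1e-9)
})

test_that("a zero-error first tree receives the capped vote weight", {
  d <- make_sep_data(80, seed = 5)
  mb <- multiboost(d$x, d$y, K = 30L, seed = 11L)
  expect_equal(mb$votes[1L], log(1e10))
  held <- make_sep_data(80, seed = 6)
  expect_equal(mean(predict(mb, held$x) != held$y), 0)
})

test_that("subcommittee boundaries follow ceil(sqrt(K)) equal blocks", {
  d <- make_sep_data(40, seed = 7)
  mb <- multiboost(d$x, d$y, K = 100L, seed = 1L)
  expect_equal(mb$boundaries, as.integer(ceiling((1:10) * 10)))
  mb2 <- multiboost(d$x, d$y, K = 30L, seed = 1L)
  expect_equal(length(mb2$boundaries), ceiling(sqrt(30)))
})

test_that("prediction equals a brute-force vote tally", {
  set.seed(63)
  n <- 60
  x <- matrix(rnorm(3 * n), ncol = 3)
  y <- factor(ifelse(x[, 1] + rnorm(n) > 0, "miRNA", "non-miRNA"),
              levels = c("non-miRNA", "miRNA"))
  mb <- multiboost(x, y, K = 12L, seed = 2L, max_expansions = 4L)
  newx <- matrix(rnorm(3 * 20), ncol = 3)
  wpos <- numeric(20)
  for (k in seq_along(mb$trees)) {
    wpos <- wpos + mb$votes[k] * (predict(mb$trees[[k]], newx) == "miRNA")
  }
  total <- sum(mb$votes)
  want <- ifelse(wpos / total > 0.5, "miRNA",
                 ifelse(wpos / total < 0.5, "non-miRNA",
                        if (mb$priors[2] > mb$priors[1]) "miRNA" else "non-miRNA"))
  expect_equal(as.character(predict(mb, newx)), unname(want))
  expect_equal(predict(mb, newx, type = "positive"), wpos / total)
  expect_equal(predict(mb, newx, type = "score"),
               pmax(wpos / total, 1 - wpos / total))
})

test_that("vote ties break to the higher prior, then the negative class", {
  leaf_tree <- function(cls) {
    x <- matrix(c(0, 1), ncol = 1)
    y <- factor(c(cls, cls), levels = c("non-miRNA", "miRNA"))
    bftree(x, y, max_expansions = 0L)
  }
  stub <- structure(list(
    trees = list(leaf_tree("miRNA"), leaf_tree("non-miRNA")),
    votes = c(2, 2), boundaries = integer(0), K = 2L, seed = 1L,
    levels = c("non-miRNA", "miRNA"), priors = c(0.5, 0.5),
    weight_drift = 0, weight_drift_raw = 0), class = "multiboost")
  expect_equal(as.character(predict(stub, matrix(0))), "non-miRNA")
  stub$priors <- c(0.3, 0.7)
  expect_equal(as.character(predict(stub, matrix(0))), "miRNA")
  # unanimous votes give score 1 regardless of vote weights
  stub$trees <- list(leaf_tree("miRNA"), leaf_tree("miRNA"))
  stub$votes <- c(5, 0.1)
  expect_equal(predict(stub, matrix(0), type = "score"), 1)
})

test_that("training is deterministic for a fixed seed", {
  set.seed(65)
  n <- 80
  x <- matrix(rnorm(2 * n), ncol = 2)
  y <- factor(ifelse(x[, 1] + rnorm(n, sd = .8) > 0, "miRNA", "non-miRNA"),
              levels = c("non-miRNA", "miRNA"))
  m1 <- multiboost(x, y, K = 20L, seed = 9L)
  m2 <- multiboost(x, y, K = 20L, seed = 9L)
  expect_identical(m1, m2)
  m3 <- multiboost(x, y, K = 20L, seed = 10L)
  expect_false(identical(m1$votes, m3$votes))
})

test_that("single-class input degrades to a majority-leaf model", {
  x <- matrix(rnorm(10), ncol = 2)
  y <- factor(rep("miRNA", 5))
  expect_warning(mb <- multiboost(x, y, K = 10L), "single-class")
  expect_equal(as.character(predict(mb, x)[1]), "miRNA")
})

test_that("evaluation metrics reach their maxima on perfect separation", {
  truth <- rep(c("miRNA", "non-miRNA"), each = 10)
  scores <- c(runif(10, .8, 1), runif(10, 0, .2))
  ev <- evaluate_predictions(truth, truth, scores)
  expect_equal(ev$sensitivity, 100)
  expect_equal(ev$specificity, 100)
  expect_equal(ev$accuracy, 100)
  expect_equal(ev$mcc, 1)
  expect_equal(ev$auc, 1)
})

test_that("rank-based AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(67)
  truth <- sample(c("miRNA", "non-miRNA"), 200, replace = TRUE)
  scores <- rnorm(200) + (truth == "miRNA")
  ev <- evaluate_predictions(truth, truth, scores)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(truth, levels = c("non-miRNA", "miRNA")),
    predictor = scores, quiet = TRUE, direction = "<")))
  expect_equal(ev$auc, ref, tolerance = 1e-12)
})
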