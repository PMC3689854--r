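# MultiBoost: boosting with wagging. AdaBoost-style reweighting runs inside
# subcommittees; at each subcommittee boundary the instance weights are reset
# to draws from a continuous Poisson approximation (w = -ln U, U ~ Uniform)
# and rescaled to sum to n. The final class is the one with the highest summed
# vote weight across all retained base trees.

VOTE_BETA_CAP <- 1e-10 # vote weight for a zero-error tree: log(1/beta)
WEIGHT_FLOOR <- 1e-8
E_HIGH_RETRIES <- 3L

#' Fit a MultiBoost ensemble of Best-First trees
#'
#' Implements boosting with wagging: instance weights start uniform (summing
#' to n); at each subcommittee termination point (\code{ceiling(sqrt(K))}
#' equal subcommittees by default) they are reset to continuous-Poisson draws
#' rescaled to n. Each iteration fits a weighted Best-First tree; with
#' weighted error e the tree receives vote weight \code{log((1 - e)/e)}
#' (capped at \code{log(1/1e-10)} when e = 0), misclassified instances are
#' reweighted by 1/(2e) and correct ones by 1/(2(1 - e)) (floored at 1e-8 and
#' rescaled to n). A tree with e > 0.5 triggers a wagging reset and refit,
#' at most 3 times before the committee stops early.
#'
#' @param x numeric feature matrix.
#' @param y two-level factor (second level = positive class).
#' @param K number of boosting iterations (conventional range 30-100;
#'   default 100).
#' @param seed RNG seed for the wagging draws.
#' @param min_leaf,max_expansions base-learner controls (base trees are kept
#'   small, default 20 expansions, as is conventional for boosted learners).
#' @param subcommittees number of subcommittees (default
#'   \code{ceiling(sqrt(K))}).
#' @return object of class \code{multiboost}: trees, vote weights,
#'   subcommittee boundaries, class priors, and the maximum deviation of the
#'   instance-weight sum from n observed after every reweighting
#'   (\code{weight_drift}, \code{weight_drift_raw}).
#' @export
multiboost <- function(x, y, K = 100L, seed = 1L, min_leaf = 2L,
                       max_expansions = 20L,
                       subcommittees = ceiling(sqrt(K))) {
  stopifnot(K >= 1L)
  x <- as.matrix(x)
  y <- as.factor(y)
  lev <- levels(y)
  if (length(lev) != 2L) {
    warning("single-class training data: returning a majority-leaf model")
    tree <- bftree(x, y, min_leaf = min_leaf, max_expansions = 0L)
    return(structure(list(trees = list(tree), votes = 1,
                          boundaries = integer(0), K = K, seed = seed,
                          levels = tree$levels,
                          priors = c(1, 0), weight_drift = 0,
                          weight_drift_raw = 0),
                     class = "multiboost"))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- nrow(x)
  s <- max(1L, as.integer(subcommittees))
  boundaries <- ceiling(seq_len(s) * K / s)
  w <- rep(1, n)
  wag_reset <- function() {
    u <- stats::runif(n)
    u[u <= 0] <- .Machine$double.eps
    ww <- -log(u)
    ww * n / sum(ww)
  }
  trees <- list()
  votes <- numeric(0)
  drift <- 0
  drift_raw <- 0
  i_sub <- 1L
  stopped <- FALSE
  for (t in seq_len(K)) {
    if (i_sub <= s && t == boundaries[i_sub]) {
      w <- wag_reset()
      i_sub <- i_sub + 1L
    }
    retries <- 0L
    repeat {
      tree <- bftree(x, y, weights = w, min_leaf = min_leaf,
                     max_expansions = max_expansions)
      pred <- predict(tree, x)
      mis <- pred != y
      e <- sum(w[mis]) / n
      if (e <= 0.5) break
      retries <- retries + 1L
      if (retries > E_HIGH_RETRIES) { stopped <- TRUE; break }
      w <- wag_reset()
      i_sub <- i_sub + 1L
    }
    if (stopped) break
    if (e <= 0) {
      vote <- log(1 / VOTE_BETA_CAP)
      trees[[length(trees) + 1L]] <- tree
      votes <- c(votes, vote)
      w <- wag_reset()
      i_sub <- i_sub + 1L
    } else {
      vote <- log((1 - e) / e)
      trees[[length(trees) + 1L]] <- tree
      votes <- c(votes, vote)
      w[mis] <- w[mis] / (2 * e)
      w[!mis] <- w[!mis] / (2 * (1 - e))
      drift_raw <- max(drift_raw, abs(sum(w) - n))
      w <- pmax(w, WEIGHT_FLOOR)
      w <- w * n / sum(w)
      drift <- max(drift, abs(sum(w) - n))
    }
  }
  if (!length(trees)) {
    warning("no usable base tree: returning a majority-leaf model")
    tree <- bftree(x, y, min_leaf = min_leaf, max_expansions = 0L)
    trees <- list(tree)
    votes <- 1
  }
  structure(list(trees = trees, votes = votes, boundaries = boundaries,
                 K = K, seed = seed, levels = lev,
                 priors = as.numeric(prop.table(table(y))),
                 weight_drift = drift, weight_drift_raw = drift_raw),
            class = "multiboost")
}

#' Predict from a MultiBoost ensemble
#'
#' The predicted class maximizes the summed vote weight; ties go to the class
#' with the higher training prior, then to the negative (first) level. The
#' score is the winning class's share of the total vote weight, in [0.5, 1]
#' for binary problems.
#'
#' @param object a \code{multiboost}.
#' @param newdata numeric feature matrix.
#' @param type "class", "score" (winning share) or "positive" (share of the
#'   positive, second level -- a monotone ranking score for ROC analysis).
#' @param ... unused.
#' @return factor, or numeric vector.
#' @export
predict.multiboost <- function(object, newdata,
                               type = c("class", "score", "positive"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  n <- nrow(newdata)
  wpos <- numeric(n)
  total <- sum(object$votes)
  for (k in seq_along(object$trees)) {
    cls <- predict(object$trees[[k]], newdata)
    wpos <- wpos + object$votes[k] * (cls == object$levels[2L])
  }
  share_pos <- if (total > 0) wpos / total else rep(0.5, n)
  if (type == "positive") return(share_pos)
  pick <- ifelse(share_pos > 0.5, 2L,
                 ifelse(share_pos < 0.5, 1L,
                        # tie: higher prior, then the negative (first) level
                        if (object$priors[2L] > object$priors[1L]) 2L else 1L))
  if (type == "class") {
    factor(object$levels[pick], levels = object$levels)
  } else {
    pmax(share_pos, 1 - share_pos)
  }
}

#' @export
print.multiboost <- function(x, ...) {
  cat(sprintf("MultiBoost ensemble: %d trees (K=%d, %d subcommittees), seed %d\n",
              length(x$trees), x$K, length(x$boundaries), x$seed))
  cat(sprintf("  max |sum(w) - n| after reweighting: %.3g\n", x$weight_drift_raw))
  invisible(x)
}

#' Classification performance metrics
#'
#' Sensitivity, specificity and accuracy (percent), Matthews correlation
#' coefficient, and rank-based AUC (equivalent to the trapezoidal area under
#' the ROC curve, ties handled as 0.5).
#'
#' @param truth factor/character of true labels.
#' @param predicted factor/character of predicted labels.
#' @param scores numeric ranking scores for the positive class (optional; AUC
#'   is NA without them).
#' @param positive label of the positive class.
#' @return named list: sensitivity, specificity, accuracy, mcc, auc.
#' @export
evaluate_predictions <- function(truth, predicted, scores = NULL,
                                 positive = "miRNA") {
  truth_pos <- truth == positive
  pred_pos <- predicted == positive
  tp <- sum(truth_pos & pred_pos)
  tn <- sum(!truth_pos & !pred_pos)
  fp <- sum(!truth_pos & pred_pos)
  fn <- sum(truth_pos & !pred_pos)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  acc <- 100 * (tp + tn) / length(truth)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else NA_real_
  auc <- NA_real_
  if (!is.null(scores) && any(truth_pos) && any(!truth_pos)) {
    r <- rank(scores)
    n1 <- sum(truth_pos)
    n0 <- sum(!truth_pos)
    auc <- (sum(r[truth_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(sensitivity = sens, specificity = spec, accuracy = acc,
       mcc = mcc, auc = auc)
}
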