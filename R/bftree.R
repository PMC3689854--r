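# Best-First decision tree: a binary tree grown by repeatedly expanding the
# frontier leaf with the largest weighted Gini gain, with post-pruning by
# k-fold cross-validation over the number of best-first expansions.

# Weighted Gini impurity mass of a node: W * (1 - sum_k (w_k/W)^2).
gini_mass <- function(w_pos, w_neg) {
  W <- w_pos + w_neg
  if (W <= 0) return(0)
  W * (1 - (w_pos / W)^2 - (w_neg / W)^2)
}

# Best (feature, threshold) binary split of the instances in `idx`.
# Candidate thresholds are midpoints between consecutive distinct sorted
# feature values; both children must hold at least `min_leaf` instances.
# Returns NULL when no split has positive gain.
best_split <- function(x, y_pos, w, idx, min_leaf) {
  n <- length(idx)
  if (n < 2L * min_leaf) return(NULL)
  wp <- sum(w[idx][y_pos[idx]])
  wn <- sum(w[idx][!y_pos[idx]])
  parent <- gini_mass(wp, wn)
  if (parent <= 0) return(NULL)
  best <- NULL
  for (f in seq_len(ncol(x))) {
    v <- x[idx, f]
    ord <- order(v, method = "radix")
    vs <- v[ord]
    ws <- w[idx][ord]
    ys <- y_pos[idx][ord]
    cut_ok <- which(diff(vs) > 0)
    cut_ok <- cut_ok[cut_ok >= min_leaf & (n - cut_ok) >= min_leaf]
    if (!length(cut_ok)) next
    cwp <- cumsum(ws * ys)
    cwn <- cumsum(ws * !ys)
    lp <- cwp[cut_ok]; ln <- cwn[cut_ok]
    rp <- wp - lp; rn <- wn - ln
    WL <- lp + ln; WR <- rp + rn
    child <- WL * (1 - (lp / WL)^2 - (ln / WL)^2) +
      WR * (1 - (rp / WR)^2 - (rn / WR)^2)
    gains <- parent - child
    # earliest (smallest threshold) among ties, robust to float noise
    k <- which(gains >= max(gains) - 1e-9)[1L]
    if (gains[k] > 1e-9 &&
        (is.null(best) || gains[k] > best$gain + 1e-9)) {
      best <- list(feature = f,
                   threshold = (vs[cut_ok[k]] + vs[cut_ok[k] + 1L]) / 2,
                   gain = gains[k])
    }
  }
  best
}

#' Fit a Best-First decision tree
#'
#' Binary splits on numeric features; node purity is measured by the Gini
#' index and the frontier leaf with the largest weighted Gini gain is expanded
#' first. A leaf stops at purity 1, when fewer than \code{2 * min_leaf}
#' instances remain, or when no split has positive gain. Instance weights
#' enter all counts. The expansion order is recorded so the tree can be
#' truncated to its first k expansions (used by CV pruning and by boosting).
#'
#' @param x numeric feature matrix.
#' @param y two-level factor of class labels.
#' @param weights positive instance weights (default 1).
#' @param min_leaf minimum instances per leaf (default 2).
#' @param max_expansions cap on best-first expansions (default Inf).
#' @return object of class \code{bftree}.
#' @export
bftree <- function(x, y, weights = NULL, min_leaf = 2L, max_expansions = Inf) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(y) > 2L) stop("bftree supports binary classification only")
  if (is.null(weights)) weights <- rep(1, nrow(x))
  stopifnot(length(weights) == nrow(x), all(weights > 0))
  lev <- levels(y)
  if (length(lev) == 1L) lev <- c(lev, ".other")
  y_pos <- y == lev[2L]
  nodes <- list()
  new_node <- function(idx, depth) {
    wp <- sum(weights[idx][y_pos[idx]])
    wn <- sum(weights[idx][!y_pos[idx]])
    list(idx = idx, depth = depth, w_pos = wp, w_neg = wn,
         n = length(idx), feature = NA_integer_, threshold = NA_real_,
         left = NA_integer_, right = NA_integer_,
         expansion_rank = NA_integer_)
  }
  nodes[[1L]] <- new_node(seq_len(nrow(x)), 0L)
  # frontier: node id -> candidate split (or NULL)
  frontier_ids <- 1L
  frontier_splits <- list(best_split(x, y_pos, weights, nodes[[1L]]$idx,
                                     min_leaf))
  rank <- 0L
  while (rank < max_expansions) {
    gains <- vapply(frontier_splits, function(s) {
      if (is.null(s)) -Inf else s$gain
    }, numeric(1L))
    if (!length(gains) || max(gains) <= 0) break
    # largest gain; ties -> smaller feature, smaller threshold, older node
    ord <- order(-gains,
                 vapply(frontier_splits, function(s) {
                   if (is.null(s)) Inf else s$feature
                 }, numeric(1L)),
                 vapply(frontier_splits, function(s) {
                   if (is.null(s)) Inf else s$threshold
                 }, numeric(1L)),
                 frontier_ids)
    pick <- ord[1L]
    nid <- frontier_ids[pick]
    sp <- frontier_splits[[pick]]
    rank <- rank + 1L
    idx <- nodes[[nid]]$idx
    go_left <- x[idx, sp$feature] <= sp$threshold
    lid <- length(nodes) + 1L
    rid <- length(nodes) + 2L
    nodes[[lid]] <- new_node(idx[go_left], nodes[[nid]]$depth + 1L)
    nodes[[rid]] <- new_node(idx[!go_left], nodes[[nid]]$depth + 1L)
    nodes[[nid]]$feature <- sp$feature
    nodes[[nid]]$threshold <- sp$threshold
    nodes[[nid]]$left <- lid
    nodes[[nid]]$right <- rid
    nodes[[nid]]$expansion_rank <- rank
    frontier_ids <- c(frontier_ids[-pick], lid, rid)
    frontier_splits <- c(frontier_splits[-pick],
                         list(best_split(x, y_pos, weights, nodes[[lid]]$idx,
                                         min_leaf),
                              best_split(x, y_pos, weights, nodes[[rid]]$idx,
                                         min_leaf)))
  }
  nodes <- lapply(nodes, function(nd) { nd$idx <- NULL; nd })
  structure(list(nodes = nodes, levels = lev, n_expansions = rank,
                 min_leaf = min_leaf, pruned_to = NA_integer_),
            class = "bftree")
}

# class index (1/2 into levels) at a node; weighted majority, tie -> first
# (negative) level
node_class <- function(nd) if (nd$w_pos > nd$w_neg) 2L else 1L

#' Predict from a Best-First tree
#'
#' @param object a \code{bftree}.
#' @param newdata numeric feature matrix.
#' @param k use only the first k best-first expansions (default: the pruned
#'   size if set, else the full tree).
#' @param type "class" or "prob" (weighted share of the positive level).
#' @param ... unused.
#' @return factor of classes, or numeric vector of probabilities.
#' @export
predict.bftree <- function(object, newdata, k = NULL,
                           type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (is.null(k)) {
    k <- if (is.na(object$pruned_to)) object$n_expansions else object$pruned_to
  }
  nodes <- object$nodes
  out_cls <- integer(nrow(newdata))
  out_p <- numeric(nrow(newdata))
  for (r in seq_len(nrow(newdata))) {
    nid <- 1L
    repeat {
      nd <- nodes[[nid]]
      if (is.na(nd$expansion_rank) || nd$expansion_rank > k) break
      nid <- if (newdata[r, nd$feature] <= nd$threshold) nd$left else nd$right
    }
    nd <- nodes[[nid]]
    out_cls[r] <- node_class(nd)
    W <- nd$w_pos + nd$w_neg
    out_p[r] <- if (W > 0) nd$w_pos / W else 0.5
  }
  if (type == "class") factor(object$levels[out_cls], levels = object$levels)
  else out_p
}

#' @export
print.bftree <- function(x, ...) {
  k <- if (is.na(x$pruned_to)) x$n_expansions else x$pruned_to
  cat(sprintf("Best-First tree: %d expansions grown, %d in use (%s)\n",
              x$n_expansions, k,
              if (is.na(x$pruned_to)) "unpruned" else "CV-pruned"))
  invisible(x)
}

#' Post-prune a Best-First tree by cross-validation
#'
#' Truncation depths are examined on a geometric ladder of best-first
#' expansion counts (0, 1, 2, 3, 5, 8, ... up to the full tree). Seeded
#' k-fold cross-validation records a per-instance misclassification loss for
#' each depth, and the tree is cut at the SHORTEST depth whose mean CV loss is
#' not significantly worse than the CV minimizer's (paired comparison,
#' \code{z} standard errors of the per-instance loss difference). This is the
#' shortest-tree reading of CV post-pruning: a depth must beat shorter ones by
#' more than its selection noise to be kept.
#'
#' @param tree a \code{bftree} fitted on \code{x}, \code{y}.
#' @param x,y,weights the training data the tree was fitted on.
#' @param folds number of CV folds (default 5).
#' @param seed seed for the fold assignment.
#' @param z significance multiple for the paired loss comparison (default
#'   2.5).
#' @return the tree with \code{pruned_to} set.
#' @export
prune_bftree <- function(tree, x, y, weights = NULL, folds = 5L, seed = 1L,
                         z = 2.5) {
  stopifnot(folds >= 2L)
  x <- as.matrix(x)
  y <- factor(y, levels = tree$levels)
  n <- nrow(x)
  if (is.null(weights)) weights <- rep(1, n)
  if (n < 2L * folds) {
    warning("too few instances for ", folds, "-fold pruning; tree unpruned")
    return(tree)
  }
  kmax <- tree$n_expansions
  if (kmax == 0L) {
    tree$pruned_to <- 0L
    return(tree)
  }
  ks <- 0L
  k <- 1L
  while (k <= kmax) {
    ks <- c(ks, k)
    k <- as.integer(ceiling(k * 1.5))
  }
  ks <- unique(c(ks, kmax))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  loss <- matrix(NA_real_, n, length(ks))
  for (f in seq_len(folds)) {
    te <- fold_id == f
    ft <- bftree(x[!te, , drop = FALSE], y[!te], weights[!te],
                 min_leaf = tree$min_leaf)
    for (ki in seq_along(ks)) {
      kk <- min(ks[ki], ft$n_expansions)
      pred <- predict(ft, x[te, , drop = FALSE], k = kk)
      loss[te, ki] <- as.numeric(pred != y[te])
    }
  }
  wsum <- sum(weights)
  me <- colSums(loss * weights) / wsum
  k_min <- which.min(me)
  keep <- which(vapply(seq_along(ks), function(ki) {
    d <- loss[, ki] - loss[, k_min]
    m <- sum(d * weights) / wsum
    sed <- stats::sd(d) / sqrt(n)
    m <= z * sed + 1e-12
  }, logical(1L)))[1L]
  tree$pruned_to <- min(ks[keep], kmax)
  tree
}
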