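# Top-level duplex classifier: aligns and encodes labelled duplex arm pairs,
# builds transition profiles from the positive class, featurizes both classes,
# and trains one MultiBoost ensemble per length cluster.

POSITIVE_LABEL <- "miRNA"
NEGATIVE_LABEL <- "non-miRNA"

# align + encode a data.frame of arm pairs (columns top, bottom)
encode_arm_pairs <- function(duplexes, scheme, workers = 1L) {
  items <- seq_len(nrow(duplexes))
  parallel_map(items, function(i) {
    d <- complement_align(duplexes$top[i], duplexes$bottom[i], scheme)
    encode_duplex(d)
  }, workers = workers)
}

#' Fit the duplex classification model
#'
#' The model couples length-clustered transition profiles (built from the
#' positive instances' encoded patterns) with one MultiBoost ensemble per
#' cluster, trained on the positional transition-score feature vectors of both
#' classes. Clusters with fewer than \code{min_cluster_n} training instances
#' are not modelled; their instances are re-featurized against the modelled
#' clusters only (nearest admissible by profile score).
#'
#' @param duplexes data.frame with columns \code{top}, \code{bottom} (arm
#'   sequences 5'->3'), or a character vector of pre-encoded patterns.
#' @param labels factor/character: "miRNA" or "non-miRNA" per duplex.
#' @param config pipeline configuration, see \code{\link{default_config}}.
#' @param seed RNG seed for the per-cluster ensembles.
#' @return object of class \code{duplex_classifier}.
#' @export
duplex_classifier <- function(duplexes, labels, config = default_config(),
                              seed = config$seed) {
  labels <- as.character(labels)
  stopifnot(all(labels %in% c(POSITIVE_LABEL, NEGATIVE_LABEL)))
  scheme <- config_scheme(config)
  patterns <- if (is.character(duplexes)) duplexes
              else unlist(encode_arm_pairs(duplexes, scheme, config$workers))
  if (length(patterns) != length(labels)) stop("labels/duplexes length mismatch")
  pos <- labels == POSITIVE_LABEL
  if (!any(pos) || all(pos)) stop("both classes must be present for training")
  profiles <- build_profiles(patterns[pos], pseudocount = config$pseudocount,
                             min_support = config$min_support)
  feats <- lapply(patterns, featurize, profiles = profiles,
                  length_tolerance = config$length_tolerance)
  cl <- vapply(feats, `[[`, character(1L), "cluster")
  tab <- table(cl)
  modelled <- names(tab)[tab >= config$min_cluster_n]
  if (!length(modelled)) {
    stop("no length cluster reaches ", config$min_cluster_n,
         " training instances; provide more duplexes or lower min_cluster_n")
  }
  # instances in unmodelled clusters fall back to the modelled profiles
  fallback <- which(!cl %in% modelled)
  if (length(fallback)) {
    sub <- structure(profiles[modelled], class = "transition_profile_list")
    for (i in fallback) {
      feats[[i]] <- featurize(patterns[i], sub,
                              length_tolerance = config$length_tolerance)
      feats[[i]]$flagged <- TRUE
    }
    cl <- vapply(feats, `[[`, character(1L), "cluster")
  }
  models <- list()
  for (cname in sort(modelled)) {
    idx <- which(cl == cname)
    xm <- do.call(rbind, lapply(feats[idx], `[[`, "values"))
    ym <- factor(labels[idx], levels = c(NEGATIVE_LABEL, POSITIVE_LABEL))
    if (nlevels(droplevels(ym)) < 2L) {
      warning("cluster ", cname, " holds a single class; skipped")
      next
    }
    models[[cname]] <- multiboost(xm, ym, K = config$K,
                                  seed = seed + match(cname, sort(modelled)),
                                  min_leaf = config$min_leaf,
                                  max_expansions = config$base_max_expansions)
  }
  if (!length(models)) stop("no cluster could be modelled")
  structure(list(profiles = profiles, models = models,
                 modelled = names(models), config = config, seed = seed,
                 levels = c(NEGATIVE_LABEL, POSITIVE_LABEL),
                 n_train = length(patterns),
                 cluster_sizes = as.list(tab)),
            class = "duplex_classifier")
}

#' @export
print.duplex_classifier <- function(x, ...) {
  cat("duplex_classifier:", length(x$models), "length-cluster ensembles (",
      paste(names(x$models), collapse = ", "), ")\n")
  cat("  trained on", x$n_train, "duplexes, seed", x$seed, "\n")
  invisible(x)
}

#' Predict miRNA duplex class and score
#'
#' @param object a \code{duplex_classifier}.
#' @param newdata data.frame with \code{top}, \code{bottom} columns, or a
#'   character vector of encoded patterns.
#' @param ... unused.
#' @return data.frame: pattern, cluster, class, score (winning vote share),
#'   positive_score (vote share of the miRNA class), rscore, flagged.
#' @export
predict.duplex_classifier <- function(object, newdata, ...) {
  config <- object$config
  patterns <- if (is.character(newdata)) newdata
              else unlist(encode_arm_pairs(newdata, config_scheme(config),
                                           config$workers))
  sub <- structure(object$profiles[object$modelled],
                   class = "transition_profile_list")
  feats <- lapply(patterns, featurize, profiles = sub,
                  length_tolerance = config$length_tolerance)
  cl <- vapply(feats, `[[`, character(1L), "cluster")
  out <- data.frame(pattern = patterns, cluster = cl,
                    class = NA_character_, score = NA_real_,
                    positive_score = NA_real_,
                    rscore = vapply(feats, `[[`, numeric(1L), "rscore"),
                    flagged = vapply(feats, `[[`, logical(1L), "flagged"),
                    stringsAsFactors = FALSE)
  for (cname in unique(cl)) {
    idx <- which(cl == cname)
    model <- object$models[[cname]]
    xm <- do.call(rbind, lapply(feats[idx], `[[`, "values"))
    out$class[idx] <- as.character(predict(model, xm, type = "class"))
    out$score[idx] <- predict(model, xm, type = "score")
    out$positive_score[idx] <- predict(model, xm, type = "positive")
  }
  out
}

#' Classify candidate duplexes at a score threshold
#'
#' A duplex is called a miRNA iff the ensemble predicts the miRNA class and
#' its winning vote share reaches \code{threshold} (0.9 for novel discovery,
#' 0.5 for plain evaluation).
#'
#' @param duplexes a \code{duplex_list} (from \code{\link{select_duplexes}}),
#'   a data.frame with top/bottom columns, or encoded pattern strings.
#' @param model a \code{duplex_classifier}.
#' @param threshold vote-share cutoff in [0.5, 1].
#' @return data.frame of predictions with a logical \code{called} column.
#' @export
classify_duplexes <- function(duplexes, model, threshold = 0.9) {
  stopifnot(threshold >= 0.5, threshold <= 1)
  if (inherits(duplexes, "duplex_list")) {
    newdata <- vapply(duplexes, function(d) d$pattern %||% encode_duplex(d),
                      character(1L))
  } else {
    newdata <- duplexes
  }
  out <- predict(model, newdata)
  out$called <- out$class == POSITIVE_LABEL & out$score >= threshold
  out
}

# ---- model persistence -----------------------------------------------------

tree_to_list <- function(tree) {
  list(nodes = lapply(tree$nodes, function(nd) {
    nd[c("depth", "w_pos", "w_neg", "n", "feature", "threshold",
         "left", "right", "expansion_rank")]
  }), levels = tree$levels, n_expansions = tree$n_expansions,
  min_leaf = tree$min_leaf, pruned_to = tree$pruned_to)
}

tree_from_list <- function(lst) {
  nodes <- lapply(lst$nodes, function(nd) {
    nd$feature <- as_na_int(nd$feature)
    nd$left <- as_na_int(nd$left)
    nd$right <- as_na_int(nd$right)
    nd$expansion_rank <- as_na_int(nd$expansion_rank)
    nd$threshold <- if (is.null(nd$threshold)) NA_real_ else nd$threshold
    nd
  })
  structure(list(nodes = nodes, levels = unlist(lst$levels),
                 n_expansions = as.integer(lst$n_expansions),
                 min_leaf = as.integer(lst$min_leaf),
                 pruned_to = as_na_int(lst$pruned_to)),
            class = "bftree")
}

as_na_int <- function(x) if (is.null(x) || is.na(x)) NA_integer_ else as.integer(x)

#' Write a duplex classifier to versioned JSON
#' @param model a \code{duplex_classifier}.
#' @param path output file.
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    format = "duplexmir-model", version = 1L,
    seed = model$seed, levels = model$levels,
    config = model$config[order(names(model$config))],
    models = lapply(model$models, function(mb) {
      list(votes = mb$votes, boundaries = mb$boundaries, K = mb$K,
           seed = mb$seed, levels = mb$levels, priors = mb$priors,
           weight_drift = mb$weight_drift,
           weight_drift_raw = mb$weight_drift_raw,
           trees = lapply(mb$trees, tree_to_list))
    }),
    modelled = model$modelled, n_train = model$n_train,
    cluster_sizes = model$cluster_sizes)
  tmp_prof <- tempfile(fileext = ".json")
  write_profiles_json(model$profiles, tmp_prof)
  obj$profiles <- jsonlite::read_json(tmp_prof)
  unlink(tmp_prof)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE, na = "null")
  invisible(path)
}

#' Read a duplex classifier from JSON
#' @param path file written by \code{\link{write_model_json}}.
#' @return a \code{duplex_classifier}.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "duplexmir-model")) {
    stop("not a duplexmir model file: ", path)
  }
  tmp_prof <- tempfile(fileext = ".json")
  jsonlite::write_json(obj$profiles, tmp_prof, auto_unbox = TRUE, digits = NA)
  profiles <- read_profiles_json(tmp_prof)
  unlink(tmp_prof)
  models <- lapply(obj$models, function(mb) {
    structure(list(trees = lapply(mb$trees, tree_from_list),
                   votes = as.numeric(unlist(mb$votes)),
                   boundaries = as.integer(unlist(mb$boundaries)),
                   K = as.integer(mb$K), seed = as.integer(mb$seed),
                   levels = unlist(mb$levels),
                   priors = as.numeric(unlist(mb$priors)),
                   weight_drift = mb$weight_drift,
                   weight_drift_raw = mb$weight_drift_raw),
              class = "multiboost")
  })
  cfg <- obj$config
  cfg[] <- lapply(cfg, function(v) if (is.list(v)) unlist(v) else v)
  structure(list(profiles = profiles, models = models,
                 modelled = unlist(obj$modelled), config = cfg,
                 seed = obj$seed, levels = unlist(obj$levels),
                 n_train = obj$n_train,
                 cluster_sizes = obj$cluster_sizes),
            class = "duplex_classifier")
}
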