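# Length-clustered transition-probability profiles over pairing-state
# patterns. For each cluster of patterns of equal length L, five subprofile
# matrices hold single-order transition probabilities for long-distance
# (i < j) co-occurrence of non-match states:
#   XX: mismatch -> mismatch        XI: mismatch <-> insertion
#   XD: mismatch <-> deletion       II: insertion -> insertion
#   DD: deletion -> deletion
# Insertion <-> deletion transitions have no subprofile and score 0.

PROFILE_FAMILIES <- list(XX = c("X", "X"), XI = c("X", "I"),
                         XD = c("X", "D"), II = c("I", "I"),
                         DD = c("D", "D"))

pattern_states <- function(p) strsplit(p, "", fixed = TRUE)

# family key of an unordered state pair, or NA if none (M involved or I/D)
family_key <- function(a, b) {
  key <- paste0(pmin(a, b), pmax(a, b))
  out <- c(XX = "XX", IX = "XI", DX = "XD", II = "II", DD = "DD")[key]
  unname(out)
}

pad_pattern <- function(states, L) {
  if (length(states) >= L) states[seq_len(L)]
  else c(states, rep("M", L - length(states)))
}

#' Build transition profiles from encoded patterns
#'
#' Patterns are clustered by exact length; clusters with fewer than
#' \code{min_support} patterns are merged into the nearest length cluster
#' (patterns right-padded with M or truncated). Within each cluster, for the
#' state-pair family (a, b), cell (i, j), i < j, holds
#' \deqn{(n_{ij} + c) / (n_i + 5c)}
#' where \eqn{n_{ij}} counts patterns with the family's states at i and j (in
#' either order for the mixed families), \eqn{n_i} counts patterns with a
#' family state at i, and c is the pseudocount.
#'
#' @param patterns character vector of encoded patterns over \{M,X,I,D\}.
#' @param pseudocount smoothing constant (default 0.5).
#' @param min_support minimum cluster size before merging (default 5).
#' @return object of class \code{transition_profile_list}: named list
#'   ("L<length>") of per-cluster profiles, each with \code{length},
#'   \code{matrices} (upper-triangular, NA elsewhere), \code{support},
#'   \code{pseudocount}.
#' @export
build_profiles <- function(patterns, pseudocount = 0.5, min_support = 5L) {
  if (!length(patterns)) stop("empty training set: no patterns to profile")
  st <- pattern_states(patterns)
  bad <- vapply(st, function(s) any(!s %in% c("M", "X", "I", "D")),
                logical(1L))
  if (any(bad)) stop("pattern contains states outside {M,X,I,D}")
  lens <- nchar(patterns)
  tab <- table(lens)
  keep_len <- as.integer(names(tab)[tab >= min_support])
  if (!length(keep_len)) {
    # degenerate: everything merges into the single most common length
    keep_len <- as.integer(names(tab)[which.max(tab)])
  }
  # merge small clusters into the nearest retained length (ties -> smaller)
  target <- vapply(lens, function(L) {
    d <- abs(keep_len - L)
    keep_len[order(d, keep_len)][1L]
  }, integer(1L))
  profiles <- lapply(sort(unique(target)), function(L) {
    members <- st[target == L]
    S <- t(vapply(members, pad_pattern, character(L), L = L))
    mats <- lapply(PROFILE_FAMILIES, function(fam) {
      A <- S == fam[1L] | S == fam[2L]
      if (fam[1L] == fam[2L]) {
        nij <- crossprod(S == fam[1L])
      } else {
        nij <- crossprod(S == fam[1L], S == fam[2L]) +
          crossprod(S == fam[2L], S == fam[1L])
      }
      ni <- colSums(A)
      denom <- ni + 5 * pseudocount
      cell <- (nij + pseudocount) / denom # broadcast over rows: denom[i]
      cell[denom == 0] <- 0
      cell[lower.tri(cell, diag = TRUE)] <- NA_real_
      dimnames(cell) <- NULL
      cell
    })
    structure(list(length = L, matrices = mats,
                   support = length(members), pseudocount = pseudocount),
              class = "transition_profile")
  })
  names(profiles) <- sprintf("L%d", vapply(profiles, `[[`, integer(1L),
                                           "length"))
  structure(profiles, class = "transition_profile_list")
}

#' @export
print.transition_profile_list <- function(x, ...) {
  cat("transition profiles for", length(x), "length clusters:\n")
  for (p in x) {
    cat(sprintf("  L=%d  support=%d  pseudocount=%g\n",
                p$length, p$support, p$pseudocount))
  }
  invisible(x)
}

#' Score a pattern against one length cluster's profile
#'
#' For each position j whose state is not M, the positional score is the
#' maximum transition-probability cell (i, j) over all earlier non-M positions
#' i (insertion/deletion pairs contribute 0; M positions and positions with no
#' earlier non-M state score 0). The matrix score is the sum.
#'
#' @param p encoded pattern string.
#' @param profile a \code{transition_profile}.
#' @return list with \code{matrix_score} and \code{positional} (length =
#'   cluster length).
#' @export
score_pattern <- function(p, profile) {
  s <- pattern_states(p)[[1L]]
  if (any(!s %in% c("M", "X", "I", "D"))) {
    stop("pattern contains states outside {M,X,I,D}")
  }
  L <- profile$length
  s <- pad_pattern(s, L)
  pos <- numeric(L)
  nonM <- which(s != "M")
  if (length(nonM) >= 2L) {
    for (jj in 2:length(nonM)) {
      j <- nonM[jj]
      prior <- nonM[seq_len(jj - 1L)]
      keys <- family_key(s[prior], s[j])
      vals <- vapply(seq_along(prior), function(k) {
        if (is.na(keys[k])) 0 else profile$matrices[[keys[k]]][prior[k], j]
      }, numeric(1L))
      pos[j] <- max(vals, 0)
    }
  }
  list(matrix_score = sum(pos), positional = pos)
}

#' Transform a pattern into its representative-profile feature vector
#'
#' The pattern is scored against every cluster whose length is within
#' \code{length_tolerance} of the pattern length (right-padding with M /
#' truncation); if none is admissible it is routed to the nearest-length
#' cluster and flagged. The cluster with the maximal matrix score is the
#' representative (ties: exact-length cluster, then larger training support,
#' then smaller length); its positional score vector becomes the feature
#' vector.
#'
#' @param p encoded pattern string.
#' @param profiles a \code{transition_profile_list}.
#' @param length_tolerance admissible |cluster length - pattern length|
#'   (default 2).
#' @return list of class \code{pattern_features}: \code{values} (numeric,
#'   length = representative cluster length), \code{cluster} (name),
#'   \code{rscore}, \code{flagged}.
#' @export
featurize <- function(p, profiles, length_tolerance = 2L) {
  if (!length(profiles)) stop("no profiles built")
  lens <- vapply(profiles, `[[`, integer(1L), "length")
  Lp <- nchar(p)
  adm <- which(abs(lens - Lp) <= length_tolerance)
  flagged <- FALSE
  if (!length(adm)) {
    d <- abs(lens - Lp)
    adm <- order(d, lens)[1L]
    flagged <- TRUE
  }
  scored <- lapply(adm, function(k) score_pattern(p, profiles[[k]]))
  ms <- vapply(scored, `[[`, numeric(1L), "matrix_score")
  sup <- vapply(profiles[adm], `[[`, integer(1L), "support")
  exact <- as.integer(lens[adm] == Lp)
  ord <- order(-ms, -exact, -sup, lens[adm])
  w <- ord[1L]
  structure(list(values = scored[[w]]$positional,
                 cluster = names(profiles)[adm[w]],
                 rscore = unname(ms[w]),
                 flagged = flagged), class = "pattern_features")
}

#' Write transition profiles to versioned JSON
#' @param profiles a \code{transition_profile_list}.
#' @param path output file.
#' @export
write_profiles_json <- function(profiles, path) {
  obj <- list(format = "duplexmir-profiles", version = 1L,
              clusters = lapply(unclass(profiles), function(p) {
                list(length = p$length, support = p$support,
                     pseudocount = p$pseudocount,
                     matrices = lapply(p$matrices, function(m) {
                       m[is.na(m)] <- -1
                       m
                     }))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read transition profiles from JSON
#' @param path file written by \code{\link{write_profiles_json}}.
#' @return a \code{transition_profile_list}.
#' @export
read_profiles_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "duplexmir-profiles")) {
    stop("not a duplexmir profile file: ", path)
  }
  profiles <- lapply(obj$clusters, function(p) {
    mats <- lapply(p$matrices, function(m) {
      m <- as.matrix(m)
      m[m < 0] <- NA_real_
      dimnames(m) <- NULL
      m
    })
    structure(list(length = as.integer(p$length), matrices = mats,
                   support = as.integer(p$support),
                   pseudocount = p$pseudocount),
              class = "transition_profile")
  })
  structure(profiles, class = "transition_profile_list")
}
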