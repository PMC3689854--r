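# Independent brute-force oracles. These deliberately use naive algorithms
# (quadratic scans, exhaustive enumeration) and share no code with the
# package implementations they check.

BASES <- c("A", "C", "G", "U")

rand_rna <- function(len) paste(sample(BASES, len, replace = TRUE),
                                collapse = "")

# ---- overlap / assembly ----------------------------------------------------

# longest suffix(a) == prefix(b), by direct substring comparison from the
# longest length down
oracle_overlap_len <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  for (L in seq(min(la, lb), 1L)) {
    if (L == la && L == lb) {
      if (a == b) return(L)
    } else if (substr(a, la - L + 1L, la) == substr(b, 1L, L)) {
      return(L)
    }
  }
  0L
}

# greedy longest-overlap-first merge with the same documented tie-breaks,
# recomputed from scratch every iteration (no caching, no KMP)
oracle_assemble_seqs <- function(seqs, min_overlap = 5L) {
  seqs <- sort(seqs, method = "radix")
  repeat {
    n <- length(seqs)
    if (n < 2L) return(sort(seqs, method = "radix"))
    best <- NULL
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      a <- seqs[i]; b <- seqs[j]
      cand <- NULL
      if (nchar(b) <= nchar(a) && grepl(b, a, fixed = TRUE)) {
        cand <- list(len = nchar(b), merged = a)
      } else if (nchar(a) < nchar(b) && grepl(a, b, fixed = TRUE)) {
        cand <- list(len = nchar(a), merged = b)
      } else {
        L <- oracle_overlap_len(a, b)
        if (L >= min_overlap) {
          cand <- list(len = L, merged = paste0(a, substring(b, L + 1L)))
        }
      }
      if (is.null(cand)) next
      cand$key <- paste(cand$merged, a, b)
      if (is.null(best) || cand$len > best$len ||
          (cand$len == best$len && cand$key < best$key)) {
        best <- cand; bi <- i; bj <- j
      }
    }
    if (is.null(best)) return(sort(seqs, method = "radix"))
    seqs <- c(seqs[-c(bi, bj)], best$merged)
  }
}

# ---- complementarity alignment ---------------------------------------------

o_pair_score <- function(a, b, sc) {
  wc <- (a == "A" && b == "U") || (a == "U" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G")
  wo <- (a == "G" && b == "U") || (a == "U" && b == "G")
  if (wc) sc$match else if (wo) sc$wobble else sc$mismatch
}

# exhaustive enumeration of every alignment (all monotone column paths, all
# admissible 3' overhang skips), affine gap scoring; feasible for short pairs
oracle_align_enum <- function(top, bottom, sc) {
  t_ch <- strsplit(top, "")[[1L]]
  b_ch <- rev(strsplit(bottom, "")[[1L]])
  n <- length(t_ch); m <- length(b_ch)
  best <- -Inf
  walk <- function(i, j, i_end, score, prev) {
    # consumed t[1..i], b'[j0+1..j]; prev in {"", "pair", "gt", "gb"}
    if (i == i_end && j == m) {
      if (prev != "") best <<- max(best, score)
      return(invisible())
    }
    if (i < i_end && j < m) {
      walk(i + 1L, j + 1L, i_end,
           score + o_pair_score(t_ch[i + 1L], b_ch[j + 1L], sc), "pair")
    }
    if (i < i_end) { # top base over gap
      pen <- if (prev == "gt") sc$gap_extend else sc$gap_open
      walk(i + 1L, j, i_end, score + pen, "gt")
    }
    if (j < m) { # gap over bottom base
      pen <- if (prev == "gb") sc$gap_extend else sc$gap_open
      walk(i, j + 1L, i_end, score + pen, "gb")
    }
  }
  for (j0 in 0:min(sc$max_overhang, m - 1L)) {
    for (k0 in 0:min(sc$max_overhang, n - 1L)) {
      walk(0L, j0, n - k0, 0, "")
    }
  }
  best
}

# independent reference DP: for each admissible (j0, k0) overhang pair run a
# plain affine-gap Gotoh global alignment on the clipped sequences
oracle_align_dp <- function(top, bottom, sc) {
  t_all <- strsplit(top, "")[[1L]]
  b_all <- rev(strsplit(bottom, "")[[1L]])
  gotoh <- function(tc, bc) {
    n <- length(tc); m <- length(bc)
    NEG <- -1e18
    M <- matrix(NEG, n + 1L, m + 1L)
    GX <- matrix(NEG, n + 1L, m + 1L) # gap in bottom
    GY <- matrix(NEG, n + 1L, m + 1L) # gap in top
    M[1L, 1L] <- 0
    for (i in 1:n) {
      GX[i + 1L, 1L] <- sc$gap_open + (i - 1L) * sc$gap_extend
    }
    for (j in 1:m) {
      GY[1L, j + 1L] <- sc$gap_open + (j - 1L) * sc$gap_extend
    }
    for (i in 1:n) for (j in 1:m) {
      M[i + 1L, j + 1L] <- max(M[i, j], GX[i, j], GY[i, j]) +
        o_pair_score(tc[i], bc[j], sc)
      GX[i + 1L, j + 1L] <- max(M[i, j + 1L] + sc$gap_open,
                                GX[i, j + 1L] + sc$gap_extend,
                                GY[i, j + 1L] + sc$gap_open)
      GY[i + 1L, j + 1L] <- max(M[i + 1L, j] + sc$gap_open,
                                GY[i + 1L, j] + sc$gap_extend,
                                GX[i + 1L, j] + sc$gap_open)
    }
    max(M[n + 1L, m + 1L], GX[n + 1L, m + 1L], GY[n + 1L, m + 1L])
  }
  best <- -Inf
  for (j0 in 0:min(sc$max_overhang, length(b_all) - 1L)) {
    for (k0 in 0:min(sc$max_overhang, length(t_all) - 1L)) {
      tc <- t_all[seq_len(length(t_all) - k0)]
      bc <- b_all[-seq_len(j0)]
      if (!j0) bc <- b_all
      best <- max(best, gotoh(tc, bc))
    }
  }
  best
}

# ---- profile scoring --------------------------------------------------------

# direct double loop over every (i, j) pair of non-M positions
oracle_score_pattern <- function(p, profile) {
  s <- strsplit(p, "")[[1L]]
  L <- profile$length
  if (length(s) >= L) s <- s[seq_len(L)] else s <- c(s, rep("M", L - length(s)))
  fam <- function(a, b) {
    k <- paste(sort(c(a, b)), collapse = "")
    switch(k, XX = "XX", IX = "XI", DX = "XD", II = "II", DD = "DD", NA)
  }
  pos <- numeric(L)
  for (j in seq_len(L)) {
    if (s[j] == "M") next
    vals <- 0
    for (i in seq_len(j - 1L)) {
      if (s[i] == "M") next
      key <- fam(s[i], s[j])
      v <- if (is.na(key)) 0 else profile$matrices[[key]][i, j]
      vals <- c(vals, v)
    }
    if (length(vals) > 1L) pos[j] <- max(vals)
  }
  list(matrix_score = sum(pos), positional = pos)
}

rand_pattern <- function(L, probs = c(M = .7, X = .15, I = .075, D = .075)) {
  paste(sample(names(probs), L, replace = TRUE, prob = probs), collapse = "")
}

# ---- decision tree ----------------------------------------------------------

# exhaustive enumeration of all (feature, midpoint) splits with weighted Gini
oracle_best_split <- function(x, y_pos, w, min_leaf = 2L) {
  n <- nrow(x)
  gini <- function(wp, wn) {
    W <- wp + wn
    if (W <= 0) 0 else W * (1 - (wp / W)^2 - (wn / W)^2)
  }
  parent <- gini(sum(w[y_pos]), sum(w[!y_pos]))
  best <- NULL
  for (f in seq_len(ncol(x))) {
    vals <- sort(unique(x[, f]))
    if (length(vals) < 2L) next
    for (k in seq_len(length(vals) - 1L)) {
      thr <- (vals[k] + vals[k + 1L]) / 2
      left <- x[, f] <= thr
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      child <- gini(sum(w[left & y_pos]), sum(w[left & !y_pos])) +
        gini(sum(w[!left & y_pos]), sum(w[!left & !y_pos]))
      gain <- parent - child
      if (gain > 1e-9 && (is.null(best) || gain > best$gain + 1e-9)) {
        best <- list(feature = f, threshold = thr, gain = gain)
      }
    }
  }
  best
}

# ---- misc -------------------------------------------------------------------

encode_pair <- function(top, bottom, scheme = scoring_scheme()) {
  encode_duplex(complement_align(top, bottom, scheme))
}

rc <- function(x) reverse_complement(x)
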