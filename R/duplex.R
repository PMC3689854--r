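# Duplex formation: global complementarity alignment of two contigs with
# affine gap penalties, G:U wobble pairing, and unpenalized 3' overhangs of up
# to `max_overhang` nucleotides per strand, followed by encoding of the paired
# region as a single pattern over {M, X, I, D}.
#
# Geometry: the top strand is written 5'->3'; the bottom strand is written
# 3'->5' beneath it, i.e. the aligner works on the reversed bottom sequence.
# The bottom strand's 3' end therefore sits at the LEFT edge of the alignment
# and the top strand's 3' end at the RIGHT edge; free overhang columns can
# occur only there (5' ends are flush).

#' Scoring scheme for complementarity alignment
#'
#' Gap penalties are the method's fixed values (open -5, extend -2); the
#' substitution scores are configurable package defaults: Watson-Crick pairs
#' +2, G:U wobble +1, other juxtapositions -1.
#'
#' @param match score of a Watson-Crick pair (A:U, G:C).
#' @param wobble score of a G:U pair.
#' @param mismatch score of a non-complementary base pair.
#' @param gap_open score of the first column of a gap run.
#' @param gap_extend score of each subsequent gap column.
#' @param max_overhang maximum unpenalized 3' overhang per strand (0-2).
#' @return list of class \code{scoring_scheme}.
#' @export
scoring_scheme <- function(match = 2, wobble = 1, mismatch = -1,
                           gap_open = -5, gap_extend = -2,
                           max_overhang = 2L) {
  stopifnot(gap_open <= gap_extend, gap_extend <= 0,
            max_overhang %in% 0:2)
  structure(list(match = match, wobble = wobble, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 max_overhang = as.integer(max_overhang)),
            class = "scoring_scheme")
}

# Column score of top base `a` against bottom base `b`.
pair_score <- function(a, b, scheme) {
  ifelse(is_wc_pair(a, b), scheme$match,
         ifelse(is_wobble_pair(a, b), scheme$wobble, scheme$mismatch))
}

#' Globally align two strands for maximum complementarity
#'
#' Needleman-Wunsch/Gotoh dynamic programming where columns score by base
#' pairing (Watson-Crick, G:U wobble, or mismatch) instead of identity. Up to
#' \code{scheme$max_overhang} terminal columns at each strand's 3' end are
#' free (reported as overhangs, excluded from the paired region). Ties are
#' resolved toward fewer gap columns, then by a deterministic leftmost-gap
#' traceback.
#'
#' @param top top strand, 5'->3'.
#' @param bottom bottom (star) strand, 5'->3' (it is reversed internally).
#' @param scheme a \code{\link{scoring_scheme}}.
#' @param top_id,bottom_id optional labels carried through.
#' @return object of class \code{duplex_alignment}: \code{score},
#'   \code{aligned_top}/\code{aligned_bottom} (gapped strings of the paired
#'   region; bottom written 3'->5'), \code{overhang_top3},
#'   \code{overhang_bottom3}, \code{gap_columns}.
#' @export
complement_align <- function(top, bottom, scheme = scoring_scheme(),
                             top_id = NA_character_,
                             bottom_id = NA_character_) {
  if (!nzchar(top) || !nzchar(bottom)) stop("empty sequence")
  t_ch <- seq_chars(top)
  b_ch <- rev(seq_chars(bottom)) # bottom written 3'->5' under the top strand
  n <- length(t_ch)
  m <- length(b_ch)
  oh <- scheme$max_overhang
  NEG <- -1e18

  # Three-state Gotoh with lexicographic (score, -gap columns) optimization.
  # State M: t_i paired with b_j; Ix: t_i over a gap (gap in bottom -> I);
  # Iy: gap in top over b_j (-> D).
  S_M <- matrix(NEG, n + 1L, m + 1L); G_M <- matrix(0L, n + 1L, m + 1L)
  S_X <- matrix(NEG, n + 1L, m + 1L); G_X <- matrix(0L, n + 1L, m + 1L)
  S_Y <- matrix(NEG, n + 1L, m + 1L); G_Y <- matrix(0L, n + 1L, m + 1L)
  P_M <- matrix(NA_character_, n + 1L, m + 1L)
  P_X <- matrix(NA_character_, n + 1L, m + 1L)
  P_Y <- matrix(NA_character_, n + 1L, m + 1L)

  # free start points: (0, j) for j = 0..oh means the first j bottom
  # characters (the bottom strand's 3' terminus) are skipped unpenalized
  start_ok <- function(i, j) i == 0L && j <= oh

  # lexicographic better-than: higher score, then fewer gap columns
  better <- function(s1, g1, s2, g2) {
    s1 > s2 + 1e-9 || (abs(s1 - s2) <= 1e-9 && g1 < g2)
  }

  for (i in 0:n) {
    for (j in 0:m) {
      if (i > 0L && j > 0L) {
        sc <- pair_score(t_ch[i], b_ch[j], scheme)
        bs <- NEG; bg <- 0L; bp <- NA_character_
        if (start_ok(i - 1L, j - 1L)) { bs <- 0; bg <- 0L; bp <- "S" }
        if (better(S_M[i, j], G_M[i, j], bs, bg)) {
          bs <- S_M[i, j]; bg <- G_M[i, j]; bp <- "M"
        }
        if (better(S_X[i, j], G_X[i, j], bs, bg)) {
          bs <- S_X[i, j]; bg <- G_X[i, j]; bp <- "X"
        }
        if (better(S_Y[i, j], G_Y[i, j], bs, bg)) {
          bs <- S_Y[i, j]; bg <- G_Y[i, j]; bp <- "Y"
        }
        if (!is.na(bp)) {
          S_M[i + 1L, j + 1L] <- bs + sc
          G_M[i + 1L, j + 1L] <- bg
          P_M[i + 1L, j + 1L] <- bp
        }
      }
      if (i > 0L) { # Ix: consume t_i against a gap
        bs <- NEG; bg <- 0L; bp <- NA_character_
        if (start_ok(i - 1L, j)) { bs <- scheme$gap_open; bg <- 1L; bp <- "S" }
        if (better(S_M[i, j + 1L] + scheme$gap_open, G_M[i, j + 1L] + 1L, bs, bg)) {
          bs <- S_M[i, j + 1L] + scheme$gap_open; bg <- G_M[i, j + 1L] + 1L; bp <- "M"
        }
        if (better(S_X[i, j + 1L] + scheme$gap_extend, G_X[i, j + 1L] + 1L, bs, bg)) {
          bs <- S_X[i, j + 1L] + scheme$gap_extend; bg <- G_X[i, j + 1L] + 1L; bp <- "X"
        }
        if (better(S_Y[i, j + 1L] + scheme$gap_open, G_Y[i, j + 1L] + 1L, bs, bg)) {
          bs <- S_Y[i, j + 1L] + scheme$gap_open; bg <- G_Y[i, j + 1L] + 1L; bp <- "Y"
        }
        if (!is.na(bp) && bs > NEG / 2) {
          S_X[i + 1L, j + 1L] <- bs; G_X[i + 1L, j + 1L] <- bg
          P_X[i + 1L, j + 1L] <- bp
        }
      }
      if (j > 0L) { # Iy: consume b_j against a gap
        bs <- NEG; bg <- 0L; bp <- NA_character_
        if (start_ok(i, j - 1L)) { bs <- scheme$gap_open; bg <- 1L; bp <- "S" }
        if (better(S_M[i + 1L, j] + scheme$gap_open, G_M[i + 1L, j] + 1L, bs, bg)) {
          bs <- S_M[i + 1L, j] + scheme$gap_open; bg <- G_M[i + 1L, j] + 1L; bp <- "M"
        }
        if (better(S_Y[i + 1L, j] + scheme$gap_extend, G_Y[i + 1L, j] + 1L, bs, bg)) {
          bs <- S_Y[i + 1L, j] + scheme$gap_extend; bg <- G_Y[i + 1L, j] + 1L; bp <- "Y"
        }
        if (better(S_X[i + 1L, j] + scheme$gap_open, G_X[i + 1L, j] + 1L, bs, bg)) {
          bs <- S_X[i + 1L, j] + scheme$gap_open; bg <- G_X[i + 1L, j] + 1L; bp <- "X"
        }
        if (!is.na(bp) && bs > NEG / 2) {
          S_Y[i + 1L, j + 1L] <- bs; G_Y[i + 1L, j + 1L] <- bg
          P_Y[i + 1L, j + 1L] <- bp
        }
      }
    }
  }

  # end points: (n - k0, m) for k0 = 0..oh -- the last k0 top characters (the
  # top strand's 3' terminus) are skipped unpenalized
  best <- NULL
  for (k0 in 0:min(oh, n - 1L)) {
    i_end <- n - k0
    for (st in c("M", "X", "Y")) {
      s <- switch(st, M = S_M, X = S_X, Y = S_Y)[i_end + 1L, m + 1L]
      g <- switch(st, M = G_M, X = G_X, Y = G_Y)[i_end + 1L, m + 1L]
      if (s <= NEG / 2) next
      if (is.null(best) || better(s, g, best$s, best$g)) {
        best <- list(s = s, g = g, k0 = k0, state = st)
      }
    }
  }
  if (is.null(best)) stop("no admissible alignment")

  # traceback
  at <- character(0)
  ab <- character(0)
  i <- n - best$k0
  j <- m
  st <- best$state
  j0 <- 0L
  repeat {
    if (st == "M") {
      p <- P_M[i + 1L, j + 1L]
      at <- c(t_ch[i], at); ab <- c(b_ch[j], ab)
      i <- i - 1L; j <- j - 1L
    } else if (st == "X") {
      p <- P_X[i + 1L, j + 1L]
      at <- c(t_ch[i], at); ab <- c("-", ab)
      i <- i - 1L
    } else {
      p <- P_Y[i + 1L, j + 1L]
      at <- c("-", at); ab <- c(b_ch[j], ab)
      j <- j - 1L
    }
    if (p == "S") { j0 <- j; break }
    st <- p
  }

  structure(list(
    top_id = top_id, bottom_id = bottom_id,
    top = top, bottom = bottom,
    aligned_top = chars_to_seq(at),
    aligned_bottom = chars_to_seq(ab),
    score = best$s,
    gap_columns = best$g,
    overhang_bottom3 = j0,
    overhang_top3 = best$k0), class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf("duplex alignment  score=%.1f  gaps=%d  overhangs 3' top=%d bottom=%d\n",
              x$score, x$gap_columns, x$overhang_top3, x$overhang_bottom3))
  cat("5'-", x$aligned_top, "-3'\n", sep = "")
  cat("3'-", x$aligned_bottom, "-5'\n", sep = "")
  invisible(x)
}

#' Encode an aligned duplex as a pairing-state pattern
#'
#' Each paired-region column becomes one state: \code{M} for a Watson-Crick or
#' G:U pair, \code{X} for a non-complementary base pair, \code{I} for a gap in
#' the bottom (star) strand, \code{D} for a gap in the top strand. Overhang
#' columns are excluded by construction.
#'
#' @param d a \code{duplex_alignment}.
#' @return single character string over \{M,X,I,D\}.
#' @export
encode_duplex <- function(d) {
  a <- seq_chars(d$aligned_top)
  b <- seq_chars(d$aligned_bottom)
  states <- character(length(a))
  gap_b <- b == "-"
  gap_a <- a == "-"
  states[gap_b] <- "I"
  states[gap_a] <- "D"
  both <- !gap_a & !gap_b
  states[both] <- ifelse(is_complementary(a[both], b[both]), "M", "X")
  chars_to_seq(states)
}

# Decide strand roles for a contig pair: the contig with the higher total
# read count is the top (reference) strand; ties go to the lexicographically
# smaller sequence.
duplex_roles <- function(count_a, seq_a, count_b, seq_b) {
  if (count_a > count_b) return(c(1L, 2L))
  if (count_b > count_a) return(c(2L, 1L))
  if (seq_a <= seq_b) c(1L, 2L) else c(2L, 1L)
}

#' Pair contigs into duplexes by best mutual complementarity
#'
#' Every unordered contig pair is aligned once (strand roles fixed by read
#' count, then lexicographic order); a duplex is emitted when the pairing is
#' mutual-best (default policy) or when a one-sided best exceeds
#' \code{min_score}. Each contig joins at most one duplex. Flagged
#' (over-length) contigs are excluded.
#'
#' @param contigs a \code{contig_set}.
#' @param scheme a \code{\link{scoring_scheme}}.
#' @param min_score minimum alignment score for an emitted duplex (default
#'   \code{-Inf}).
#' @param policy "mutual" (default) or "one_sided".
#' @param workers parallel workers for the all-vs-all alignment stage.
#' @return list of \code{duplex_alignment} objects (with \code{pattern} and
#'   arm read counts attached); unpaired contig indices in
#'   \code{attr(, "unpaired")}.
#' @export
select_duplexes <- function(contigs, scheme = scoring_scheme(),
                            min_score = -Inf, policy = c("mutual", "one_sided"),
                            workers = 1L) {
  policy <- match.arg(policy)
  keep <- which(!vapply(contigs, `[[`, logical(1L), "flagged"))
  if (length(keep) < 2L) {
    return(structure(list(), unpaired = keep, class = "duplex_list"))
  }
  seqs <- vapply(contigs, `[[`, character(1L), "sequence")
  counts <- vapply(contigs, `[[`, numeric(1L), "total_count")
  pairs <- utils::combn(keep, 2L, simplify = FALSE)
  alns <- parallel_map(pairs, function(p) {
    r <- duplex_roles(counts[p[1L]], seqs[p[1L]], counts[p[2L]], seqs[p[2L]])
    ti <- p[r[1L]]; bi <- p[r[2L]]
    complement_align(seqs[ti], seqs[bi], scheme,
                     top_id = as.character(ti), bottom_id = as.character(bi))
  }, workers = workers)
  nall <- length(contigs)
  S <- matrix(-Inf, nall, nall)
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    S[p[1L], p[2L]] <- S[p[2L], p[1L]] <- alns[[k]]$score
  }
  # best partner per contig; ties -> higher partner read count, then
  # lexicographically smaller partner sequence
  best_partner <- rep(NA_integer_, nall)
  for (i in keep) {
    cand <- keep[keep != i]
    s <- S[i, cand]
    mx <- max(s)
    tied <- cand[s >= mx - 1e-9]
    if (length(tied) > 1L) {
      tied <- tied[order(-counts[tied], seqs[tied], method = "radix")]
    }
    best_partner[i] <- tied[1L]
  }
  emitted <- list()
  taken <- rep(FALSE, nall)
  for (i in keep[order(seqs[keep], method = "radix")]) {
    if (taken[i]) next
    j <- best_partner[i]
    if (is.na(j) || taken[j]) next
    ok <- if (policy == "mutual") identical(best_partner[j], i)
          else S[i, j] >= min_score
    if (!ok || S[i, j] < min_score) next
    k <- which(vapply(pairs, function(p) all(sort(p) == sort(c(i, j))),
                      logical(1L)))[1L]
    d <- alns[[k]]
    d$pattern <- encode_duplex(d)
    d$top_count <- counts[as.integer(d$top_id)]
    d$bottom_count <- counts[as.integer(d$bottom_id)]
    emitted[[length(emitted) + 1L]] <- d
    taken[i] <- taken[j] <- TRUE
  }
  structure(emitted, unpaired = keep[!taken[keep]], class = "duplex_list")
}

#' @export
print.duplex_list <- function(x, ...) {
  cat("duplex_list with", length(x), "duplexes,",
      length(attr(x, "unpaired")), "unpaired contigs\n")
  invisible(x)
}

#' Export duplexes as TSV
#' @param duplexes a \code{duplex_list} (or list of duplex alignments).
#' @param path output file.
#' @export
write_duplexes_tsv <- function(duplexes, path) {
  df <- data.frame(
    top_id = vapply(duplexes, `[[`, character(1L), "top_id"),
    bottom_id = vapply(duplexes, `[[`, character(1L), "bottom_id"),
    top = vapply(duplexes, `[[`, character(1L), "top"),
    bottom = vapply(duplexes, `[[`, character(1L), "bottom"),
    score = vapply(duplexes, `[[`, numeric(1L), "score"),
    overhang_top3 = vapply(duplexes, `[[`, integer(1L), "overhang_top3"),
    overhang_bottom3 = vapply(duplexes, `[[`, integer(1L), "overhang_bottom3"),
    pattern = vapply(duplexes, function(d) d$pattern %||% encode_duplex(d),
                     character(1L)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
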