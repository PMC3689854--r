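# Seeded synthetic data: duplex libraries with known pairing-state patterns,
# tiled reads, and negative decoys, so every stage of the pipeline is testable
# with known ground truth.
#
# The positive generative model emulates mature miRNA duplexes: arm lengths
# peaked at 21-22 nt, a pairing-state pattern dominated by M with a structured
# co-occurring mismatch pair (plus occasional insertion and deletion pairs),
# G:U wobble realizations, and 0-2 nt 3' overhangs. Negatives are broader in
# length with position-independent state noise, plus state-shuffled positives
# as hard negatives of identical composition.

#' Specification of a synthetic duplex library
#'
#' All defaults are the package's documented study conditions (see the methods
#' vignette); generators are pure functions of (spec, seed).
#'
#' @param n_positive,n_negative instance counts.
#' @param seed RNG seed.
#' @param pos_lengths,pos_length_probs positive pattern length distribution.
#' @param neg_lengths negative (noise-model) length range.
#' @param anchor_x_prob probability of the structured mismatch pair (always
#'   present by default).
#' @param ins_pair_prob,del_pair_prob probabilities of the structured
#'   insertion / deletion pairs.
#' @param noise_x background mismatch rate at interior positions.
#' @param wobble_prob probability that an M column is realized as G:U.
#' @param shuffle_frac fraction of negatives drawn as state-shuffled
#'   positives.
#' @param neg_state_probs iid state probabilities (M, X, I, D) of the
#'   noise-model negatives.
#' @param overhang_probs probabilities of 3' overhang lengths 0, 1, 2.
#' @param self_consistent require positive realizations whose optimal
#'   alignment re-encodes to the planted pattern (default TRUE).
#' @return list of class \code{duplex_spec}.
#' @export
duplex_spec <- function(n_positive = 500L, n_negative = 500L, seed = 1L,
                        pos_lengths = 19:24,
                        pos_length_probs = c(.05, .15, .30, .30, .15, .05),
                        neg_lengths = 18:30,
                        anchor_x_prob = 1.0,
                        ins_pair_prob = 0.5,
                        del_pair_prob = 0.2,
                        noise_x = 0.02,
                        wobble_prob = 0.25,
                        shuffle_frac = 0.4,
                        neg_state_probs = c(M = .80, X = .12, I = .04, D = .04),
                        overhang_probs = c(`0` = .1, `1` = .2, `2` = .7),
                        self_consistent = TRUE) {
  stopifnot(n_positive >= 1L, n_negative >= 0L,
            abs(sum(pos_length_probs) - 1) < 1e-9,
            abs(sum(neg_state_probs) - 1) < 1e-9)
  structure(as.list(environment()), class = "duplex_spec")
}

# one positive pattern: anchored mismatch pair, optional insertion and
# deletion pairs, sparse interior noise; the 3 terminal columns on each side
# stay M (seed-region pairing)
sample_positive_pattern <- function(spec) {
  L <- sample(spec$pos_lengths, 1L, prob = spec$pos_length_probs)
  s <- rep("M", L)
  interior <- 4:(L - 3L)
  if (stats::runif(1) < spec$anchor_x_prob) {
    i1 <- sample(5:6, 1L)
    i2 <- L - sample(5:6, 1L)
    s[c(i1, i2)] <- "X"
  }
  # gapped states appear as contiguous 2-nt bulges (a single gap run), the
  # geometry real duplex bulges take and the one a gap-affine aligner keeps
  if (stats::runif(1) < spec$ins_pair_prob) {
    u <- sample(9:11, 1L)
    at <- c(u, u + 1L)
    at <- at[at %in% interior & s[at] == "M"]
    s[at] <- "I"
  }
  if (stats::runif(1) < spec$del_pair_prob) {
    v <- sample(13:15, 1L)
    at <- c(v, v + 1L)
    at <- at[at %in% interior & s[at] == "M"]
    s[at] <- "D"
  }
  flip <- interior[s[interior] == "M" & stats::runif(length(interior)) < spec$noise_x]
  s[flip] <- "X"
  s
}

sample_negative_pattern <- function(spec) {
  if (stats::runif(1) < spec$shuffle_frac) {
    return(sample(sample_positive_pattern(spec)))
  }
  L <- sample(spec$neg_lengths, 1L)
  sample(names(spec$neg_state_probs), L, replace = TRUE,
         prob = spec$neg_state_probs)
}

# realize concrete arms from a state pattern; returns top/bottom arm
# sequences (5'->3') and the overhang lengths used
realize_duplex <- function(states, spec) {
  L <- length(states)
  top <- character(L)
  bot <- character(L) # written 3'->5' (left to right under the top strand)
  for (k in seq_len(L)) {
    st <- states[k]
    if (st == "M") {
      if (stats::runif(1) < spec$wobble_prob) {
        top[k] <- sample(c("G", "U"), 1L)
        bot[k] <- if (top[k] == "G") "U" else "G"
      } else {
        top[k] <- sample(RNA_BASES, 1L)
        bot[k] <- WC_PARTNER[[top[k]]]
      }
    } else if (st == "X") {
      top[k] <- sample(RNA_BASES, 1L)
      excl <- WC_PARTNER[[top[k]]]
      if (top[k] %in% c("G", "U")) excl <- c(excl, setdiff(c("G", "U"), top[k]))
      bot[k] <- sample(setdiff(RNA_BASES, excl), 1L)
    } else if (st == "I") {
      top[k] <- sample(RNA_BASES, 1L)
      bot[k] <- "-"
    } else {
      top[k] <- "-"
      bot[k] <- sample(RNA_BASES, 1L)
    }
  }
  oh_top <- sample(0:2, 1L, prob = spec$overhang_probs)
  oh_bot <- sample(0:2, 1L, prob = spec$overhang_probs)
  top_arm <- paste0(chars_to_seq(top[top != "-"]),
                    if (oh_top) random_seq(oh_top) else "")
  # the bottom row reads 3'->5'; its 5'->3' sequence is the reverse, and the
  # bottom strand's 3' overhang extends past the row's left edge
  bot_arm <- paste0(chars_to_seq(rev(bot[bot != "-"])),
                    if (oh_bot) random_seq(oh_bot) else "")
  list(top = top_arm, bottom = bot_arm, overhang_top3 = oh_top,
       overhang_bottom3 = oh_bot)
}

# draw one labelled duplex; positive realizations are accepted only when
# self-consistent, i.e. the planted pattern equals the encoding of the arms'
# own optimal alignment, so the planted structure is exactly what the
# pipeline sees (negatives are unconstrained: their generative pattern is not
# claimed to be the optimal alignment, only their label is ground truth)
draw_duplex <- function(label, spec, scheme) {
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 2000L) stop("duplex realization failed to converge")
    states <- if (label == POSITIVE_LABEL) sample_positive_pattern(spec)
              else sample_negative_pattern(spec)
    rd <- realize_duplex(states, spec)
    if (nchar(rd$top) < 15L || nchar(rd$bottom) < 15L) next
    if (label == POSITIVE_LABEL && spec$self_consistent) {
      d <- complement_align(rd$top, rd$bottom, scheme)
      if (encode_duplex(d) != chars_to_seq(states)) next
    }
    return(list(states = states, rd = rd))
  }
}

#' Simulate a labelled synthetic duplex library
#'
#' Draws pairing-state patterns from the class models of \code{spec}, then
#' samples concrete nucleotide arms consistent with each pattern (M columns
#' complementary or G:U, X columns non-complementary, I/D columns gapped,
#' random 3' overhangs). Arms shorter than 15 nt are rejected and redrawn;
#' positive realizations are additionally required to be self-consistent
#' (their optimal complementarity alignment re-encodes to the planted
#' pattern).
#'
#' @param spec a \code{\link{duplex_spec}}.
#' @param seed overrides \code{spec$seed} when given.
#' @return data.frame: top, bottom, pattern (the planted ground truth), label,
#'   overhang_top3, overhang_bottom3.
#' @export
simulate_duplexes <- function(spec, seed = spec$seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  scheme <- scoring_scheme()
  n <- spec$n_positive + spec$n_negative
  labs <- c(rep(POSITIVE_LABEL, spec$n_positive),
            rep(NEGATIVE_LABEL, spec$n_negative))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    dd <- draw_duplex(labs[i], spec, scheme)
    rows[[i]] <- data.frame(top = dd$rd$top, bottom = dd$rd$bottom,
                            pattern = chars_to_seq(dd$states), label = labs[i],
                            overhang_top3 = dd$rd$overhang_top3,
                            overhang_bottom3 = dd$rd$overhang_bottom3,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tile reads across source sequences
#'
#' Consecutive tiles overlap by at least \code{min_tile_overlap}; each tile is
#' duplicated to the requested depth via its count. Sources shorter than the
#' read length yield a single full-length read.
#'
#' @param sources character vector of source sequences (named or not).
#' @param read_length target read length (default 18).
#' @param min_tile_overlap minimum overlap of consecutive tiles (default 10).
#' @param depth copy count per tile (default 2).
#' @param seed unused placeholder for interface symmetry (tiling is
#'   deterministic).
#' @return read table.
#' @export
simulate_reads <- function(sources, read_length = 18L, min_tile_overlap = 10L,
                           depth = 2L, seed = NULL) {
  stopifnot(min_tile_overlap < read_length)
  nm <- names(sources) %||% sprintf("src_%03d", seq_along(sources))
  rows <- lapply(seq_along(sources), function(i) {
    s <- sources[[i]]
    len <- nchar(s)
    if (len <= read_length) {
      starts <- 1L
      rl <- len
    } else {
      rl <- read_length
      step <- rl - min_tile_overlap
      starts <- unique(c(seq(1L, len - rl + 1L, by = step), len - rl + 1L))
    }
    data.frame(id = sprintf("%s_t%02d", nm[i], seq_along(starts)),
               sequence = substring(s, starts, starts + rl - 1L),
               count = as.integer(depth), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# TRUE when `cand` can be added to `accepted` without any terminal
# suffix-prefix overlap >= min_overlap, containment, or self-periodicity
source_compatible <- function(cand, accepted, min_overlap = 5L) {
  # periodic termini: longest proper border of the candidate itself
  ch <- seq_chars(cand)
  if (kmp_failure(ch)[length(ch)] >= min_overlap) return(FALSE)
  for (s in accepted) {
    if (grepl(cand, s, fixed = TRUE) || grepl(s, cand, fixed = TRUE)) {
      return(FALSE)
    }
    if (kmp_overlap(cand, s) >= min_overlap ||
        kmp_overlap(s, cand) >= min_overlap) {
      return(FALSE)
    }
  }
  TRUE
}

#' Simulate mutually overlap-free source sequences
#'
#' Random sequences accepted by rejection so that no pair shares a terminal
#' suffix-prefix overlap of \code{min_overlap} or more, none contains another,
#' and none has periodic termini -- i.e. a "repeat-free" library whose tiled
#' reads reassemble unambiguously.
#'
#' @param n number of sources.
#' @param length_range inclusive source length range.
#' @param min_overlap assembler overlap threshold to stay under (default 5).
#' @param seed RNG seed.
#' @return character vector of sources.
#' @export
simulate_repeat_free_sources <- function(n, length_range = c(20L, 70L),
                                         min_overlap = 5L, seed = 1L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 1000L * n) stop("rejection sampling failed to converge")
    cand <- random_seq(sample(length_range[1L]:length_range[2L], 1L))
    if (source_compatible(cand, out, min_overlap)) out <- c(out, cand)
  }
  out
}

#' The standard synthetic train/test benchmark
#'
#' 500 positive + 500 negative duplexes for training and the same counts for
#' testing, drawn from the default \code{\link{duplex_spec}} with disjoint
#' sub-seeds; duplexes duplicated across splits are redrawn, so the splits are
#' disjoint by construction.
#'
#' @param seed benchmark seed.
#' @param n_positive,n_negative per-split class sizes (default 500 each).
#' @return list with \code{train} and \code{test} duplex data.frames and the
#'   \code{spec} used.
#' @export
make_benchmark <- function(seed = 1L, n_positive = 500L, n_negative = 500L) {
  spec <- duplex_spec(n_positive = n_positive, n_negative = n_negative,
                      seed = seed)
  train <- simulate_duplexes(spec, seed = seed * 2L + 1L)
  test <- simulate_duplexes(spec, seed = seed * 2L + 2L)
  dup <- paste(test$top, test$bottom) %in% paste(train$top, train$bottom)
  if (any(dup)) {
    redo <- simulate_duplexes(spec, seed = seed * 2L + 3L)
    test[dup, ] <- redo[dup, ]
  }
  list(train = train, test = test, spec = spec)
}

#' A planted discovery library: positive duplexes, decoys, and tiled reads
#'
#' Draws \code{n_positive} positive and \code{n_decoy} negative duplexes whose
#' arm sequences are mutually overlap-free (rejection sampling against the
#' assembler's overlap threshold), then tiles reads over every arm. The
#' planted positives are the ground truth a discovery run should recover.
#'
#' @param seed RNG seed.
#' @param n_positive planted positive duplexes (default 10).
#' @param n_decoy decoy negative duplexes (default 10).
#' @param depth star-arm read copy count per tile; mature arms are tiled at
#'   5x this depth (mature-strand abundance bias).
#' @param min_overlap assembler overlap threshold the library stays free of.
#' @return list: \code{duplexes} (planted data.frame with label), \code{reads}
#'   (read table over all arms), \code{arms} (named character vector).
#' @export
make_planted_library <- function(seed = 1L, n_positive = 10L, n_decoy = 10L,
                                 depth = 3L, min_overlap = 5L) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  spec <- duplex_spec(n_positive = 1L, n_negative = 1L, seed = seed)
  scheme <- scoring_scheme()
  accepted <- character(0)
  rows <- list()
  want <- c(rep(POSITIVE_LABEL, n_positive), rep(NEGATIVE_LABEL, n_decoy))
  for (i in seq_along(want)) {
    guard <- 0L
    repeat {
      guard <- guard + 1L
      if (guard > 2000L) stop("rejection sampling failed to converge")
      dd <- draw_duplex(want[i], spec, scheme)
      rd <- dd$rd
      if (!source_compatible(rd$top, accepted, min_overlap)) next
      if (!source_compatible(rd$bottom, c(accepted, rd$top), min_overlap)) next
      break
    }
    accepted <- c(accepted, rd$top, rd$bottom)
    rows[[i]] <- data.frame(top = rd$top, bottom = rd$bottom,
                            pattern = chars_to_seq(dd$states), label = want[i],
                            stringsAsFactors = FALSE)
  }
  duplexes <- do.call(rbind, rows)
  arms <- stats::setNames(
    accepted,
    as.vector(rbind(sprintf("dx%02d_top", seq_along(want)),
                    sprintf("dx%02d_bot", seq_along(want)))))
  # the mature (top) arm is tiled at higher depth than the star arm,
  # reflecting the strong mature-strand bias of real libraries; the
  # count-based strand-role rule then recovers the planted duplex orientation
  is_top <- grepl("_top$", names(arms))
  reads <- rbind(
    simulate_reads(arms[is_top], read_length = 18L, min_tile_overlap = 12L,
                   depth = 5L * depth),
    simulate_reads(arms[!is_top], read_length = 18L, min_tile_overlap = 12L,
                   depth = depth))
  list(duplexes = duplexes, reads = reads, arms = arms)
}
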