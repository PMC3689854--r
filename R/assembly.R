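# Reference-free contig assembly: reads sharing an exact terminal
# suffix-prefix overlap of at least `min_overlap` nucleotides are merged,
# greedily longest-overlap-first, until no pair can be merged. Containment
# (one sequence a substring of another) is absorbed into the container.

# KMP failure (prefix) function of a character vector.
kmp_failure <- function(ch) {
  n <- length(ch)
  pi <- integer(n)
  if (n < 2L) return(pi)
  k <- 0L
  for (i in 2:n) {
    while (k > 0L && ch[i] != ch[k + 1L]) k <- pi[k]
    if (ch[i] == ch[k + 1L]) k <- k + 1L
    pi[i] <- k
  }
  pi
}

# Longest L such that the length-L suffix of `a` equals the length-L prefix
# of `b`, via the KMP failure function over b#a. Returns 0 when none.
kmp_overlap <- function(a, b) {
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  ch <- c(cb, "#", ca)
  pi <- kmp_failure(ch)
  L <- pi[length(ch)]
  # failure values are capped below length(b)+1 by the sentinel; also cap at
  # length(a) (a border cannot be longer than either string)
  min(L, length(ca), length(cb))
}

#' Best terminal suffix-prefix overlap between two sequences
#'
#' Finds the longest L >= \code{min_overlap} such that the length-L suffix of
#' \code{a} equals the length-L prefix of \code{b}, computed in linear time
#' with the KMP failure function over \code{b#a}. Containment of one sequence
#' in the other is reported as a distinct outcome.
#'
#' @param a,b nucleotide strings.
#' @param min_overlap minimum overlap length (default 5).
#' @return list with \code{type} ("overlap", "contained" or "none") and
#'   \code{length} (overlap length, or length of the contained sequence).
#'   For "contained", \code{which} says whether "b_in_a" or "a_in_b".
#' @export
find_overlap <- function(a, b, min_overlap = 5L) {
  stopifnot(min_overlap >= 1L)
  if (nchar(b) <= nchar(a) && grepl(b, a, fixed = TRUE)) {
    return(list(type = "contained", which = "b_in_a", length = nchar(b)))
  }
  if (nchar(a) < nchar(b) && grepl(a, b, fixed = TRUE)) {
    return(list(type = "contained", which = "a_in_b", length = nchar(a)))
  }
  L <- kmp_overlap(a, b)
  if (L >= min_overlap) list(type = "overlap", length = L)
  else list(type = "none", length = 0L)
}

# A contig is a list: sequence, members (data.frame id, offset, length,
# count), total_count. Offsets are 0-based.
new_contig <- function(sequence, members) {
  list(sequence = sequence, members = members,
       total_count = sum(members$count))
}

contig_from_read <- function(id, sequence, count) {
  new_contig(sequence, data.frame(id = id, offset = 0L,
                                  length = nchar(sequence), count = count,
                                  stringsAsFactors = FALSE))
}

# Merge b onto a with suffix-prefix overlap L (or containment).
merge_contigs <- function(a, b, type, L, which = NULL) {
  if (type == "overlap") {
    merged <- paste0(a$sequence, substring(b$sequence, L + 1L))
    shift <- nchar(a$sequence) - L
    mb <- b$members
    mb$offset <- mb$offset + shift
    return(new_contig(merged, rbind(a$members, mb)))
  }
  # containment: locate inner inside outer (first occurrence)
  if (which == "b_in_a") { outer <- a; inner <- b } else { outer <- b; inner <- a }
  at <- regexpr(inner$sequence, outer$sequence, fixed = TRUE)[1L] - 1L
  mi <- inner$members
  mi$offset <- mi$offset + at
  new_contig(outer$sequence, rbind(outer$members, mi))
}

# Candidate merge between two contigs, described as (priority length, merged
# sequence). Containment ranks above any terminal overlap of the same length
# by treating its length as the contained sequence length (maximal possible).
merge_candidate <- function(a, b, min_overlap) {
  ov <- find_overlap(a$sequence, b$sequence, min_overlap)
  if (ov$type == "none") return(NULL)
  merged <- if (ov$type == "contained") {
    if (ov$which == "b_in_a") a$sequence else b$sequence
  } else {
    paste0(a$sequence, substring(b$sequence, ov$length + 1L))
  }
  list(type = ov$type, length = ov$length, which = ov$which %||% NA_character_,
       merged = merged)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Assemble collapsed reads into contigs
#'
#' Greedy iterative merging: among all ordered contig pairs, the pair with the
#' longest exact terminal overlap is merged first; ties are broken
#' lexicographically by the merged sequence, then by the pair's sequences.
#' Containment is treated as a mergeable case (the contained read is absorbed
#' with its counts). The result does not depend on input order.
#'
#' @param reads collapsed read table (unique sequences).
#' @param min_overlap minimum exact terminal overlap (default 5).
#' @param max_length contigs longer than this are flagged and excluded from
#'   duplex search (default 80).
#' @return object of class \code{contig_set}: list of contigs, each with
#'   \code{sequence}, \code{members}, \code{total_count}, \code{flagged}.
#' @export
assemble <- function(reads, min_overlap = 5L, max_length = 80L) {
  contigs <- lapply(seq_len(nrow(reads)), function(i) {
    contig_from_read(reads$id[i], reads$sequence[i], reads$count[i])
  })
  # canonical start order so the greedy walk is input-order independent
  contigs <- contigs[order(vapply(contigs, `[[`, character(1L), "sequence"),
                           method = "radix")]
  n <- length(contigs)
  if (n > 1L) {
    # pairwise candidate tables: priority length (containment counts as the
    # contained sequence's length), merged sequence, and containment flag
    LEN <- matrix(NA_real_, n, n)
    MRG <- matrix(NA_character_, n, n)
    TYP <- matrix(NA_character_, n, n)
    WCH <- matrix(NA_character_, n, n)
    fill_pair <- function(i, j) {
      cc <- merge_candidate(contigs[[i]], contigs[[j]], min_overlap)
      if (is.null(cc)) {
        LEN[i, j] <<- NA_real_; MRG[i, j] <<- NA_character_
        TYP[i, j] <<- NA_character_; WCH[i, j] <<- NA_character_
      } else {
        LEN[i, j] <<- cc$length; MRG[i, j] <<- cc$merged
        TYP[i, j] <<- cc$type; WCH[i, j] <<- cc$which
      }
    }
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) fill_pair(i, j)
    alive <- rep(TRUE, n)
    seqs <- vapply(contigs, `[[`, character(1L), "sequence")
    repeat {
      if (all(is.na(LEN))) break
      m <- max(LEN, na.rm = TRUE)
      hits <- which(LEN == m, arr.ind = TRUE)
      if (nrow(hits) > 1L) {
        key <- paste(MRG[hits], seqs[hits[, 1L]], seqs[hits[, 2L]])
        hits <- hits[order(key, method = "radix")[1L], , drop = FALSE]
      }
      bi <- hits[1L, 1L]; bj <- hits[1L, 2L]
      merged <- merge_contigs(contigs[[bi]], contigs[[bj]], TYP[bi, bj],
                              as.integer(LEN[bi, bj]),
                              if (!is.na(WCH[bi, bj])) WCH[bi, bj])
      contigs[[bi]] <- merged
      seqs[bi] <- merged$sequence
      alive[bj] <- FALSE
      LEN[bj, ] <- NA_real_; LEN[, bj] <- NA_real_
      MRG[bj, ] <- NA_character_; MRG[, bj] <- NA_character_
      for (j in which(alive)) {
        if (j == bi) next
        fill_pair(bi, j)
        fill_pair(j, bi)
      }
    }
    contigs <- contigs[alive]
  }
  contigs <- contigs[order(vapply(contigs, `[[`, character(1L), "sequence"),
                           method = "radix")]
  contigs <- lapply(contigs, function(cg) {
    cg$members <- cg$members[order(cg$members$offset, cg$members$id,
                                   method = "radix"), , drop = FALSE]
    rownames(cg$members) <- NULL
    cg$flagged <- nchar(cg$sequence) > max_length
    cg$depth <- contig_depth(cg)
    cg
  })
  structure(contigs, class = "contig_set")
}

# Per-position read coverage of a contig.
contig_depth <- function(contig) {
  d <- integer(nchar(contig$sequence))
  for (i in seq_len(nrow(contig$members))) {
    a <- contig$members$offset[i] + 1L
    b <- contig$members$offset[i] + contig$members$length[i]
    d[a:b] <- d[a:b] + contig$members$count[i]
  }
  d
}

#' @export
print.contig_set <- function(x, ...) {
  cat("contig_set with", length(x), "contigs\n")
  if (length(x)) {
    lens <- vapply(x, function(c) nchar(c$sequence), integer(1L))
    cat("  lengths:", paste(range(lens), collapse = "-"),
        " flagged:", sum(vapply(x, `[[`, logical(1L), "flagged")), "\n")
  }
  invisible(x)
}

#' Summarize a contig set as a data.frame
#' @param x contig_set.
#' @param ... unused.
#' @return data.frame with sequence, length, n_members, total_count, flagged.
#' @export
as.data.frame.contig_set <- function(x, ...) {
  data.frame(
    sequence = vapply(x, `[[`, character(1L), "sequence"),
    length = vapply(x, function(c) nchar(c$sequence), integer(1L)),
    n_members = vapply(x, function(c) nrow(c$members), integer(1L)),
    total_count = vapply(x, `[[`, numeric(1L), "total_count"),
    flagged = vapply(x, `[[`, logical(1L), "flagged"),
    stringsAsFactors = FALSE)
}

#' Export contigs as FASTA (+ member offsets TSV sidecar)
#'
#' Headers carry the member count and summed read count. The sidecar lists
#' each member read with its 0-based offset in the contig.
#'
#' @param contigs contig_set.
#' @param path output FASTA path; the sidecar is written to
#'   \code{paste0(path, ".members.tsv")}.
#' @export
write_contigs_fasta <- function(contigs, path) {
  ids <- sprintf("contig_%04d", seq_along(contigs))
  hdr <- sprintf("%s members=%d total_count=%d", ids,
                 vapply(contigs, function(c) nrow(c$members), integer(1L)),
                 vapply(contigs, function(c) as.integer(c$total_count),
                        integer(1L)))
  seqs <- Biostrings::BStringSet(
    stats::setNames(vapply(contigs, `[[`, character(1L), "sequence"), hdr))
  Biostrings::writeXStringSet(seqs, path)
  side <- do.call(rbind, lapply(seq_along(contigs), function(i) {
    cbind(contig = ids[i], contigs[[i]]$members, stringsAsFactors = FALSE)
  }))
  utils::write.table(side, paste0(path, ".members.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
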