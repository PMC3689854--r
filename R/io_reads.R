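# Reading, collapsing and mapping of small RNA sequencing reads.
#
# Reads are held in a plain data.frame with columns `id`, `sequence`, `count`;
# sequences are kept in the internal RNA alphabet (T normalized to U).

#' Construct a read table
#'
#' @param id character vector of read labels.
#' @param sequence character vector of nucleotide sequences (DNA or RNA).
#' @param count positive integer multiplicities (recycled).
#' @return data.frame with columns id, sequence, count.
#' @export
reads_table <- function(id, sequence, count = 1L) {
  sequence <- normalize_seq(sequence)
  count <- as.integer(rep_len(count, length(sequence)))
  if (length(sequence) && (anyNA(count) || any(count < 1L))) {
    stop("read counts must be positive integers")
  }
  if (length(sequence) && any(!nzchar(sequence))) {
    stop("read sequences must be non-empty")
  }
  data.frame(id = as.character(id), sequence = sequence, count = count,
             stringsAsFactors = FALSE)
}

#' Read small RNA sequences from FASTA, FASTQ or tag-count files
#'
#' FASTA and FASTQ (4-line dialect, qualities ignored) records yield one read
#' of count 1 each; collapsing identical sequences is a separate step
#' (\code{\link{collapse_reads}}). Tag files are two-column
#' \code{SEQUENCE<TAB>COUNT} tables.
#'
#' @param path file path.
#' @param format one of "fasta", "fastq", "tags". Defaults to a guess from the
#'   file extension.
#' @return read table (see \code{\link{reads_table}}).
#' @export
read_fastx <- function(path, format = c("auto", "fasta", "fastq", "tags")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     fa = , fasta = , fna = "fasta",
                     fq = , fastq = "fastq",
                     tsv = , txt = , tags = "tags",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || all(!nzchar(lines))) {
    warning("empty input file: ", path)
    return(reads_table(character(0), character(0), integer(0)))
  }
  switch(format,
         fasta = .read_fasta(path, lines),
         fastq = .read_fastq(lines),
         tags = .read_tags(lines))
}

.read_fasta <- function(path, lines) {
  first <- which(nzchar(lines))[1L]
  if (!startsWith(lines[first], ">")) {
    stop("malformed FASTA at line ", first, ": expected '>' header")
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(as.character(set)))) {
    bad <- which(!nzchar(as.character(set)))[1L]
    stop("malformed FASTA record '", ids[bad], "': empty sequence")
  }
  reads_table(ids, as.character(set), 1L)
}

.read_fastq <- function(lines) {
  lines <- lines[seq_len(max(which(nzchar(lines))))]
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ at line ", length(lines) + 1L,
         ": record count is not a multiple of 4")
  }
  idx <- seq(1L, length(lines), by = 4L)
  bad_hdr <- idx[!startsWith(lines[idx], "@")]
  if (length(bad_hdr)) {
    stop("malformed FASTQ at line ", bad_hdr[1L], ": expected '@' header")
  }
  bad_sep <- (idx + 2L)[!startsWith(lines[idx + 2L], "+")]
  if (length(bad_sep)) {
    stop("malformed FASTQ at line ", bad_sep[1L], ": expected '+' separator")
  }
  bad_len <- idx[nchar(lines[idx + 1L]) != nchar(lines[idx + 3L])]
  if (length(bad_len)) {
    stop("malformed FASTQ at line ", bad_len[1L] + 3L,
         ": quality length differs from sequence length")
  }
  ids <- sub("\\s.*$", "", substring(lines[idx], 2L))
  reads_table(ids, lines[idx + 1L], 1L)
}

.read_tags <- function(lines) {
  keep <- which(nzchar(lines))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    stop("malformed tag file at line ", keep[which(nf != 2L)[1L]],
         ": expected SEQUENCE<TAB>COUNT")
  }
  seqs <- vapply(parts, `[`, character(1L), 1L)
  counts <- suppressWarnings(as.integer(vapply(parts, `[`, character(1L), 2L)))
  if (anyNA(counts) || any(counts < 1L)) {
    stop("malformed tag file at line ",
         keep[which(is.na(counts) | counts < 1L)[1L]],
         ": count must be a positive integer")
  }
  reads_table(sprintf("tag_%d", seq_along(seqs)), seqs, counts)
}

#' Collapse reads to unique sequence tags
#'
#' One row per distinct sequence with summed counts, ordered
#' lexicographically (C locale) by sequence. The id of the first member (by
#' lexicographic id) is retained.
#'
#' @param reads read table.
#' @return collapsed read table.
#' @export
collapse_reads <- function(reads) {
  if (!nrow(reads)) return(reads)
  ord <- order(reads$sequence, reads$id, method = "radix")
  reads <- reads[ord, , drop = FALSE]
  first <- !duplicated(reads$sequence)
  counts <- rowsum(reads$count, group = reads$sequence, reorder = TRUE)
  out <- data.frame(id = reads$id[first],
                    sequence = reads$sequence[first],
                    count = as.integer(counts[, 1L]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Construct a named reference set
#'
#' @param name label for the set (e.g. "pre-miRNA", "ncRNA").
#' @param sequences named character vector of reference sequences, or a path
#'   to a FASTA file.
#' @return list with elements name and seqs (named, RNA alphabet).
#' @export
reference_set <- function(name, sequences) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences) && is.null(names(sequences))) {
    set <- Biostrings::readBStringSet(sequences, format = "fasta")
    sequences <- stats::setNames(as.character(set),
                                 sub("\\s.*$", "", names(set)))
  }
  if (!length(sequences)) {
    return(list(name = name,
                seqs = stats::setNames(character(0), character(0))))
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("reference sequences must have unique names")
  }
  list(name = name, seqs = normalize_seq(sequences))
}

#' Map reads onto a reference set by substring matching
#'
#' Reports every occurrence of a read as a substring of a reference (same
#' strand only, no reverse complement) with at most \code{max_mismatch}
#' substitutions. Coordinates are 0-based, half-open.
#'
#' @param reads read table.
#' @param refset reference set from \code{\link{reference_set}}.
#' @param max_mismatch maximum number of substitutions (default 0 = exact).
#' @return data.frame (read_id, ref_id, start, end, mismatches).
#' @export
map_reads_to_refs <- function(reads, refset, max_mismatch = 0L) {
  stopifnot(max_mismatch >= 0L)
  empty <- data.frame(read_id = character(0), ref_id = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  if (!nrow(reads) || !length(refset$seqs)) return(empty)
  if (max_mismatch == 0L) return(.map_exact(reads, refset, empty))
  subjects <- lapply(refset$seqs, Biostrings::RNAString)
  rows <- vector("list", nrow(reads) * length(subjects))
  k <- 0L
  for (i in seq_len(nrow(reads))) {
    rs <- reads$sequence[i]
    if (grepl("N", rs, fixed = TRUE)) next
    pat <- Biostrings::RNAString(rs)
    for (j in seq_along(subjects)) {
      if (length(pat) > length(subjects[[j]])) next
      hits <- Biostrings::matchPattern(pat, subjects[[j]],
                                       max.mismatch = max_mismatch,
                                       with.indels = FALSE)
      if (!length(hits)) next
      starts <- BiocGenerics::start(hits)
      mm <- vapply(starts, function(s) {
        sum(seq_chars(rs) !=
              seq_chars(substr(refset$seqs[j], s, s + nchar(rs) - 1L)))
      }, integer(1L))
      ok <- mm <= max_mismatch
      if (!any(ok)) next
      k <- k + 1L
      rows[[k]] <- data.frame(read_id = reads$id[i],
                              ref_id = names(refset$seqs)[j],
                              start = starts[ok] - 1L,
                              end = starts[ok] - 1L + nchar(rs),
                              mismatches = mm[ok],
                              stringsAsFactors = FALSE)
    }
  }
  if (!k) return(empty)
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}

# exact-match mapping of every read against every reference in one pass per
# reference (preprocessed dictionary; overlapping occurrences included)
.map_exact <- function(reads, refset, empty) {
  usable <- which(!grepl("N", reads$sequence, fixed = TRUE))
  if (!length(usable)) return(empty)
  pats <- Biostrings::DNAStringSet(chartr("U", "T", reads$sequence[usable]))
  pd <- Biostrings::PDict(pats, tb.start = 1L,
                          tb.end = min(BiocGenerics::width(pats)))
  rows <- vector("list", length(refset$seqs))
  for (j in seq_along(refset$seqs)) {
    subject <- Biostrings::DNAString(chartr("U", "T", refset$seqs[[j]]))
    hits <- Biostrings::matchPDict(pd, subject)
    n_hit <- lengths(hits)
    if (!sum(n_hit)) next
    widx <- which(n_hit > 0L)
    starts <- lapply(widx, function(w) BiocGenerics::start(hits[[w]]))
    rows[[j]] <- data.frame(
      read_id = rep(reads$id[usable][widx], lengths(starts)),
      ref_id = names(refset$seqs)[j],
      start = unlist(starts) - 1L,
      end = unlist(starts) - 1L +
        rep(nchar(reads$sequence[usable][widx]), lengths(starts)),
      mismatches = 0L, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  # canonical order: by read, then reference, then offset
  out <- out[order(match(out$read_id, reads$id), out$ref_id, out$start), ]
  rownames(out) <- NULL
  out
}

#' Screen reads against reference sets in priority order
#'
#' Each read is assigned to the first set (in list order) it maps to; reads
#' matching nothing fall through to the "novel" pool used for de novo
#' discovery.
#'
#' @param reads read table.
#' @param refsets list of reference sets, highest priority first.
#' @param max_mismatch substitutions allowed during screening (default 0).
#' @return list with \code{assignment} (read table plus \code{set} column),
#'   \code{novel} (read table), and \code{summary} (per-set read/copy totals).
#' @export
screen_reads <- function(reads, refsets, max_mismatch = 0L) {
  set_names <- vapply(refsets, `[[`, character(1L), "name")
  assigned <- rep(NA_character_, nrow(reads))
  remaining <- rep(TRUE, nrow(reads))
  for (k in seq_along(refsets)) {
    if (!any(remaining)) break
    mp <- map_reads_to_refs(reads[remaining, , drop = FALSE], refsets[[k]],
                            max_mismatch)
    hit_ids <- unique(mp$read_id)
    hit <- remaining & reads$id %in% hit_ids
    assigned[hit] <- set_names[k]
    remaining <- remaining & !hit
  }
  assigned[is.na(assigned)] <- "novel"
  assignment <- cbind(reads, set = assigned, stringsAsFactors = FALSE)
  lvl <- c(set_names, "novel")
  summary <- data.frame(
    set = lvl,
    n_reads = vapply(lvl, function(s) sum(assigned == s), integer(1L)),
    total_count = vapply(lvl, function(s) sum(reads$count[assigned == s]),
                         integer(1L)),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(assignment = assignment,
       novel = reads[assigned == "novel", , drop = FALSE],
       summary = summary)
}

#' References with enough distinct mapped reads to seed training instances
#'
#' @param mapping mapping table from \code{\link{map_reads_to_refs}}.
#' @param min_reads minimum number of distinct reads (default 2).
#' @return character vector of reference ids.
#' @export
select_instance_refs <- function(mapping, min_reads = 2L) {
  stopifnot(min_reads >= 1L)
  if (!nrow(mapping)) return(character(0))
  tab <- tapply(mapping$read_id, mapping$ref_id,
                function(x) length(unique(x)))
  sort(names(tab)[tab >= min_reads])
}

#' Export a mapping table as TSV
#' @param mapping mapping table.
#' @param path output file.
#' @export
write_mapping_tsv <- function(mapping, path) {
  utils::write.table(mapping, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a mapping table as BED6
#'
#' Intervals are written 0-based half-open on the references; strand is fixed
#' to "+" (mapping is same-strand only) and the score column carries the
#' mismatch count.
#'
#' @param mapping mapping table.
#' @param path output file.
#' @export
write_mapping_bed <- function(mapping, path) {
  if (!nrow(mapping)) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = mapping$ref_id,
    ranges = IRanges::IRanges(start = mapping$start + 1L, end = mapping$end),
    strand = "+")
  gr$name <- mapping$read_id
  gr$score <- mapping$mismatches
  rtracklayer::export.bed(gr, path)
  invisible(path)
}
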