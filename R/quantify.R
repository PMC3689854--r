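# Iso-miR grouping of reads mapped to reference miRNAs, and read-count
# expression values.

#' Group mapped reads into iso-miR variants
#'
#' Reads mapped to a reference miRNA are partitioned by their variant
#' signature: 5' offset on the reference, read length, and the set of
#' substituted positions (1-based within the read). A partition is emitted as
#' an iso-miR group iff its count-weighted share of that reference's mapped
#' reads reaches \code{frac_threshold} (default 3.5\%) and it carries at most
#' \code{max_subs} substituted positions (default 2).
#'
#' @param mapping mapping table from \code{\link{map_reads_to_refs}} restricted
#'   to miRNA references.
#' @param reads the read table the mapping was computed from.
#' @param refset the miRNA reference set.
#' @param frac_threshold minimum within-reference count fraction (default
#'   0.035). With \code{basis = "library"} the denominator is the total mapped
#'   count across all references instead.
#' @param max_subs maximum number of substituted positions (default 2).
#' @param basis "reference" (default) or "library".
#' @param total_reads library size for the expression column (default: sum of
#'   all read counts in \code{reads}).
#' @return data.frame of all partitions with columns ref_id, offset5, length,
#'   sub_positions, n_subs, n_reads, copies, fraction, expression, and logical
#'   \code{emitted}; ordered by (ref_id, fraction desc).
#' @export
group_isomirs <- function(mapping, reads, refset, frac_threshold = 0.035,
                          max_subs = 2L, basis = c("reference", "library"),
                          total_reads = sum(reads$count)) {
  basis <- match.arg(basis)
  if (!nrow(mapping)) {
    return(data.frame(ref_id = character(0), offset5 = integer(0),
                      length = integer(0), sub_positions = character(0),
                      n_subs = integer(0), n_reads = integer(0),
                      copies = integer(0), fraction = numeric(0),
                      expression = numeric(0), emitted = logical(0)))
  }
  seq_by_id <- stats::setNames(reads$sequence, reads$id)
  count_by_id <- stats::setNames(reads$count, reads$id)
  rs <- seq_by_id[mapping$read_id]
  len <- nchar(rs)
  sub_pos <- vapply(seq_len(nrow(mapping)), function(i) {
    ref <- refset$seqs[[mapping$ref_id[i]]]
    window <- substr(ref, mapping$start[i] + 1L, mapping$end[i])
    d <- which(seq_chars(rs[i]) != seq_chars(window))
    paste(d, collapse = ",")
  }, character(1L))
  key <- paste(mapping$ref_id, mapping$start, len, sub_pos, sep = "|")
  copies <- as.integer(count_by_id[mapping$read_id])
  agg_copies <- rowsum(copies, key, reorder = TRUE)
  agg_nreads <- rowsum(rep(1L, length(key)), key, reorder = TRUE)
  parts <- strsplit(rownames(agg_copies), "|", fixed = TRUE)
  # keys with an empty signature lose the 4th field in strsplit
  sig <- vapply(parts, function(p) if (length(p) >= 4L) p[4L] else "",
                character(1L))
  out <- data.frame(ref_id = vapply(parts, `[`, character(1L), 1L),
                    offset5 = as.integer(vapply(parts, `[`, character(1L), 2L)),
                    length = as.integer(vapply(parts, `[`, character(1L), 3L)),
                    sub_positions = sig,
                    n_subs = ifelse(nzchar(sig),
                                    lengths(strsplit(sig, ",", fixed = TRUE)),
                                    0L),
                    n_reads = as.integer(agg_nreads[, 1L]),
                    copies = as.integer(agg_copies[, 1L]),
                    stringsAsFactors = FALSE)
  ref_tot <- rowsum(out$copies, out$ref_id, reorder = TRUE)
  denom <- if (basis == "reference") {
    ref_tot[out$ref_id, 1L]
  } else {
    rep(sum(out$copies), nrow(out))
  }
  out$fraction <- out$copies / denom
  out$expression <- vapply(out$copies, expression_value,
                           numeric(1L), total_reads = total_reads)
  out$emitted <- out$fraction >= frac_threshold & out$n_subs <= max_subs
  out <- out[order(out$ref_id, -out$fraction, out$offset5, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Read-count expression value
#'
#' Mode "readcount" (the default) computes
#' \code{mapped_count * 1e-9 / total_reads}, the method's verbatim
#' read-count abundance formula. Mode "rpkm"
#' computes the conventional reads-per-kilobase-per-million,
#' \code{mapped_count * 1e9 / (total_reads * length_nt / 1000)}, and requires
#' the sequence length.
#'
#' @param mapped_count reads mapped to the assembled sequence.
#' @param total_reads total reads in the experiment (> 0).
#' @param mode "readcount" (default) or "rpkm".
#' @param length_nt sequence length in nucleotides (rpkm mode only).
#' @return numeric expression value.
#' @export
expression_value <- function(mapped_count, total_reads,
                             mode = c("readcount", "rpkm"), length_nt = NULL) {
  mode <- match.arg(mode)
  if (total_reads <= 0) stop("total_reads must be positive")
  if (mode == "readcount") {
    mapped_count * 1e-9 / total_reads
  } else {
    if (is.null(length_nt)) stop("rpkm mode requires length_nt")
    mapped_count * 1e9 / (total_reads * (length_nt / 1000))
  }
}

#' Write the iso-miR information sheet
#' @param groups data.frame from \code{\link{group_isomirs}}.
#' @param path output TSV; by default only emitted groups are written.
#' @param emitted_only write only qualifying groups (default TRUE).
#' @export
write_isomir_tsv <- function(groups, path, emitted_only = TRUE) {
  if (emitted_only) groups <- groups[groups$emitted, , drop = FALSE]
  utils::write.table(groups, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
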