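# End-to-end orchestration: configuration with provenance, deterministic
# parallel mapping, reference-based training-set construction, and de novo
# discovery.

#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its provenance: values marked "method"
#' are fixed by the discovery method itself; values marked "artifact" are
#' package defaults where the method leaves the choice open. See
#' \code{attr(default_config(), "provenance")}.
#'
#' @param ... overrides by name.
#' @return named list of class \code{duplexmir_config}.
#' @export
default_config <- function(...) {
  cfg <- list(
    read_len_min = 15L,        # artifact: read-length window
    read_len_max = 35L,        # artifact
    min_overlap = 5L,          # method: ">= 5 bp overlap, no mismatch"
    max_contig_len = 80L,      # artifact: duplex arms are short
    match = 2,                 # artifact: substitution scores unstated
    wobble = 1,                # artifact
    mismatch = -1,             # artifact
    gap_open = -5,             # method
    gap_extend = -2,           # method
    max_overhang = 2L,         # method: "3' overhangs with two to zero nt"
    pseudocount = 0.5,         # artifact: profile smoothing
    min_support = 5L,          # artifact: minimum cluster size
    length_tolerance = 2L,     # artifact: admissible |L - L'| at scoring
    min_cluster_n = 40L,       # artifact: minimum instances per model
    K = 100L,                  # method: max 100 iterations (min 30)
    base_max_expansions = 20L, # artifact: weak base learners
    min_leaf = 2L,             # artifact
    cv_folds = 5L,             # method: 5-fold CV post-pruning
    threshold_discover = 0.9,  # method: novel-call score cutoff
    threshold_eval = 0.5,      # artifact: plain argmax for evaluation
    max_mismatch_map = 0L,     # method: exact mapping for dataset construction
    max_mismatch_screen = 0L,  # artifact: screening tolerance unstated
    min_reads_ref = 2L,        # method: ">= 2 reads mapping" rule
    isomir_frac = 0.035,       # method: "around 3.5% of total reads or more"
    isomir_max_subs = 2L,      # method: "maximum two positions"
    workers = 1L,              # artifact
    seed = 1L)                 # artifact
  prov <- c(read_len_min = "artifact", read_len_max = "artifact",
            min_overlap = "method", max_contig_len = "artifact",
            match = "artifact", wobble = "artifact", mismatch = "artifact",
            gap_open = "method", gap_extend = "method", max_overhang = "method",
            pseudocount = "artifact", min_support = "artifact",
            length_tolerance = "artifact", min_cluster_n = "artifact",
            K = "method", base_max_expansions = "artifact",
            min_leaf = "artifact", cv_folds = "method",
            threshold_discover = "method", threshold_eval = "artifact",
            max_mismatch_map = "method", max_mismatch_screen = "artifact",
            min_reads_ref = "method", isomir_frac = "method",
            isomir_max_subs = "method", workers = "artifact",
            seed = "artifact")
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, provenance = prov, class = c("duplexmir_config", "list"))
}

config_scheme <- function(config) {
  scoring_scheme(match = config$match, wobble = config$wobble,
                 mismatch = config$mismatch, gap_open = config$gap_open,
                 gap_extend = config$gap_extend,
                 max_overhang = config$max_overhang)
}

#' Read or write a configuration as YAML
#' @param path YAML file.
#' @return a \code{duplexmir_config}.
#' @export
read_config_yaml <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' @rdname read_config_yaml
#' @param config configuration to write.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Deterministic parallel map
#'
#' Applies \code{fun} over \code{items}, preserving input order, with results
#' guaranteed identical for any worker count (workers must therefore only run
#' deterministic, RNG-free work -- in this pipeline the overlap search and the
#' duplex alignment stages). Worker errors are propagated with the failing
#' item's index.
#'
#' @param items list/vector of work items.
#' @param fun function of one item.
#' @param workers number of workers (1 = plain lapply).
#' @return list of results, one per item, in input order.
#' @export
parallel_map <- function(items, fun, workers = 1L) {
  stopifnot(workers >= 1L)
  if (!length(items)) return(list())
  if (workers == 1L || length(items) == 1L ||
      .Platform$OS.type != "unix") {
    return(lapply(items, fun))
  }
  res <- parallel::mclapply(items, fun, mc.cores = workers,
                            mc.preschedule = TRUE)
  bad <- which(vapply(res, inherits, logical(1L), "try-error"))
  if (length(bad)) {
    stop("parallel worker failed on item ", bad[1L], ": ",
         attr(res[[bad[1L]]], "condition")$message)
  }
  res
}

# assemble the reads mapped to one reference and pair its contigs
duplexes_for_ref <- function(ref_id, mapping, reads, config, scheme) {
  ids <- unique(mapping$read_id[mapping$ref_id == ref_id])
  sub <- reads[reads$id %in% ids, , drop = FALSE]
  contigs <- assemble(collapse_reads(sub), min_overlap = config$min_overlap,
                      max_length = config$max_contig_len)
  select_duplexes(contigs, scheme, workers = 1L)
}

#' Build training instances from reads and reference sets, and train
#'
#' Reads are mapped exactly onto the positive (pre-miRNA) and negative (other
#' ncRNA) references; references with at least \code{min_reads_ref} distinct
#' mapped reads seed per-reference assembly; the resulting contigs are paired
#' into duplexes that become the positive/negative instances. A held-out split
#' is evaluated and returned with the model.
#'
#' @param reads read table (uncollapsed is fine).
#' @param pre_mirna_refs positive reference set.
#' @param ncrna_refs negative reference set.
#' @param config pipeline configuration.
#' @param split_frac fraction of instances held out for evaluation (default
#'   0.5: equal train/test halves).
#' @param seed seed for the split and the ensembles.
#' @return list: \code{model} (a \code{duplex_classifier}), \code{evaluation},
#'   \code{instances} (data.frame of patterns/labels/split), \code{log}
#'   (accounting counts).
#' @export
run_train <- function(reads, pre_mirna_refs, ncrna_refs,
                      config = default_config(), split_frac = 0.5,
                      seed = config$seed) {
  if (!length(pre_mirna_refs$seqs)) stop("empty positive reference set")
  if (!length(ncrna_refs$seqs)) stop("empty negative reference set")
  reads <- collapse_reads(reads)
  keep <- nchar(reads$sequence) >= config$read_len_min &
    nchar(reads$sequence) <= config$read_len_max
  reads <- reads[keep, , drop = FALSE]
  scheme <- config_scheme(config)
  harvest <- function(refset) {
    mapping <- map_reads_to_refs(reads, refset, config$max_mismatch_map)
    refs <- select_instance_refs(mapping, config$min_reads_ref)
    dups <- lapply(refs, duplexes_for_ref, mapping = mapping, reads = reads,
                   config = config, scheme = scheme)
    list(mapping = mapping, refs = refs,
         patterns = unlist(lapply(dups, function(dl) {
           vapply(dl, `[[`, character(1L), "pattern")
         })))
  }
  pos <- harvest(pre_mirna_refs)
  neg <- harvest(ncrna_refs)
  if (!length(pos$patterns) || !length(neg$patterns)) {
    stop("could not form both positive and negative duplex instances; ",
         "check reference sets and read depth")
  }
  patterns <- c(pos$patterns, neg$patterns)
  labels <- c(rep(POSITIVE_LABEL, length(pos$patterns)),
              rep(NEGATIVE_LABEL, length(neg$patterns)))
  lens <- nchar(patterns[labels == POSITIVE_LABEL])
  if (length(unique(lens)) < 2L) {
    stop("fewer than 2 positive length clusters with support; ",
         "more read depth or references are needed to train")
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  in_train <- logical(length(patterns))
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    n_tr <- max(1L, round(length(idx) * split_frac))
    in_train[sample(idx, n_tr)] <- TRUE
  }
  model <- duplex_classifier(patterns[in_train], labels[in_train],
                             config = config, seed = seed)
  pred <- predict(model, patterns[!in_train])
  evaluation <- evaluate_predictions(labels[!in_train], pred$class,
                                     pred$positive_score)
  list(model = model, evaluation = evaluation,
       instances = data.frame(pattern = patterns, label = labels,
                              split = ifelse(in_train, "train", "test"),
                              stringsAsFactors = FALSE),
       log = list(reads_in = nrow(reads),
                  pos_refs_used = length(pos$refs),
                  neg_refs_used = length(neg$refs),
                  pos_instances = length(pos$patterns),
                  neg_instances = length(neg$patterns)))
}

#' De novo duplex discovery from reads
#'
#' Screens reads against the provided reference sets (known miRNAs, other
#' ncRNAs, transcriptome -- in the order given), collapses and assembles the
#' novel pool, pairs contigs into candidate duplexes, classifies them, and
#' reports candidates passing the score threshold with expression values.
#'
#' @param reads read table.
#' @param model a trained \code{duplex_classifier}.
#' @param screen_refsets optional list of reference sets, priority order.
#' @param config pipeline configuration.
#' @param threshold score cutoff (default \code{config$threshold_discover}).
#' @return list: \code{candidates} (data.frame, all classified duplexes with
#'   \code{called} flags), \code{screen} (per-set totals or NULL),
#'   \code{diagnostics} (stage accounting).
#' @export
run_discover <- function(reads, model, screen_refsets = NULL,
                         config = default_config(),
                         threshold = config$threshold_discover) {
  reads <- collapse_reads(reads)
  keep <- nchar(reads$sequence) >= config$read_len_min &
    nchar(reads$sequence) <= config$read_len_max
  reads <- reads[keep, , drop = FALSE]
  total_reads <- sum(reads$count)
  screen_summary <- NULL
  pool <- reads
  if (!is.null(screen_refsets) && length(screen_refsets)) {
    sc <- screen_reads(reads, screen_refsets, config$max_mismatch_screen)
    pool <- sc$novel
    screen_summary <- sc$summary
  }
  diagnostics <- list(reads_in = nrow(reads), total_count = total_reads,
                      novel_reads = nrow(pool))
  scheme <- config_scheme(config)
  contigs <- assemble(pool, min_overlap = config$min_overlap,
                      max_length = config$max_contig_len)
  diagnostics$contigs <- length(contigs)
  duplexes <- select_duplexes(contigs, scheme, workers = config$workers)
  diagnostics$duplex_candidates <- length(duplexes)
  diagnostics$unpaired_contigs <- length(attr(duplexes, "unpaired"))
  if (!length(duplexes)) {
    return(list(candidates = data.frame(), screen = screen_summary,
                diagnostics = diagnostics))
  }
  res <- classify_duplexes(duplexes, model, threshold = threshold)
  res$top <- vapply(duplexes, `[[`, character(1L), "top")
  res$bottom <- vapply(duplexes, `[[`, character(1L), "bottom")
  res$alignment_score <- vapply(duplexes, `[[`, numeric(1L), "score")
  res$read_count <- vapply(duplexes, function(d) {
    as.numeric(d$top_count + d$bottom_count)
  }, numeric(1L))
  res$expression <- vapply(res$read_count, expression_value, numeric(1L),
                           total_reads = total_reads)
  list(candidates = res, screen = screen_summary, diagnostics = diagnostics)
}

#' Run manifest for bit-exact reproduction
#'
#' Records the resolved configuration, seeds, package version and md5 digests
#' of the inputs.
#'
#' @param config pipeline configuration.
#' @param inputs named list of objects or file paths to digest.
#' @param path optional JSON output path.
#' @return the manifest list, invisibly if written.
#' @export
run_manifest <- function(config, inputs = list(), path = NULL) {
  digest_one <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      return(unname(tools::md5sum(x)))
    }
    tf <- tempfile()
    on.exit(unlink(tf))
    saveRDS(x, tf, version = 2L, compress = FALSE)
    unname(tools::md5sum(tf))
  }
  man <- list(package = "duplexmir",
              version = as.character(utils::packageVersion("duplexmir")),
              config = unclass(config),
              provenance = as.list(attr(config, "provenance")),
              seed = config$seed,
              inputs = lapply(inputs, digest_one))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
    return(invisible(man))
  }
  man
}
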