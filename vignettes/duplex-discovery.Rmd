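---
title: "Reference-free discovery of mature miRNA duplexes: methods and design"
author: "duplexmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free discovery of mature miRNA duplexes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexmir)
```

## The problem

Mature microRNAs are released by Dicer as ~21-nt double-stranded duplexes: the
mature strand paired, imperfectly, with its star (\*) strand, typically with
2-nt 3' overhangs. Practically all discovery tools require a genome or at
least precursor sequences, because they detect the hairpin around the duplex.
`duplexmir` takes the opposite route: in small RNA sequencing data both arms
of a processed duplex are usually present as reads, so duplexes can be
reconstructed from the reads alone. The pipeline is:

1. **Collapse** reads to unique tags with copy counts.
2. **Assemble** tags into contigs by exact terminal suffix–prefix overlaps of
   at least 5 nt (KMP string matching; no mismatches).
3. **Pair** contigs by global complementarity alignment (affine gaps,
   G:U wobble pairing, free 3' overhangs of 0–2 nt) and keep mutual-best
   pairs.
4. **Encode** each duplex as one string over `{M, X, I, D}`: complementary
   match, mismatch, insertion (gap in the star strand), deletion (gap in the
   reference strand). Nucleotide identity is deliberately discarded — the
   discriminating signal is the pairing-state geometry, not base composition.
5. **Profile** encoded patterns, per length cluster, as long-range
   single-order transition probabilities of non-match states (five
   subprofiles: X→X, X↔I, X↔D, I→I, D→D).
6. **Classify** the positional transition-score vectors with a MultiBoost
   ensemble of Best-First trees, one ensemble per length cluster.

No folding, no thermodynamics, no genome.

## The aligner

Columns score `match = +2` (Watson–Crick), `wobble = +1` (G:U),
`mismatch = -1`; gaps are affine with `open = -5`, `extend = -2`. The gap
penalties are the method's fixed values; the substitution scores are
package defaults (exposed in `scoring_scheme()`) because the method does not
fix them — wobble is scored between match and mismatch since G:U is a
pairing state, but a weaker one. Up to 2 terminal columns at each strand's
3' end are unpenalized and reported as overhangs (Dicer-product geometry);
5' ends are flush. Ties are resolved toward fewer gap columns, then by a
deterministic traceback. The implementation is a three-state Gotoh dynamic
program whose start/end boundary conditions realize the free overhangs in a
single pass; the test suite checks it against complete enumeration of every
alignment (short pairs) and against an independent clip-then-align reference
DP (1,000 random pairs).

```{r aligner-example}
top <- "UGAGGUAGUAGGUUGUAUAGUU"
d <- complement_align(top, reverse_complement(top))
d
encode_duplex(d)
```

## Profiles and features

Encoded patterns are clustered by exact length L (clusters below 5 patterns
merge into the nearest length). For a state-pair family (a, b) the cell
(i, j), i < j, is the smoothed conditional frequency

\[(n_{ij} + c)\,/\,(n_i + 5c),\]

with pseudocount c = 0.5 — unsmoothed zeros would make the max-scoring rule
brittle. Insertion↔deletion transitions have no subprofile and contribute 0,
matching the five families the method defines. A query pattern is scored
against every cluster within ±2 of its length (right-padded with M, which
contributes nothing); each non-M position takes the maximum cell over all
earlier non-M positions, the positional scores sum to the matrix score, and
the cluster with the maximal matrix score is the representative. Its
positional score vector — fixed width within a cluster — is the classifier
input. Conditional (rather than joint) normalization is used; both are
simple re-normalizations of the same counts, and conditioning on the
anchoring state keeps cells interpretable as transition probabilities.

## The classifier

The base learner is a from-scratch Best-First tree: binary splits on
(feature, midpoint) thresholds, frontier ordered by weighted Gini gain,
expansion stops at purity 1, fewer than 2·`min_leaf` instances, or zero gain.
The expansion sequence is recorded, so a tree can be truncated to its first
k expansions.

**Post-pruning.** Five-fold seeded cross-validation records per-instance
losses at a geometric ladder of truncation depths (0, 1, 2, 3, 5, 8, …).
The tree is cut at the shortest depth whose mean CV loss is within 2.5
standard errors (paired, per-instance differences) of the CV minimizer. A
plain "argmin of mean CV error" was rejected during development: with 30+
candidate depths the minimum of that many noisy error estimates is almost
never the root even on pure-noise labels, defeating the purpose of pruning.
The paired shortest-tree rule collapses pure noise to a root leaf and retains
full accuracy on separable and moderately noisy data.

**MultiBoost** is boosting with wagging. Weights start uniform (summing to
n); `ceiling(sqrt(K))` equal subcommittees are scheduled, and at each
boundary the weights are reset to continuous-Poisson draws (`-log U`)
rescaled to n. Each iteration fits a weighted tree; with weighted error e the
vote weight is `log((1-e)/e)`, misclassified weights are multiplied by
`1/(2e)` and correct ones by `1/(2(1-e))` — an exactly mass-conserving
update (checked to 1e-9 throughout training) — with a floor of 1e-8 and
rescaling to n. A zero-error tree receives the capped vote `log(1/1e-10)`
and triggers a reset; e > 0.5 triggers a reset and refit, at most 3 times.
Defaults: K = 100 iterations (30 is the accepted minimum),
base trees capped at 20 expansions — boosting conventionally uses weak
learners, and small trees also make the e > 0.5 path rare. Prediction sums
vote weights per class; ties go to the larger training prior, then the
negative class. The winning share (in [0.5, 1]) is the score: 0.9 is the
novel-discovery call threshold, 0.5 plain evaluation.

Per-cluster ensembles are trained for clusters with at least 40 instances;
instances in smaller clusters are re-featurized against the modelled
clusters only and routed to the best-scoring of those.

## Synthetic data: what it emulates, and what it does not

All tests run on seeded synthetic libraries (`duplex_spec()`,
`simulate_duplexes()`, `simulate_reads()`, `make_benchmark()`,
`make_planted_library()`); nothing is downloaded.

The **positive model** emulates mature duplexes: pattern lengths 19–24
peaked at 21–22 (probabilities .05/.15/.30/.30/.15/.05); a structurally
conserved mismatch pair — X at position i1 ∈ {5, 6} co-occurring with X at
i2 ∈ {L−6, L−5} — always present; a 2-nt insertion bulge at (u, u+1),
u ∈ {9, 10, 11}, with probability 0.5; a 2-nt deletion bulge at (v, v+1),
v ∈ {13, 14, 15}, with probability 0.2; background mismatch noise 0.02 on
interior columns; the three terminal columns on each side held paired
(seed-region pairing). M columns are realized as G:U wobbles with
probability 0.25; each arm carries a 3' overhang of 2/1/0 nt with
probability .7/.2/.1. Gapped states are contiguous 2-nt bulges because that
is the geometry real duplex bulges take — and the only one an affine-gap
aligner preserves: split single-column gaps cost two gap-opens and are
legitimately realigned into cheaper forms, in which case the "planted"
pattern would not be the pattern the pipeline sees. For the same reason,
positive realizations are rejection-sampled until the encoding of the arms'
own optimal alignment equals the planted pattern (self-consistency);
negatives are not constrained — only their label is ground truth.

The **negative model** mixes 60% position-independent state noise
(M/X/I/D = .80/.12/.04/.04) over lengths 18–30 with 40% state-shuffled
positives — hard negatives with identical composition but no positional
structure, so the classifier cannot win on length or state frequencies
alone.

What passing tests on this generator do **not** show: robustness to
sequencing error and adapter artefacts (reads are error-free tiles),
repeat-induced mis-assembly (planted libraries are generated mutually
overlap-free, i.e. identifiable by construction), chimeric contigs,
expression-dependent sampling biases, or the real covariance structure of
miRNA families. The benchmark measures whether the machinery — assembly,
alignment, encoding, profiling, boosting — extracts a planted pairing-state
signal at realistic sizes, not field performance on a real library.

Problem sizes used by the shipped tests and the acceptance script: 500+500
training and 500+500 testing duplexes, 10
planted duplexes + 10 decoys for discovery, K = 100, and 200 seeded read
sets for the assembler oracle. These sizes are the package's documented
study conditions.

## Numerical and degenerate-input choices

* Assembly ties (equal overlap length) break lexicographically on the merged
  sequence, making the greedy result independent of input order; containment
  is absorbed with maximal priority. Contigs longer than 80 nt are flagged
  and excluded from duplex search (duplex arms are short).
* `select_duplexes` default policy is mutual-best with each contig in at
  most one duplex; the strand with the higher read count is the reference
  (top) strand for I/D orientation, ties lexicographic.
* Profile cells with an empty conditioning count are 0; all-M patterns score
  0 under every profile and are classified by the per-cluster prior through
  the ensemble.
* Pattern/cluster length mismatches within ±2 are right-padded with M
  (contributing nothing) or truncated; farther lengths route to the nearest
  cluster and are flagged in the output.
* Empty inputs: empty FASTA/FASTQ warn and return empty tables; an empty
  reference set is allowed as a screening set but rejected for training;
  discovery with no formed duplex returns an empty report plus stage
  diagnostics.
* Parallelism (`parallel_map`) applies only to deterministic, RNG-free
  stages (overlap search, duplex alignment), so results are identical for
  any worker count; every stochastic step takes an explicit seed and model
  serialization is byte-stable.

## Known limitations

* Single-strand duplexes (mature miRNAs whose star strand was degraded below
  detectability) cannot be found — the method requires both arms.
* The expression value follows the method's read-count formula
  (`mapped_count * 1e-9 / total_reads`) verbatim in its default mode; it is
  dimensionally a scaled fraction, not an RPKM, so a conventional RPKM mode
  (requiring the sequence length) is provided separately.
* Iso-miR grouping keys on (5' offset, length, substitution positions) and
  applies the 3.5% share rule per reference by default; whether that
  share should be per-reference or per-library is ambiguous, so the
  denominator is a config switch.
* Training needs at least one length cluster with 40 instances and both
  classes; sparse libraries should lower `min_cluster_n` consciously rather
  than silently.
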