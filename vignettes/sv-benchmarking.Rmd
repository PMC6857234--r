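---
title: "Benchmarking and integrating structural variant call sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking and integrating structural variant call sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Structural variants (SVs) — deletions, insertions, duplications, inversions,
translocations of roughly 50 bp and larger — are called from long-read
sequencing data by pipelines that pair an aligner with an SV caller. Call
sets from different pipelines disagree substantially: each pipeline has its
own precision/recall trade-off, its own size-dependent blind spots, and its
own systematic artifacts, and each caller reports a different subset of
quality features in its VCF output. `svbenchr` provides the machinery to

* normalize heterogeneous SV call sets into one canonical record model,
* score a call set against a truth set with the matching rules standard in
  this field,
* merge call sets across pipelines into a consensus set filtered by
  supporting-pipeline count, and
* integrate call sets with a random-forest classifier trained on the
  caller-reported features,

together with a simulator that generates reference sequences with implanted
SVs, matching truth sets, and noisy pipeline-like call sets, so the whole
workflow can be exercised and tested end to end without any external data.

## The record model and normalization

Internally every call is an interval on a 0-based, half-open coordinate
system; VCF `POS` converts by subtracting one, BED coordinates pass through
unchanged. A single convention throughout the package prevents the
off-by-one errors that plague interval matching. Insertions are represented
by a single reference position (`end = start + 1`) with the inserted length
carried in `svlen`, which is stored as an absolute value regardless of the
sign convention in the source VCF.

Normalization applies the standard pre-evaluation filters, in this order:

1. keep only chr1–chr22, chrX, chrY (mitochondrial and unplaced-contig
   calls are dropped); names are accepted with or without the `chr` prefix
   and normalized to the prefixed form, because call sets routinely mix
   GRCh37-derived and GRCh38-derived naming;
2. keep deletions, insertions and duplications; duplications are relabeled
   as insertions — a duplication is extra sequence relative to the
   reference — anchored at the duplication start, with the duplicated span
   as the SV length. Inversions and breakends are parsed for provenance but
   excluded from evaluation;
3. filter for SV size between 30 and 100,000 bp. Both bounds are inclusive,
   matching the usual BEDTools-style closed-interval reading of a size
   range;
4. sort by (chrom, start, end) and collapse byte-identical same-category
   records to one. Only records with *identical* coordinates are merged;
   abutting (book-ended) records remain separate, since two adjacent calls
   are distinct events under a half-open representation.

Missing caller features are kept as `NA`, never zero-filled: a read-support
count of 0 and an unreported read-support count mean different things, and
downstream imputation should be explicit.

## Matching rules and metrics

Two calls match only on the same chromosome, and matching is
many-to-many — no one-to-one assignment is attempted, so a record counts
once no matter how many partners it has. This mirrors the
`bedtools intersect`/`window` semantics that the field's evaluations are
built on.

**Deletions** match by reciprocal overlap: call $c$ and truth $t$ match when

$$\mathrm{overlap}(c,t) \ge f \cdot |c| \quad\text{and}\quad
  \mathrm{overlap}(c,t) \ge f \cdot |t|,$$

with $f = 0.5$ by default and the bound inclusive — an exactly-50% reciprocal
overlap is a match. The phrase "at least 50% overlap between the two
regions" names both regions, so the reciprocal form is the default; a
one-way mode (`reciprocal = FALSE`, fraction of the call only) is provided
because the underlying intersect utility's native `-f` is one-way.

**Insertions** are points, so they match by breakpoint distance:
$|p_c - p_t| \le w$ with $w = 100$ bp by default, again inclusive.

From TP/FP/FN counts the package computes precision $TP/(TP+FP)$, recall
$TP/(TP+FN)$ and their harmonic mean F1. Zero-denominator cases return 0
with an explicit `degenerate` flag rather than `NaN`, so downstream
aggregation never silently propagates undefined values.

Size-stratified evaluation assigns each call to one bin by its `svlen`
(left-closed, right-open; the last bin right-closed so 100,000 bp is
covered). The default bins

$$[30,100),\ [100,200),\ [200,500),\ [500,1000),\ [1000,10^4),\ [10^4,10^5]$$

straddle the ~300 bp Alu peak and separate the sub-200 bp regime (where
false positives concentrate) from the rare >10 kb tail; they are fully
configurable because no canonical binning exists.

Repeat-region filtering removes calls overlapping a supplied BED of simple
repeats / low-complexity regions by at least 1 bp; insertions are tested on
their point position only, since a point either falls in a repeat or does
not.

The indexed implementations are built on `GenomicRanges::findOverlaps`; the
test suite checks them against an independent all-pairs brute force on
randomized instances.

## Consensus integration

All records of one category from all pipelines are pooled and clustered by
transitive overlap (`GenomicRanges::reduce` with a zero gap, i.e. the
connected components of the ≥1 bp-overlap graph). Insertion points are
padded by ±100 bp — the same value as the matching window, for
consistency — before clustering so positional jitter groups. Each cluster
becomes one consensus call: the envelope of its member intervals, the
median member `svlen`, and a support count equal to the number of
*distinct* pipelines contributing (two records from one pipeline count
once, which is what "identified by k pipelines" should mean). Filtering by
minimum support produces nested call sets, and scoring each against truth
yields the F1-versus-support curve. When converting insertion clusters back
to records, the position is the rounded median member position; the median
is the natural robust choice and the paper-style merge does not dictate
one.

## Random-forest integration

Every individual call from every pipeline becomes one labeled row: the
label is its TP status under the category's matching rule, and the features
are the seven caller-reported INFO attributes, in fixed order: `SVLEN`,
`DEPTHPVAL`, `RE`, `MAPQ`, `CIEND`, `CIPOS`, `PRECISE` (encoded 0/1).
Callers differ in which features they provide (Sniffles: no depth P value,
no confidence intervals; NanoSV: no read-support count; Picky: no mapping
quality, no depth P value); a missing feature is encoded as the sentinel −1
plus a 0/1 availability mask column, rather than imputed — tree ensembles
split on sentinels naturally and the choice is explicit and testable.

Rows are split 20%/80% into training and testing (unstratified uniform
split, recorded seed), and the model is a random forest fitted with
xgboost: 500 trees grown in a single boosting round with row subsampling
and per-node column subsampling, single-threaded for exact
reproducibility. Per-feature contribution percentages are the ensemble's
total-Gain importances normalized to sum to 100. Metrics are computed on
the held-out rows; rows, not post-merge clusters, are the evaluation unit
for the classifier.

## The simulator

The simulator replaces everything upstream of a call set — read simulation,
alignment, SV calling — with a two-stage model. This is its central,
deliberate substitution: read-level error modeling is out of scope, so
corruption operates directly at the call-set level.

**Stage 1 — truth generation.** SV sizes are drawn from a mixture: with
weight 0.6 a Gaussian bump at 300 ± 50 bp (the Alu peak), otherwise a
log-uniform background on [30, 100,000] bp. This reproduces the gross shape
of real truth sets: a mode at ~300 bp, most sizes below 500 bp, a thin tail
beyond 10 kb. Deletions and insertions are placed uniformly at random
without mutual overlap; `implant_svs()` additionally edits the reference
sequence (deletions remove their substring, insertions add uniform random
nucleotides at a point) and records everything needed to reconstruct the
edit. Truth coordinates are always expressed on the original reference.
The default counts (96 deletions, 181 insertions) copy the
chromosome-20-scale design of real implantation benchmarks, including the
insertion excess seen in real truth sets.

**Stage 2 — corruption.** Each pipeline profile drops truth SVs with
probability `fn_rate`, jitters kept breakpoints (Gaussian, per-caller SD)
and sizes (multiplicative Gaussian), and adds Poisson(`fp_rate · n_truth`)
private false calls placed uniformly in SV-free regions. Features are drawn
from separate true-call and false-call distributions (negative-binomial
read support, clamped-normal mapping quality, beta depth P values — small
for true calls, uniform for false ones — Bernoulli PRECISE, exponential
confidence-interval widths), then masked per caller.

Two shipped design choices deserve emphasis because the benchmark's
qualitative behavior depends on them:

* **Correlated artifacts.** If all false calls were private, any
  support-≥2 filter would remove them almost perfectly and the F1-vs-support
  curve would be trivially monotone. Real pipelines share systematic errors,
  most strongly when they share a caller. The simulator therefore draws part
  of each pipeline's false calls from shared artifact-site pools — one
  global pool and one per caller — with per-caller inclusion
  probabilities (`make_artifact_pools()`). Back-of-envelope
  Poisson-binomial arithmetic on the shipped pool sizes and probabilities
  places the deletion curve's maximum at an interior support threshold
  (k ≈ 4–5), which the default benchmark reproduces.
* **Size-skewed false calls.** By default `corrupt_truth_to_callset()`
  draws false-call sizes from the same spec as the truth, so SV length
  alone cannot separate the classes. The shipped benchmark profile instead
  uses a small-shifted spec (bump at 70 ± 30 bp, weight 0.75), emulating
  the observed concentration of false calls below ~200 bp. This ties part
  of the label signal to `SVLEN`, and the trained forest correspondingly
  ranks SV length as the dominant feature (~50–65% of total gain), with
  the depth P value second — the ordering seen when such classifiers are
  trained on real data.

What the simulator does **not** model: nanopore base-error profiles,
coverage-dependent dropout, diploid genotypes, repeat-aware placement
(placement is uniform; real SVs cluster in repeats), SV types beyond
deletions and insertions, and breakpoint micro-homology. Tests passing on
this simulator therefore validate the *bookkeeping and statistical
machinery* — matching, consensus, feature handling, training — not any
claim about a specific caller's behavior on real reads.

## The end-to-end benchmark

`run_benchmark()` chains the stages: simulate truth → corrupt into seven
pipeline call sets → per-pipeline metrics (overall and per size bin) →
consensus curve for support 2–7 → classifier training and evaluation, per
category. The default scale is a 60 Mb toy chromosome with 500 deletions
and 900 insertions: large enough that per-pipeline metrics are stable to a
few parts in a hundred and the feature matrix has ~10,000 rows, small
enough that the full run takes well under five minutes on one core. All
randomness derives from the single config seed through fixed arithmetic, so
a config determines the report byte-for-byte; sub-seeds keep every stage's
stream independent. The report writers emit TSV and JSON plus a YAML
provenance record (config, seed, version) sufficient to recompute every
number.

## Numerical and degenerate-input choices

* Overlap and window bounds are inclusive at the threshold, per the
  "at least" wording of both rules.
* Jittered coordinates are clamped to valid positions and jittered sizes to
  [30, 100,000] bp, so corruption never produces records that normalization
  would reject for being out of range.
* False calls that cannot be placed off-truth after bounded retries (a
  dense toy genome) are dropped with a warning rather than silently placed
  on truth, which would corrupt the configured rates.
* Empty call sets are legal everywhere; metrics on empty inputs return 0
  with the degenerate flag; an empty written file is a valid header-only
  VCF/BED.
* The zero-noise benchmark configuration yields all-true labels, on which
  the classifier cannot be trained; the report records that it was skipped
  instead of fabricating a fit.

## Known limitations

* BED round-trips are lossless only for the fields BED can carry; VCF is
  the full-fidelity format.
* Duplication-to-insertion conversion anchors at the duplication start;
  the alternative (end anchor) would shift matched positions by the
  duplicated span.
* Whether abutting same-category records should merge during
  deduplication is genuinely ambiguous; this package keeps them separate
  (see above), and a user wanting BEDTools-merge semantics can apply
  `build_consensus()` to a single call set pair.
* The classifier is trained and evaluated within one simulated dataset;
  cross-dataset transfer and probability calibration are out of scope.
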