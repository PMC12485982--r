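---
title: "Methods: models, parameters and design choices in procapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in procapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`procapr` analyses strand-specific nascent-transcription 5′-end signal
(PRO-cap and kindred run-on assays). This vignette is the package's own
account of the statistics it implements, the defaults it chose where the
underlying conventions are genuinely open, and what its synthetic data
can and cannot certify.

## Data model and coordinate conventions

All coordinates are 0-based and half-open (BED convention), everywhere.
The atomic observable is a `signal_track`: sparse per-base counts of read
5′ (or 3′) ends keyed by chromosome, strand and position. Minus-strand
counts are stored as non-negative magnitudes with strand as a key;
because signed minus-strand bedGraphs are common in the wild,
`read_bedgraph()` accepts that dialect and folds values to magnitudes
with a message. bedGraph is the canonical on-disk format: it is plain
text, round-trips losslessly for integer tracks, and keeps the whole test
surface binary-free.

## TRE classification

Divergent elements are pairs of opposite-strand peaks whose summits lie
within a pairing gap (default 300 bases). Several details are not forced
by that definition and were fixed as follows:

* **Distance is summit-to-summit.** Peak widths vary with the caller;
  summits are the stable anchor.
* **Greedy nearest-first matching.** Among all cross-strand candidate
  pairs within the gap, the closest is taken first (ties: leftmost plus
  summit, then leftmost minus summit); each peak joins at most one
  element. The procedure is deterministic and independent of input
  order. A test enumerates all maximal matchings exhaustively and
  confirms that the greedy result is the one whose sorted distance
  vector is lexicographically smallest; the two can differ only at exact
  distance ties, which the tests log and skip.
* **Proximity anchor is the span midpoint**, and the ±500 bp cutoff is
  inclusive ("within ±500 bp" is read as ≤ 500). Edge- or
  dominant-TSS-anchored variants would change only borderline elements;
  the midpoint is symmetric for divergent spans.
* Genomic context is intragenic on ≥ 1 bp half-open overlap with any
  gene interval.

The bundled `naive_peak_call()` (sliding-window sum ≥ `min_count` over
`window` bases, summit = leftmost maximum) exists to turn synthetic
tracks into peaks for testing; real analyses should ingest peaks from a
dedicated nascent-TSS caller as BED.

## Gene-body-ratio QC

Capped libraries concentrate reads at TSSs. Over highly expressed genes
(top 10% by sense-strand signal in the window 1 kb upstream to 100 bp
downstream of the TSS), each gene contributes a ratio
d_body / (d_body + d_TSS), where d_body is read density over the gene
body (TSS+500 to TTS−500) and d_TSS the density over TSS..TSS+500, each
normalized by region length. Genes shorter than about 1 kb have no
defined body and are skipped with a warning; a gene with no signal in
either window contributes 0.

Two aggregation modes exist because "the" per-sample ratio can be formed
either way: the default averages per-gene ratios (robust to one dominant
gene); `mode = "pooled"` sums densities across genes before a single
division. Only sense-strand reads are counted in both the ranking and the
ratio — gene-body signal is sense transcription, and mixing in antisense
reads from divergent promoters would blur the metric. The exclusion
threshold is 0.025 (fail at ≥ 0.025); the ratio is invariant to global
scaling of the library and can only grow when reads move from TSS windows
into bodies.

## Quantification and normalization

Counts are 5′ ends within element spans, both strands; overlapping
elements each count shared reads. Size factors are median-of-ratios: the
per-element reference is the geometric mean across samples over elements
with strictly positive counts in every sample (the method's defining
filter), each sample's factor is the median of its count/reference
ratios, and factors are rescaled to geometric mean 1 since the method
only identifies them up to a constant.

Downstream analyses use log2(count/s + 1). A parametric
variance-stabilizing transform would require fitting a dispersion trend;
the shifted log achieves the same practical goal for the correlation,
clustering and PCA uses the package makes of the matrix, and both the
log values and the plain normalized counts (count/s) are exposed.
`normalize_against()` scales new (query) samples by the median ratio to a
training cohort's references, so queries join an already-normalized
space without refitting it.

## Tissue specificity

q_{e,t} is the mean expression of element e across samples of tissue t.
Probabilities require non-negative values, so **q is computed from
normalized counts (count/s), not the log matrix**; the membership
t-statistic, by contrast, is computed on the log matrix, which is the
variance-stabilized scale a linear model wants. This split resolves the
ambiguity in "normalized expression" in the only internally consistent
way. Elements with zero total expression have undefined probabilities;
they are flagged and excluded from scoring and selection.

The t-statistic regresses each element's log expression on an intercept
and a ±1 tissue-membership indicator, reporting the membership
coefficient's t (residual df n − 2); for balanced designs this equals
the classical equal-variance two-sample t, which the tests verify to
1e−8, alongside a direct normal-equations oracle. Tissues need ≥ 3
samples to be tested. Zero residual variance yields ±Inf with the
coefficient's sign (a documented sentinel, ranked accordingly).

Per tissue, the specific set is the top ⌈5% of the scored union set⌉ by
t, ties broken by element id for determinism. The non-specific set is
{distal with S < 0.1} ∪ {proximal with S < 0.02} minus every specific
set. The 5% is read as 5% of the union-set count applied per tissue.

## Initiation shape

SI = 2 + Σ p_i log2 p_i over within-element positions with ≥ 1 read on
the strand; reads outside the span (possible after pooling) are ignored.
SI is 2 for a point mass and 2 − log2 L for a uniform profile over L
positions (the closed form the tests check for L = 1..64). Strands need
≥ 50 reads to be scored; thinner strands are filtered and reported, not
errored. The peaked/broad boundary is SI > −1.5 for P; exactly −1.5 is
B (the rule is a strict inequality). Pooling across samples of a tissue
sums raw counts; SI is scale-invariant per element, so per-sample
depth-scaling before pooling would only reweight samples, not change any
single-sample SI.

## Pause distances

Each read pair contributes distance 3′ − 5′ (plus strand) or 5′ − 3′
(minus strand); negative distances are malformed and tallied, not
scored. Reads attach to the element containing their **5′ end** — the
initiation site defines membership; when spans overlap, the first
containing element in table order wins. Per-element summaries use the
lower median (an actual observation).

Early/intermediate/late classes have no published numeric boundaries, so
the default is data-driven tertiles of the per-element medians with a
fixed-cut override. Pause medians are discrete and heavily tied, and a
quantile that lands inside a tied group would split it arbitrarily, so
each tertile boundary snaps to the distinct median value whose
cumulative count is closest to n/3 (respectively 2n/3): tied groups are
never split, and for continuous data the rule reduces to ordinary
tertiles. If the two boundaries coincide (e.g. all medians equal),
everything is "intermediate". Perturbation comparisons (factor-depletion
experiments) are summarized as a difference of lower medians with a
seeded percentile bootstrap (1,000 resamples by default).

## Tissue of origin

Sample dendrograms use 1 − Pearson correlation with average linkage —
the standard choice for expression matrices; both are exposed as
arguments since nothing deeper forces them. Tumour–normal similarity is
computed in the subspace of leading principal components reaching 90%
cumulative variance, with the PCA fitted on tumours and normals jointly
(the similarity question is about a shared space; fitting on normals
only is available by subsetting before the call).

The classifier is a one-vs-rest linear SVM with cost 1 on features that
are specific to exactly one tissue (elements appearing in multiple
tissues' specific sets are excluded; a tissue losing all its features is
an error naming it). "Default hyperparameters" of an unnamed
implementation are not reproducible, so the pin — linear kernel,
one-vs-rest, C = 1, no class weighting — is explicit and documented.
The trained model stores plain weight vectors and intercepts (JSON
serializable), so prediction is linear scoring with deterministic
tie-breaks by tissue name; query samples missing a feature get 0 after
normalization, with a warning.

## The synthetic generator

`truth_config()` defines the generative model; every planted quantity is
returned as ground truth. Per sample, element counts are negative
binomial with mean = baseline × tissue-activity × size factor;
defaults: baseline mean 100 reads/element, NB size 100 (the mild
overdispersion of good-quality replicate libraries), size factors
log-uniform in [0.5, 2] so normalization has something to recover.
Tissue-specific elements carry multiplier 8 in their active tissue and
0.1 elsewhere — tissue-restricted enhancers are nearly silent in
non-expressing tissues, which is what makes entropy scores informative.
Read 5′ positions follow the planted strand shape: peaked = two-sided
geometric around the summit (decay 0.5/bp; 1 collapses to a point
mass), broad = uniform over the span. Divergent elements place
opposite-strand summits a sampled gap apart (≤ 300 by default) and
split reads between strands with equal probability. 3′ ends sit a
Normal(μ, 5)-distributed offset downstream (truncated at 0), with μ
drawn per element from three regimes (25/50/90 bp) emulating
early/intermediate/late pausing. A uniform background (0.05 reads/kb
per library) adds unassigned noise. `degrade_library()` relocates a
chosen fraction of reads uniformly into gene bodies, which is what lost
cap enrichment looks like to the QC metric.

What the generator does *not* emulate: genomic sequence and motifs,
mappability artefacts, chromatin-driven covariance between neighbouring
elements, element-width variation from a real peak caller, replicate
batch structure, or heavy-tailed count dispersion differences between
tissues. Passing recovery tests therefore certifies the algorithms'
correctness on data matching these assumptions, not performance on any
real atlas; accuracy numbers from the origin classifier in particular
are generator-calibrated and say nothing about published tumour
cohorts.

The count-level cohort generator `simulate_origin_cohort()` mirrors a
15-tissue / 93-normal-sample / 23-query design; query expectations are
0.7 × primary + 0.3 × destination signature with NB noise (size 10 by
default — single biopsies are noisier than replicate means).

## Problem sizes and determinism

The recovery tests run at sizes chosen to make their statistical
assertions stable: 200 elements × 10 samples for size-factor recovery
(CV of estimated/planted < 2%), 1,000 elements for shape-label recovery
(≥ 99%), 300 elements × ~500 reads for pause recovery (median within
±1 bp; tertile classes ≥ 95%), 8 tissues × 3 samples for specificity
selection (≥ 90% of planted single-tissue elements in the right top-5%
set with S ≥ 0.5), and 20 seeded cohort replicates for origin
prediction (mean top-1 ≥ 90%, top-3 ≥ 95%, accuracy non-increasing in
noise). All generator randomness flows from a single integer seed, and
the pipeline writes md5 checksums of every output; reruns with an
identical config are byte-identical.

## Known limitations

* The naive peak caller is a fixture, not a statistical caller; real
  element calls should come from a dedicated tool.
* Differential-expression testing between conditions is out of scope;
  the package stops at normalized matrices and set definitions.
* Overlapping elements double-count shared reads in the count matrix
  (documented; disjoint element sets avoid it).
* The tertile pause classes are a descriptive device; with strongly
  non-trimodal median distributions the fixed-cut mode is the better
  tool.
* PC-space correlations depend on which samples enter the PCA fit;
  results are reported with the component count used.
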