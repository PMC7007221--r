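---
title: "Predicting regulatory variants with tissue-specific CNN ensembles: models and methods"
author: "epiconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting regulatory variants with tissue-specific CNN ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`epiconv` implements a complete sequence-to-epigenome analysis: ensembles of
multi-task convolutional neural networks (CNNs) learn to predict the
presence of epigenomic features (open chromatin, histone marks,
transcription-factor binding) in 1 kb windows of DNA; trained ensembles
score single-nucleotide variants by the change in predicted feature
probabilities between alleles; and the resulting regulatory scores are
integrated statistically with GWAS fine-mapping (credible sets, posterior
probabilities of association) and with allele-specific chromatin
accessibility read counts. Because the real studies this workflow serves
require dozens of epigenome datasets and GPU-scale training, the package
ships a synthetic-data generator that emulates the statistical structure of
such a study at desk scale, with known ground truth, so every stage is
testable end to end.

# The prediction model

## Windows and labels

Each epigenomic feature contributes a set of peaks. Every peak becomes a
window of `window_length` (default 1000 bp) centered on the peak midpoint;
windows are then greedily merged until no two overlap by more than
`max_overlap` (default 200 bp, strict inequality). When two windows merge,
the new center is the nearest integer to the mean of the original peak
midpoints weighted by the number of features on each peak, and the label
vectors are unioned. The merge order is deterministic: the
largest-overlap pair first, ties broken by leftmost coordinate. Windows
protruding beyond a chromosome end are dropped with a warning rather than
padded — padding would fabricate sequence. Sequence is one-hot encoded
(rows A, C, G, T; ambiguous bases give all-zero columns, a documented
convention), and whole chromosomes are held out as validation and test
sets so that no locus leaks across splits.

## Architecture and training

Each network has three convolutional stages (valid convolution, ReLU, max
pooling) followed by two fully connected hidden layers and a sigmoid output
with one unit per feature. The loss is mean binary cross-entropy across
features; the optimizer is RMSprop. Training stops when the mean validation
AUROC (over features with both classes present in the validation split) has
not improved for `patience` epochs (default 10), and the parameters of the
best epoch are kept. All of this is implemented in compiled code
(RcppArmadillo, im2col + GEMM); weight initialization, minibatch shuffling
and dropout use a private deterministic generator so a fixed seed
reproduces a model bit for bit.

Two defaults deserve comment:

* **Weight decay** (`weight_decay`, default `2e-3`). On desk-scale
  training sets (a few hundred windows) unregularized networks interpolate
  the training windows and behave erratically on sequence far from the
  training distribution — exactly where most credible-set variants sit.
  An L2 penalty concentrates first-layer weights on genuinely informative
  motif positions, which both stabilizes out-of-distribution predictions
  and makes variant-effect scores respond to motif disruption rather than
  to incidental wiggle. At the default the held-out classification
  performance is unchanged while variant-effect discrimination improves
  substantially.
* **Early-stopping metric.** The unweighted mean AUROC across features; a
  single stopping event for the whole multi-task model is simpler than
  per-feature stopping and matches how the stopping epoch is logged.

The ensemble is a list of independently initialized and trained members
(optionally across a hyperparameter grid); member seeds are derived
deterministically from one master seed. Predictions average member
probabilities; member-level values are always returned alongside the mean.

## Evaluation

AUROC uses the mid-rank (tie-aware) rank statistic; AUPRC uses step
integration of precision over recall with tied scores collapsed. Features
whose evaluation split contains a single class are reported as `NA`, never
as 0. Both implementations are tested against brute-force pair-counting and
threshold-sweep oracles.

# Motif discovery from first-layer filters

For each first-layer filter, activations are computed over a sample of
encoded windows. A filter is *informative* when its activation standard
deviation is positive (the strict reading of "greater than zero"; the
standard deviation is computed over the sample, as is the maximum). All
subsequence alignments activating the filter above half its maximum are
stacked into base counts, a pseudocount of 0.5 per base is added, and rows
are normalized into a position weight matrix (PWM).

PWM-to-database matching is implemented internally rather than shelling out
to an external comparison tool: the score of an alignment is the sum of
per-column Pearson correlations between the aligned probability columns,
maximized over all offsets with at least 4 overlapping columns and both
orientations; the null distribution is obtained by shuffling the database
motif's columns and re-scoring, and p-values are BH-corrected across the
database. Only the decision surface (which matches pass a 5% FDR) is meant
to emulate established motif-comparison tools; scores are not numerically
comparable to theirs. Recurrence asks, per database motif, in how many
networks its best match passes the FDR threshold; with a 1000-network
ensemble the historical threshold of 50 networks applies, and for other
ensemble sizes it scales as 5% of the ensemble unless set explicitly
(desk-scale experiments in this package use a majority threshold, 3 of 5
networks, which is far more conservative than 5%). Redundant database
motifs are collapsed greedily by descending recurrence, absorbing motifs
that match the representative at FDR < 5% as secondary motifs.

Two sizing notes matter for recurrence experiments. First, the q < 0.05
decision is only as stringent as the database is large: against a handful
of motifs, BH leaves q < 0.05 reachable by chance for a few filters per
network, so the package's benchmark experiments use a database of the
planted motifs plus 40 decoys. Second, the permutation depth bounds the
smallest attainable p (1/(shuffles+1)); with a 43-motif database, 2000
shuffles are needed for a rank-one match to clear q < 0.05 at all. Decoys
are screened to be null by the matcher's own standard (no match to a
planted motif at p ≤ 0.1), so any decoy passing recurrence would be a
genuine false positive of the procedure.

# Variant scoring

For each variant, two windows are built with the variant's position at the
window midpoint, carrying the reference and alternative allele; the
per-feature effect is the difference in predicted probability (alternative
minus reference) averaged over ensemble members, accumulated in a fixed
member order so that repeated computations are bit-identical.

The *reported* effect is always this probability difference — the scale on
which such effects are conventionally printed. The *test statistic*,
however, is by default computed on the log-odds (logit) scale
(`effect_scale = "logit"`): windows containing a functional element are
predicted near probability 1, where the sigmoid compresses even large
internal changes into tiny probability differences, while windows of
nondescript sequence sit mid-range where the same internal jitter produces
large probability differences. Standardizing raw probability differences
therefore systematically favors noise over signal; log-odds differences are
variance-stable across the sigmoid's range and restore the intended
ordering. `effect_scale = "probability"` tests the raw differences
instead.

Per feature, effects are standardized across the scored variant set
(`center = "empirical"`; `center = "zero"` is available), converted to
two-sided normal-CDF p-values (a one-sided mode exists behind the `sided`
flag, as the direction convention is a genuinely open choice), and
BH-corrected within feature. A variant's overall regulatory score is its
lowest q-value across features, reported without an extra cross-feature
correction — the minimum is a selection, not a test. Reference-mismatch
variants are skipped and recorded per variant rather than failing the run.

In-silico saturated mutagenesis evaluates the effect grid of every
possible substitution within `flank` (default 20) bp of a position for one
feature; reference-base cells are identically zero, and the per-position
importance is the largest-magnitude effect at that position, signed. The
center cell of the grid equals the scoring effect for that variant computed
on the same members, bit for bit, because both go through the same code
path. Motifs overlapping a variant are found with an internal log-odds PWM
scanner whose placement p-values come from an exact discretized
dynamic-programming null under the background composition.

# Convergence with fine-mapping

The central claim the statistics address: if CNN regulatory scores carry
causal information, variants with high posterior probability of association
(PPA) should be enriched for low q-values.

* **Threshold curves** report the fraction of regulatory variants
  (q < 0.05) among variants with PPA at or above each of 101 thresholds
  (1.00 down to 0.00 in steps of 0.01). Thresholds with empty denominators
  are carried as missing and skipped; the curve's AUC is a trapezoid over
  the defined thresholds, normalized by their span.
* **Permutation null.** q-value assignments are permuted across variants
  while credible-set memberships and PPAs stay fixed — this preserves set
  sizes, set structure, and the global number of significant variants. The
  enrichment p-value is the add-one estimator
  (1 + #{null AUC ≥ observed}) / (1 + n). A size-stratified variant
  (permuting only within credible sets of equal size) is available behind
  the `scheme` flag.
* **Rank curves** repeat the analysis by within-signal PPA rank instead of
  PPA value; tied PPAs receive average ranks with their regulatory mass
  split across the tied integer ranks, and an optional class filter
  restricts to, say, insulin-secretion signals.
* **Ranked-set enrichment** is a gage-style two-sample t-test on
  rank-transformed statistics, set versus complement, with one-sided
  p-values in both directions and BH across sets. Calibration and
  direction, not numerical equality with any particular package, are the
  contract, and both are tested against brute-force permutation nulls.
* **Group comparisons** (e.g. conservation scores of regulatory versus
  non-regulatory variants) use the Wilcoxon rank-sum test, exact when the
  smaller group has at most 10 observations and no ties occur.
* **Signal refinement** flags signals ambiguous after functional
  fine-mapping (at least two variants with fPPA ≥ 0.2) and resolves them
  to a single candidate when exactly one variant is regulatory or when the
  top variant leads the runner-up by more than 100 units of −log10(q).

# Allelic imbalance (caQTL) testing

Variants are testable when at least 2 heterozygous subjects carry them and
the counts summed across subjects have at least 5 reads per allele
(inclusive bounds; a per-subject mode exists behind a flag). The test asks
whether the summed reference count deviates from half the total under an
extra-binomially overdispersed model: a beta-binomial conditional on total
depth, whose overdispersion is estimated globally from all testable
variants by matching the median standardized squared deviation to its null
(chi-square) expectation — the median rather than the mean keeps the
estimate stable when a minority of variants carries true imbalance. With
dispersion 0 the test reduces exactly to the two-sided binomial test.
P-values are BH-corrected and caQTLs flagged at FDR 0.05.

# The synthetic study generator

The generator emulates, with known ground truth, the statistical structure
the analysis assumes:

* **Genome.** i.i.d. background bases at a configurable GC content (0.41
  by default, a typical mammalian value); no higher-order composition —
  sufficient for filter-learning tests and simple to reason about.
  Motif instances are sampled from their PWMs (the highest-information
  column forced to consensus, see below) and implanted without overlap,
  away from chromosome edges, forward strand only — a deliberate
  simplification that keeps the filter-recovery oracle crisp.
* **Peaks.** Each feature receives a peak of ±200 bp around every instance
  of its associated motifs (a binary feature × motif matrix, by default 3
  single-motif and 3 two-motif features over 3 motifs), plus Poisson
  background peaks at 5 per Mb per feature. Background peaks act as label
  noise: positives without sequence signal, as in real peak sets.
* **Credible sets.** Each of 40 signals hosts 5 variants: one causal
  variant substituting the consensus base at the highest-information
  column of a motif instance with that column's least-probable base
  (among near-ties in information content the most central column is
  chosen — disrupting an edge column is not an unambiguous
  loss-of-function), and background variants placed outside motif
  instances. Per-signal PPAs are symmetric-Dirichlet draws in which the
  causal variant carries the top value with probability exactly
  `convergence_pi` (default 0.9); fPPAs are drawn independently with their
  own convergence. The shipped motifs are sharp (per-position consensus
  probabilities 0.95–0.985): with soft motifs, training instances
  themselves average a mismatch, networks learn single-mismatch tolerance,
  and the "causal" substitution no longer guarantees a detectable
  disruption — defeating the generator's purpose of unambiguous ground
  truth.
* **Allele counts.** Per variant and heterozygous subject (4 by default),
  depth is negative-binomial with mean 50; reference counts are
  beta-binomial with allelic fraction 0.5 (non-causal) or 0.7 (causal) and
  overdispersion 0.01, a realistic magnitude for allele-specific ATAC
  data. Overdispersion 0 reduces to binomial sampling, which the moment
  tests exploit.

All randomness flows from one master seed through named substreams
(`genome`, `peaks`, `ppa`, `counts`, `models`), so any stage can be
regenerated independently and every artifact is byte-identical under a
fixed seed.

## What the generator does and does not emulate

It reproduces the *statistical* structure: multi-feature labels with
shared sequence drivers, label noise, credible sets with one causal
variant and tunable genetic-functional convergence, overdispersed allelic
counts with planted imbalance. It does not attempt realistic genome
composition, linkage disequilibrium, diploid genomes, indels, strand
symmetry of motif placement, or read-level simulation. Passing tests on
this benchmark therefore demonstrate that the pipeline's machinery is
correct and calibrated under its stated assumptions — not that any
particular real-data effect size will be recovered.

# Problem sizes used in tests and the acceptance script

The standard benchmark is a 2.1 Mb genome (5 × 420 kb chromosomes; chr4
validation, chr5 test), 3 motifs × 150 instances, 6 features,
40 signals × 5 variants, and a 5-member ensemble drawn from the small
hyperparameter grid (24–40 first-layer filters of width 14–18). These
sizes were chosen so that the full suite — training included — runs on a
single CPU in minutes while leaving all power checks comfortably away from
their thresholds; they are the package's reference configuration, stated
here so results can be reproduced exactly.

# Numerical choices and degenerate inputs

* Merged window centers round half away from zero; banker's rounding would
  make results depend on parity.
* Curve AUCs use trapezoidal integration; permutation p-values use the
  add-one estimator, so the smallest attainable p with 1000 permutations
  is 1/1001.
* Zero-variance features in variant scoring are skipped with a warning
  (their z-scores are undefined); variants whose reference allele does not
  match the genome are skipped and recorded.
* Empty peak lists, empty credible-set classes, single-class evaluation
  features, all-tied rank tests, and zero-depth count records all have
  explicit, tested behaviors (empty outputs, errors naming the problem, or
  `NA`s — never silent zeros).

# Known limitations

* Desk-scale ensembles (5–10 members) leave visible member-to-member
  variance in variant effects. The *ranking* of variants by min-q is
  informative at this scale (causal-versus-background discrimination well
  above 0.8 AUROC on the benchmark), but *absolute* significance calling at
  FDR 0.05 is conservative: only the strongest planted effects pass, so the
  per-variant detection rate is low. Large ensembles (hundreds of members)
  are what make FDR-level calling powerful in production use; the
  convergence statistics are therefore also exercised against detection
  indicators at a stated strength, separating the permutation machinery's
  power from the upstream ensemble's calling power.
* The matcher's permutation null is conditional on the database motif's
  column multiset; motifs with highly repetitive columns get conservative
  p-values.
* The caQTL test assumes a shared global overdispersion; per-variant
  dispersion is deliberately not estimated (too few subjects in realistic
  designs).
* The CNN forward pass is exactly reproducible for a fixed seed on a fixed
  BLAS; bit-reproducibility across different BLAS builds is not promised.
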