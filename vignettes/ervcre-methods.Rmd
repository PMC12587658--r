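---
title: "Identifying ERV-derived cis-regulatory elements and their dysregulation in preeclampsia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying ERV-derived cis-regulatory elements and their dysregulation in preeclampsia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervcre)
```

## The scientific problem

Endogenous retroviruses (ERVs) litter the human genome with long terminal
repeats (LTRs) that retain transcription-factor binding sites. In the
epigenetically permissive placenta, some of these LTRs act as
trophoblast-specific enhancers for nearby host genes, and their
dysregulation is a plausible contributor to preeclampsia (PE), a
human-specific hypertensive pregnancy disorder. `ervcre` implements the
computational chain used to nominate such elements and their target genes:

1. **Sequence-based enhancer scoring.** A one-dimensional convolutional
   network scores repeat-derived sequences for enhancer potential and bins
   the probability into *strong*, *weak* and *non*-enhancer calls.
2. **Chromatin support.** ChIP peaks (e.g. H3K4me1) are intersected with
   repeat annotations under 50% reciprocal-overlap semantics, and coverage
   over repeat coordinates is summarised into a scale-regions signal matrix.
3. **Target pairing.** Strong-called ERVs overlapping the 15-kb window
   upstream of a gene's transcription start site (TSS) are paired with that
   gene, and expression correlation across samples (Spearman, BH-adjusted)
   selects strong ERV-gene pairs.
4. **AP-1 motif scanning.** LTR sequences are scanned with a
   position-weight-matrix (PWM) for the AP-1 (FOS::JUN) heptamer `TGACTCA`.
5. **PE dysregulation.** DEG filtering, per-batch centering, per-gene
   relative abundance, and a one-sided hypergeometric test for
   overrepresentation of high-expressing samples among PE patients.

Because all the cohort and ChIP inputs of the original analyses are
external, every stage here is exercised on synthetic data with *planted
ground truth*, generated by the `simulate_*` family, so the recovery of each
signal can be asserted quantitatively.

## The enhancer classifier

Sequences are one-hot encoded (4 × L matrix; rows A, C, G, T; `N` columns
all-zero) after center-cropping or symmetric zero-padding to a fixed
`input_length` (default 600 bp, matching typical LTR fragment lengths). The
GC fraction is computed on the original, uncropped sequence — so cropping
cannot change it — and enters the model as a scalar side feature,
standardized with the training-set mean and standard deviation.

The default architecture is a minimal motif detector, chosen to be
CPU-trainable in minutes: 32 filters of width 12 with max-pooling 4, 64
filters of width 8, global max-pooling, the GC scalar concatenated onto the
64 pooled features, a 32-unit ReLU dense layer with dropout 0.2, and a
sigmoid output trained by Adam on binary cross-entropy. All randomness
(initialisation, shuffling, dropout) is driven by one seed, so a training
run is exactly reproducible. The default of 30 epochs was fixed from the
training-loss trajectory on the synthetic set (the loss is still falling at
12 epochs, and longer training sharpens the probability scores so that
planted enhancers clear the *strong* cut-point).

Probability cut-points default to 0.8 (*strong*) and 0.5 (*weak*), inclusive
at the lower edge of each class, so every scored sequence falls in exactly
one class. The cut-points are conventions of this package (no published
values exist for them) and are exposed in `cnn_config()` and reported in all
outputs. Scoring is single-strand: the score of a sequence is computed on
the orientation given, without reverse-complement averaging.

One design point deserves emphasis: the GC side feature is *not* the only
route by which the model can sense base composition. A convolution filter
under global max-pooling can act as a GC counter, and on a GC-only synthetic
set the sequence path alone classifies nearly perfectly. The test suite
therefore verifies the feature's wiring directly — perturbing the GC input
moves predictions if and only if `use_gc = TRUE` — rather than expecting an
accuracy collapse when the scalar is removed.

## Interval semantics

All coordinates are 0-based half-open on disk (BED convention) and
validated on read; `GRanges` is used internally. Reciprocal overlap retains
a (peak, repeat) pair iff the overlap covers at least `min_frac` of *both*
intervals, with inclusive `>=` comparisons (50 bp qualifies as 50% of a
100-bp feature). Blacklist removal uses any-overlap (`>=` 1 bp), the common
ENCODE practice. The signal matrix follows deepTools scale-regions
semantics: the interval body is resampled into `n_bins` equal windows,
flanks are binned at fixed bp width, each bin is the length-weighted mean of
overlapping coverage steps (uncovered positions count 0), and minus-strand
rows are column-reversed. Binning conserves the integrated signal to 1e-9
relative — this is asserted in the tests.

## ERV-gene pairing

"Upstream" is strand-aware: for a plus-strand gene the window is
`[tss - w, tss)`, for a minus-strand gene `[tss, tss + w)`, with `w` = 15 kb
by default. A repeat qualifies as a candidate for a gene when it overlaps
the window by at least 1 bp (full containment is not required) *and* its
enhancer class is *strong*. Candidate pairs are scored by Spearman
correlation across samples: average ranks for ties, a two-sided p-value from
the t approximation `t = rho * sqrt((n-2)/(1-rho^2))`, and
Benjamini–Hochberg adjustment over the candidate list. A pair is *strong*
when `rho >= 0.5` and `q <= 0.05`; both thresholds are package conventions
(the source analyses do not print theirs) and are arguments of
`call_strong_pairs()`.

Correlation is computed on batch-centered expression. This matters: an
additive batch shift common to all features correlates *every* feature
pair — in the synthetic conditions the null strong-pair rate is 0.67
uncorrected versus 0.00 after centering.

The correlation structure of a chosen feature set can also be clustered:
`cluster_correlation_matrix()` builds the pairwise Spearman matrix and runs
seeded k-means (Euclidean distance, 10 restarts) on its rows; `k` defaults
to the caller's choice, with `k` equal to the feature count handled as the
degenerate one-feature-per-cluster partition.

## PWM scanning

JASPAR-style counts are normalized column-wise after adding a pseudocount
(default 1) to every cell, guaranteeing strictly positive probabilities. A
window of length 7 (the AP-1 heptamer) is slid at stride 1 and scored as
`sum_i log(p[base_i, i] + eps)` with `eps = 1e-6`; an `N` contributes the
uniform `log(0.25 + eps)` unless `drop_n_windows` discards such windows. Two
scoring conventions appear in the source descriptions of this procedure —
`log(p + eps)` and `log(p + 1)` — and they are not interchangeable: with
`log(p + 1)` all scores are positive and small, incompatible with
thresholding a 7-term log-likelihood sum. This package implements
`log(p + eps)` and exposes `eps`.

The normalized score is min–max over the PWM's attainable range, mapping the
per-column argmax consensus to 1 and the anti-consensus to 0; at window
length 7 the range is verified against exhaustive enumeration of all 16,384
heptamers. Two threshold modes exist because two thresholds are on record
for this procedure: `normalized` mode (default, threshold 0.5, i.e. roughly
"at least 4 of 7 consensus matches" for a sharply peaked PWM) and `raw`
mode (threshold 8). Note that raw log-probability scores are necessarily
negative, so a raw threshold of 8 can never pass — the raw-score scale
behind that published threshold is unstated, and the package deliberately
leaves the mode explicit instead of guessing a rescaling. Scanning is
forward-strand by default (LTR consensus sequences have a defined
orientation); `both_strands = TRUE` adds the reverse complement with a
strand column.

The normalized threshold of 0.5 is permissive: on random background roughly
7% of windows pass a sharply peaked heptamer PWM. That is a property of the
published procedure, not of this implementation; users wanting specificity
should raise the threshold.

## The dysregulation stage

DE tables are filtered with strict inequalities, adjusted p < 0.05 and
log2 fold-change > 1 (absolute value in two-sided mode). The adjustment
method is assumed to be Benjamini–Hochberg wherever tables carry an
"adjusted p"; `bh_adjust()` wraps `stats::p.adjust` and is cross-checked in
the tests against the direct step-up formula.

Batch adjustment is a transparent location/scale stand-in, not a
reimplementation of ComBat's empirical-Bayes shrinkage: within each batch
every gene is standardized and then restored to the pooled gene mean and
standard deviation, and a PC1-versus-batch R² diagnostic is reported before
and after so residual batch variance is visible. ComBat itself is an
established external method and deliberately out of scope here.

Relative abundance is the ratio of a gene's expression in a sample to the
gene's cross-sample mean, computed on the linear TPM scale (`2^x - 1` for
log2(TPM+1) input) because a ratio of log values is not a fold measure; the
per-gene mean of ratios is exactly 1. "Relatively high" samples are those
with ratio strictly above 1 (the mean; a median reference is a one-line
change via the threshold argument). Enrichment of high samples in the PE
group is the one-sided upper hypergeometric tail, computed with log-binomial
arithmetic, stable to N = 10,000 and verified against full enumeration.

With the cohort geometry of 24 PE / 22 control and high fractions of 60%
and 25%, the planted counts are 14 high PE samples and 5.5 high controls;
both integer roundings give p = 0.0150 (5 controls) and p = 0.0333
(6 controls), bracketing the 0.03 bound this statistic is known to satisfy.

## What the synthetic data emulate — and what they do not

The generators are pure functions of a `sim_config()` and its seed; same
seed, byte-identical files. Defaults encode the study conditions:

* **Genome/repeats** — 2 chromosomes × 600 kb at 41% GC (human-like), 60
  non-overlapping 600-bp repeats, 40% of them "enhancer" repeats carrying
  two embedded `TGACTCA` copies and +0.10 GC, labelled with ERV3/MLT1-style
  families; 30 genes with strand and TSS; 10 planted (ERV, gene) pairs with
  the repeat wholly inside the gene's 15-kb upstream window.
* **Training set** — 200 positives (motif + GC shift) and 200 negatives
  (i.i.d. background; chance motif occurrences are not suppressed), 600 bp.
* **ChIP** — every enhancer repeat covered by a peak jittered within ±10% of
  its length (reciprocal overlap ≥ 0.8 by construction), 5% off-repeat
  decoys, coverage 1 with plateaus of 10.
* **Expression** — genes ∪ ERV loci on log2(TPM+1), i.i.d. N(4, 1)
  background; planted pairs from a Gaussian copula with
  `r = 2 sin(pi * rho_s / 6)` so the Spearman target (0.9) is hit in
  expectation; 24 PE / 22 control samples in two balanced batches with +2 on
  batch 2; one gene shifted +1.5 in 60% of PE and 25% of control samples.
* **DE tables** — 400 genes, 25 planted common DEGs passing the strict
  filter in both tables with fold-changes rank-correlated at 0.9 via a
  monotone transform of the copula; all other genes fail at least one
  criterion per table.

These are deliberately clean: sequencing noise, repeat-family sequence
divergence, mappability artifacts, peak-caller idiosyncrasies, correlated
gene networks and realistic batch × condition imbalance are all absent.
Passing tests therefore demonstrate that the machinery recovers signals it
was built to detect at realistic sizes — not that it would perform equally
on real cohort data.

One planted signal is *not* fully recoverable by design: with background
noise sd 1 and an overexpression shift of +1.5, flagging samples by relative
abundance > 1 recovers the planted high set only partially (roughly 60–80%
of high samples flagged and 10–25% of low ones), so the downstream
hypergeometric test reaches p ≤ 0.05 in only a minority of replicates even
though the test is exact and the flagging is faithful. With perfect recovery
of the planted memberships the p-value is 0.015–0.033 deterministically.
This attenuation is reported honestly by the acceptance machinery rather
than hidden by narrowing the noise.

## Numerical choices and degenerate inputs

* Thresholds are inclusive (`>=`) at every lower class edge; DEG filters are
  strict (`<`, `>`) as published.
* Spearman p-values use the t approximation; `rho = ±1` reports the smallest
  positive double rather than 0. Zero-variance vectors flag `rho = NA`.
* A uniform PWM has zero score range; its normalized score is defined as 1
  with a warning.
* All-N sequences encode to an all-zero matrix with `gc = 0` and a flag.
* Genes constant within a batch skip the scale step of batch centering.
* Intervals shorter than the bin count are binned on fractional boundaries
  with a warning rather than dropped.
* Problem sizes in tests: the unit tests run a reduced genome (200 kb
  chromosomes, 20 repeats, 300-bp sequences) and a small network; the
  acceptance tests run the full default conditions, including the 400-
  sequence classifier experiment and 100 dysregulation replicates.

## Known limitations

* The classifier is a minimal CNN; no strand averaging, no published
  enhancer compendia, no architecture search.
* The batch stand-in removes location/scale effects only; interaction
  effects survive it.
* PWM scanning has no genomic background model (no log-odds scoring) and no
  JASPAR retrieval; counts come from a file or from
  `consensus_pwm_counts()`, which is synthetic and clearly labelled as such.
* The pipeline's DE filter stage uses a convenience Wilcoxon test on the
  synthetic expression; real analyses should supply DE tables from a
  dedicated caller.
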