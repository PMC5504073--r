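---
title: "Methods: consensus peaks, two-part CTCF motifs, repeat association and Hox landscapes"
author: "ctcfLandscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus peaks, two-part CTCF motifs, repeat association and Hox landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ctcfLandscape characterises a species' CTCF binding landscape starting from
ChIP-seq *peak calls* (not reads): it selects reproducible and significant
peaks, discovers the two-part CTCF recognition sequence de novo, tests which
repeat families carry binding sites, and maps oriented sites across Hox
clusters. This vignette is the package's account of the underlying models,
the tunable parameters, and the design choices that were genuinely open.

## Peak selection

Peak calling is assumed done (e.g. MACS2) for three runs per sample:
replicate 1, replicate 2, and the merged replicates. A **consensus peak** is
a merged-run peak that overlaps, by at least one base, at least one peak in
*each* replicate. Coordinates, summit and fold enrichment (FE) are taken
from the merged run, because downstream FE cutoffs are defined on merged-run
values. Two readings of a "three-way intersect" exist — truncating peaks to
the common intersection versus keeping whole peaks — and the package keeps
whole merged-run peaks; the alternative would shrink scan windows around
summits, which are the only coordinates used downstream anyway.

**Significant peaks** are consensus peaks with merged-run FE at or above an
explicit cutoff (boundary inclusive). `suggest_fe_cutoff()` reports the mean
consensus FE and the largest of {5, 10, 20} below it — mirroring how such
cutoffs are chosen in practice, by reference to the mean — but the cutoff is
always an explicit argument, never silently derived.

Peak sharing between samples (`shared_fraction()`) uses the same ≥ 1 bp
overlap rule. No reciprocal-overlap refinement is applied; with ~100–500 bp
peaks and summit-anchored analyses the simple rule is the behaviour of the
standard interval tooling this stage emulates.

## Motif model

The CTCF recognition sequence is modelled in two parts: a 16-bp **core**
position weight matrix (PWM) and a shorter **upstream (M2) motif** expected
within 20 bp 5′ of the core *on the core's own strand*. Core width is fixed
at 16; the upstream width defaults to 10 and is configurable, since the
second motif's width is a modelling choice rather than a constant of nature.

### Background model

`train_markov_background()` fits an order-1 Markov chain on the summit ± 100
bp windows of the top-2,000 peaks by FE, with pseudocount 0.01 on every
(context, base) cell, counting both strands so the model is
reverse-complement symmetric. Discovery uses the full order-1 model;
scanning p-values use its order-0 marginal (`background_order0()`), because
the exact p-value dynamic programme is defined over independent positions —
the convention of standard PWM scanners.

### Discovery: ZOOPS EM

`em_discover()` fits the "zero or one occurrence per sequence" (ZOOPS)
model: sequence *i* with $P_i$ candidate positions (both strands) either
contains one motif occurrence (prior $\gamma / 2P_i$ per position and
strand) or none (prior $1-\gamma$). The E-step computes posterior occurrence
weights from the PWM-to-background likelihood ratio of every window; the
M-step re-estimates the PWM from expected base counts plus pseudocount and
updates $\gamma$. The log-likelihood is non-decreasing by construction and
asserted at every iteration. Restarts are seeded from the most
over-represented width-w words (count first, then count relative to
background probability); each restart runs 5 burn-in iterations and the best
continues to convergence (tolerance $10^{-4}$, at most 100 iterations).
ZOOPS (not OOPS/ANR) is the right family here because not all peaks harbour
the motif.

Two deliberate safeguards:

* **Null calibration.** Maximum-likelihood ZOOPS EM sharpens even on pure
  background — with hundreds of windows per sequence, some word pattern
  always fits a subset. `em_discover()` therefore re-runs itself on
  per-sequence shuffled copies of the input and requires the real fit's
  log-likelihood gain to exceed twice the shuffled fit's; otherwise it
  reports "no motif" (a background-flat PWM, `significant = FALSE`). On
  planted data the two gains differ by roughly two orders of magnitude, so
  the factor-2 margin is conservative in both directions.
* **Orientation.** A single-motif two-strand EM determines the core PWM only
  up to reverse complement. The two-part geometry disambiguates:
  `two_part_pipeline()` discovers the upstream motif in the 20-bp 5′
  extensions under both core orientations and keeps the orientation whose
  upstream PWM is more informative. With no real upstream motif both fits
  collapse to flat under the null calibration and the EM's arbitrary
  orientation is kept, which is then genuinely arbitrary.

### Scanning: exact p-values by dynamic programming

`score_pvalue_table()` discretises each log-odds column to a shared integer
grid (default 1,000 bins per column, rounding down, hence conservative
p-values) and convolves column distributions under the order-0 background to
get the exact null distribution of the integer score. The scanner uses the
*same* integerised matrix, so every reported score has an exactly consistent
p-value; tests verify the distribution against full enumeration of all
$4^w$ words for widths up to 5. Scanning covers both strands; minus-strand
hits are reported on the forward-strand footprint; windows containing `N`
skip those positions. Thresholds follow the two-stage convention: core at
p ≤ 1e-4 genome-wide, upstream at p ≤ 1e-3 within the 20-bp extension, and
p ≤ 1e-3 for the cross-cluster orientation calls. When several hits fall in
one peak, the lowest p-value wins, with deterministic ties (higher score,
leftmost start, then + strand).

The pseudocount 0.01 is applied consistently in PWM estimation and before
taking log-odds for scanning.

## Repeat-family association

For each repeat family the question is whether its copies coincide with
CTCF binding more often than chance. The pipeline: consensus peaks with FE ≥
5 → summit ± 50 bp windows → `n` control regions (default 50,000 of 100 bp
at genome scale; 2,000 at the simulator's scale) sampled uniformly over
eligible start positions, rejecting candidates containing `N` or overlapping
an already accepted region (retry cap 50·n, then a capacity error naming the
shortfall) → per family, the number of copies touched by ≥ 1 peak window
(`a`) and by ≥ 1 control region (`c`), each copy counted once → the 2×2
table `[[a, n_peaks − a], [c, n_controls − c]]` → two-sided Fisher's exact
test (probability method) and the conditional-MLE odds ratio → q-values
across families. The table mixes units (repeat copies against region
totals); this construction is adopted because it exactly reproduces the
published per-family odds ratios from their printed counts, which is the
operative definition of the statistic. Both the conditional-MLE and the
sample odds ratio are available; the two differ by < 0.1% at the published
counts.

Q-values use Storey's fixed-λ estimator (λ = 0.5,
$\hat\pi_0 = \min(1, \overline{\mathbb{1}[p>λ]}/(1-λ))$) followed by the
step-up rule, or Benjamini–Hochberg ($\pi_0 = 1$); the automatic default
switches to BH below 50 families because $\hat\pi_0$ from a handful of
p-values is noise. A family is *called* associated when q < 1e-10 and odds
ratio > 10 — deliberately stringent, since genome-scale margins make
mild q-significance uninteresting.

Control sampling is deliberately plain — no GC matching, no chromosome
stratification, and control regions may overlap peaks — matching the
arbitrary-regions design this stage reproduces. A flag to exclude
peak-overlapping controls was considered and left out: at realistic peak
densities (< 1% of the genome) its effect is far below the decision
thresholds.

## Hox-cluster landscapes

`hox_cluster()` normalises each cluster to a frame in which position 0 is
the low-paralog (3′) end and coordinates increase with paralog-group number;
the axis is inferred from the gene order and validated (non-monotone
paralog order is an error). Orientation **forward** means the core motif's
5′→3′ direction points toward higher paralog groups; a motif near a cluster
end is **outward** when it points away from the span between the first and
last gene bodies — reverse at the 3′ end, forward at the 5′ end. Peaks are
assigned to intergenic segments *by summit* (the binding-point estimate),
with within-gene and flank positions labelled as such; the flank window
defaults to 10 kb. The Hox1–4 count covers all intergenic segments strictly
between the group-1 and group-4 gene bodies. Cross-cluster comparison keys
segments by paralog-group pairs ("5-6", "8-9"), so homologous segments align
across clusters and species; "shared positioning" is formalised as a
segment occupied in ≥ k clusters (default 2) — one defensible reading of
what is inherently a visual claim.

## The synthetic-data generator

`generator_config()` fixes the study conditions under which every recovery
property is tested; the defaults are chosen once as a realistic desk-scale
emulation, not tuned per test:

* **Genome:** 4 Mb in 2 chromosomes from an order-1 Markov chain with mild
  AT richness and CpG depletion; optional N blocks for control-sampling
  tests. The 4-Mb scale keeps every repeat family's footprint density low
  enough that the q < 1e-10 / OR > 10 rule can in principle separate a
  genuinely associated family from chance — at 2 Mb the associated family's
  own footprint density forces its odds ratio under the decision threshold,
  making the rule untestable.
* **Repeats:** five families (120–350 copies, 120–420 bp consensus, 10%
  per-copy divergence, substitutions only). One family's consensus embeds
  the 16-bp core, so binding sites propagate with the repeat — the
  hAT-Tip100-style carriage mechanism.
* **Sites:** 1,500 true sites with ≥ 500 bp spacing; 20% refreshed inside
  copies of the motif family, the rest in repeat-free background; 50% carry
  the upstream motif 6 bp 5′ of the core; per-position site mutation rate
  0.05 — strong, mostly-intact sites, as observed for CTCF.
* **Peaks:** each site is detected per replicate with probability 0.85; the
  merged run detects the union. FE is log-normal, mean 15 for sites versus
  3.5 for noise peaks, which is what couples FE to motif presence. Noise
  peaks are placed independently per run and > 600 bp from any true site,
  so they can neither form three-way consensus nor rescue half-detected
  sites into it — this keeps the consensus recovery rate at its analytic
  p² expectation.
* **Samples:** "embryo" and "liver" share 75% of their sites (1,200 each
  from the 1,500-site pool), with the repeat-borne sites in the shared
  block.

What the generator does **not** emulate: read-level noise, fragment-size
effects, GC bias, indel divergence of repeats, copy-number variation, or
chromatin context. Passing recovery tests therefore demonstrates the
correctness of the pipeline's logic under its stated model, not performance
on real libraries.

Problem sizes in the test-suite and acceptance runs: the full default bundle
(4 Mb, 1,500 sites, ~900–1,000 consensus peaks) for recovery properties;
300 kb / 150-site configurations for unit tests; enumeration oracles at
widths ≤ 5 and margins ≤ 60. These sizes make the whole suite run in a few
minutes on one CPU while keeping every statistical check adequately powered.

## Numerical and convention notes

* In memory, all intervals are `GenomicRanges` (1-based, closed) — the
  universal convention of R genomics; converters at the IO boundary handle
  BED/narrowPeak (0-based half-open) and RepeatMasker `.out`/GFF3 (1-based
  closed). Overlap semantics are unaffected.
* narrowPeak summit offsets are required (`-1` is a format error): every
  downstream stage is summit-anchored.
* FASTA input is case-folded; IUPAC ambiguity codes become `N` (conservative
  for every downstream use; a warning counts them).
* Score discretisation rounds down, so scan p-values err on the conservative
  side; at 1,000 bins per column the bias is far below any threshold used.
* All randomness (control sampling, EM tie-breaks, the generator) flows from
  explicit integer seeds recorded in outputs, so whole-bundle byte-identical
  reproducibility holds.

## Known limitations

* The EM implements single-motif ZOOPS; it does not rank multiple motifs by
  E-value as a full MEME search would. For this pipeline — one core, one
  upstream motif — that is the intended scope.
* The upstream-motif scan is restricted to the core's strand and its 20-bp
  5′ extension; a divergent two-part geometry would not be found.
* Storey's π0 estimator is unstable for small family counts (hence the BH
  default below 50 tests).
* The rejection sampler for control regions can, on adversarially tiny
  genomes, fail to find a non-overlapping packing that does exist; it
  reports a capacity error rather than backtracking.
* In-silico prediction of binding sites in unassayed species is out of
  scope: a PWM scan alone is not a reliable predictor of in-vivo binding.
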