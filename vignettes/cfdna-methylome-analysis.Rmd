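---
title: "Methods: differential methylation and hotspot analysis of pooled cfDNA methylomes"
author: "cfmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation and hotspot analysis of pooled cfDNA methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfmeth)
```

## The problem

Plasma cell-free DNA (cfDNA) carries a mixture of DNA from normal and, in
cancer patients, tumor cells. Whole-genome bisulfite sequencing (WGBS) of
pooled plasma turns each CpG into a pair of read counts — reads supporting
methylation and reads supporting non-methylation — and tumor-derived signal
appears as two superimposed distortions of the methylome: a *global*
reduction of the predominantly high background methylation, and *focal*
hypermethylation of individual CpG islands that are unmethylated in normal
tissue. The analytic task is to compare pooled methylomes (here labelled H,
DFS, MBC for healthy, disease-free survivor, and metastatic-cancer-like
pools), quantify both distortions, and distill the focal component into a
small panel of island "hotspots" usable as a blood-based biomarker.

`cfmeth` implements that workflow end to end: per-base two-group
differential methylation, genomic-context annotation, island hotspot
calling, pool similarity analyses, cross-platform concordance, and a
synthetic-data generator with planted ground truth so every step can be
tested for recovery and calibration.

## Per-base differential methylation

At each CpG retained by the coverage filter the two pools form a 2×2 table
(methylated/unmethylated × case/control). The package computes:

* **Fisher's exact test**, two-sided, by conditioning on both margins: the
  p-value is the total conditional (hypergeometric) probability of all
  tables whose point probability does not exceed that of the observed table.
  The computation runs in log space so deeply sequenced tables do not
  underflow, and p-values are never reported as 0.
* **DMV (differential methylation value)** — the difference in percent
  methylation, case minus control, on the 0–100 scale.
* **Benjamini–Hochberg q-values** over all united loci, via
  `stats::p.adjust`.

A locus is a DML (differentially methylated locus) iff |DMV| ≥ 20, p ≤ 0.05,
and — only when a q bound is explicitly set, as in targeted amplicon
validation (q ≤ 0.5) — q below that bound. All thresholds are *inclusive*:
a locus at DMV exactly 20 is called; tests pin this down to one ULP. The
coverage floor is ≥ 5 reads in **each** group, applied after destranding;
sex chromosomes (`X`, `Y`, `chrX`, `chrY`) are removed before testing.

Destranding merges the two cytosines of each CpG dyad (minus-strand counts
at position *p* are added to the plus-strand cytosine at *p − 1*). It is on
by default — the two strands measure the same biological methylation state,
and merging doubles the effective coverage — but can be disabled
(`diffmeth_params(destrand = FALSE)`); whether the original analysis merged
strands is not documented, so both modes are supported. Minus-strand loci
without a plus partner are kept at their dyad position and counted in a
message, rather than dropped silently.

Direction is fixed by convention: group A (the first argument of
`call_dml()`) is the case, and `hyper` means DMV > 0, i.e. the case pool is
more methylated.

## Context annotation

Each DML is labelled with every genomic context whose intervals contain its
position: CPGI, TSS1500 (1500 bp upstream of the TSS), UTR5, Exon1,
GeneBody. Assignment is deliberately **multi-label** — a promoter-island
locus counts in both CPGI and TSS1500 — because per-context summaries are
reported per context, not as a partition; this changes denominators relative
to a priority scheme and is therefore stated prominently. Loci in no track
appear only in the genome-wide row. Overlapping intervals within a track are
never merged, and chromosome namespaces (`chr1` vs `1`) are never coerced —
a disjoint namespace raises an error instead of silently annotating nothing.

## Island hotspot calling

The biomarker rule: an island is a hotspot iff it contains at least
`min_dml = 8` hypermethylated DML with DMV ≥ `min_dmv = 50`. The DMV bound
is inclusive (the rule is stated both as "greater than 50" and "≥ 50" in
different places of the original description; the delivered signature
matches the inclusive reading, and the bound is configurable). No adjacency
or maximum-span constraint is applied to the 8 loci; the call reports the
full island interval, with the minimal window spanning the qualifying loci
as auxiliary columns. When two case comparisons are available (case vs each
control), their intersection gives the consensus signature.

## Pool similarity

Profiles are percent methylation at the loci covered ≥ 5× in *every* pool —
the same floor as DML calling, a documented convention since the original
restriction is unstated. On these common loci the package computes pairwise
Pearson correlations, Ward clustering (`ward.D2`) on the correlation
distance 1 − r, PCA of the centered profiles (component signs fixed by
making the largest-magnitude loading positive), and equal-width histograms
of percent methylation over [0, 100]. Zero-variance profiles yield `NA`
correlations with a warning, never a silent 0.

## Cross-platform concordance

Targeted deep re-sequencing of a few amplicons is emulated by re-measuring
the same underlying per-locus proportions at ~250× the WGBS depth. Loci
inside the target regions measured on both platforms are paired by exact
locus identity (after identical destranding); the report gives pooled
Pearson r and **R² defined as r²** — stated explicitly because R² could
otherwise mean a regression goodness of fit. Per-amplicon case/control
tests aggregate counts within each amplicon into one 2×2 Fisher test, with
BH correction across amplicons (the q ≤ 0.5 convention). The analysis pools
pairs across all three pools, as a validation spanning near-0% controls and
high-methylation cases must.

## The synthetic-data generator

`simulate_study()` generates the three-pool study the analyses assume:

* **Genome.** One 2 Mb chromosome, 200 non-overlapping CpG islands
  (400–1200 bp; 30% centered on the promoters of 100 simulated gene models,
  the rest intergenic), CpG dyads placed with mean spacing 125 bp outside
  islands and 4× denser inside (gaps are 2 + Geometric, so the density
  ratio is exact in expectation). Context tracks (TSS1500, UTR5, Exon1,
  GeneBody) derive from the gene models. This yields ~20,000 dyads — a
  desk-scale genome that runs in seconds.
* **Per-locus baselines.** Each locus draws a true methylation proportion:
  Beta(1, 19) inside islands (mean 0.05, the unmethylated island state) and
  Beta(12, 1.5) in the background (mean 0.89, the "major peak close to 1").
  The baseline is a *locus* property: all pools of one study share the
  proportion stream, so pools with identical parameters differ only by
  measurement noise and form a sharp null for the exact test. Independent
  landscapes are available by passing different `prop_seed` values.
* **Pool distortions.** The affected (MBC-like) pool subtracts a global
  shift from background proportions only (islands stay low), and redraws
  proportions inside the planted islands around `planted_hyper_level = 0.9`
  (Beta with concentration 30). The shift default is **0.25**, a free
  parameter with no measured counterpart: it was fixed, once, by a
  design-phase calibration so the generator reproduces the qualitative
  structure the analyses are meant to detect — a visibly left-shifted
  percent methylation histogram and >90% hypomethylated DML in the affected
  pool, while unshifted pools correlate at r ≈ 0.92–0.95. Smaller shifts
  (≤ 0.15) leave the left shift within sampling noise and the
  hypomethylated fraction below 90%, i.e. a generator that does not produce
  the phenomenon under study.
* **Counts.** Coverage per strand-cytosine is negative binomial with mean
  `depth_mean` (defaults 7.4 / 9.6 / 16.9 for H / DFS / MBC, the reported
  study depths; variance = μ + 0.25 μ²), drawn independently for the two
  strands of each dyad so destranding is exercised; destranded dyad coverage
  is about twice `depth_mean`. Methylated counts are beta-binomial with
  intra-pool correlation ρ = 0.02 (pooled plasma from tens of donors is
  mildly overdispersed relative to binomial); ρ = 0 recovers binomial
  exactly, which is what calibration tests use.

**What the generator does not emulate:** read-level artifacts (bisulfite
conversion failure, mapping bias, PCR duplicates), copy-number alterations,
cell-type deconvolution structure, distance-dependent correlation between
neighbouring CpGs, and partially methylated domains. Passing tests therefore
demonstrate correctness of the statistics and recovery under the stated
generative model — not performance on real plasma WGBS, where effect sizes,
within-island heterogeneity and coverage biases are less favourable.

## Numerical and design choices

* Internal coordinates are 1-based cytosine positions; intervals 1-based
  closed. The BED 0-based half-open conversion happens exactly once, at
  read/write boundaries (property-tested on random intervals).
* Zero-coverage rows are retained at parse time (they carry positional
  information) and excluded only by the coverage filter, so filtering is
  observable in one place. Every filtering stage logs input count, output
  count, and the rule.
* p-values are exact and bounded below by the observed table's probability
  (and by the smallest positive double under extreme depth); q ≥ p holds
  elementwise after BH monotonicity enforcement.
* All randomness flows from one root seed through per-stage substreams
  (`derive_seed()`), so adding a stage never perturbs another stage's
  draws, and `run_pipeline()` reruns are byte-identical (timings go to a
  separate log, not the manifest).
* Default problem sizes used by the test suite: the 2 Mb / 200-island /
  ~20,000-dyad genome above, with recovery and null calibration repeated
  across 5 seeds; the exact-test oracle sweep enumerates every 2×2 table
  with total ≤ 40.

## Known limitations

The exact test treats pools as two homogeneous groups; it does not model
between-individual variance inside a pool (a beta-binomial *test* is out of
scope by design, though the *generator* produces overdispersed data, which
is one reason the null-calibration check uses ρ = 0). Hotspot calls inherit
the island definitions supplied by the user — no island annotation is built
in, because the original coordinate source is unspecified. The 21-gene
hotspot identity of the original study cannot be reproduced without the
patient data; recovery is therefore scored against planted synthetic truth
instead.
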