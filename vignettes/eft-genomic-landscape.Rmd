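---
title: "Methods: genomic-landscape analysis of Ewing sarcoma family tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic-landscape analysis of Ewing sarcoma family tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eftlandscape)
library(dplyr)
```

## The analysis problem

The Ewing sarcoma family of tumors (EFT) is a group of small round blue
cell sarcomas driven, in the large majority of cases, by a TET-ETS fusion
oncogene (most commonly EWSR1-FLI1). Beyond the fusion, EFT carries one of
the lowest somatic mutation burdens of any cancer (~0.15 coding mutations
per megabase), so cohort-level conclusions rest on a small number of
recurrently altered tumor suppressors — STAG2, TP53 and CDKN2A — detected
through several complementary evidence channels: somatic point mutations
and indels, coverage-based copy-number loss, and loss of RNA expression.
This package implements that multi-channel evidence cascade as reusable,
tested, tibble-in/tibble-out functions:

1. **Somatic filtering** — panel-of-normals artifact removal, somatic-score
   cutoff calibration against orthogonally verified calls, the rare
   protein-altering consequence filter, and mutation-rate summarisation.
2. **Structural variants and CNV** — discordant-mate-pair junction
   filtering, copy-number segment confidence classification, and a
   coverage-ratio CNV caller for targeted sequencing.
3. **Expression** — exon-level RPKM, median normalisation against a
   normal-tissue panel, exon z-scores, expression-loss and
   contiguous-exon-loss detection, Welch group comparison, signature
   scoring, and Ward/Euclidean sample clustering.
4. **Alleles and fusions** — RNA variant allele frequency,
   allele-specific-expression classification, fusion reading-frame
   annotation on transcript models, and TET-ETS subtype labelling.
5. **Cohort integration** — the oncoprint alteration matrix, mutational
   frequencies, union coverage, mutual exclusivity, and Fisher exact
   enrichment.
6. **A synthetic cohort generator** that emulates the statistical
   structure all the above assume, so the full cascade is testable
   end-to-end without any sequencing data.

## Models and procedures

### Somatic-score calibration

Platform somatic scores (a Bayesian confidence over read depth, base
quality and mapping probability) are calibrated against a verified label
set. For each candidate cutoff $c$, predicted-positive means score
$\ge c$, giving sensitivity $TP/(TP+FN)$ and specificity $TN/(TN+FP)$.
The operating point is the smallest cutoff meeting the configured minima,
or, absent minima, the smallest cutoff maximising Youden's
$J = \text{sens} + \text{spec} - 1$. Sensitivity is non-increasing and
specificity non-decreasing in the cutoff by construction, which the test
suite asserts against a brute-force confusion-matrix oracle. Downstream
filtering keeps calls at or above the cutoff *plus all verified calls
below it*. The shipped default operating point is 3, the conventional
cutoff for this score in low-burden tumors; the verified label counts
behind any particular published operating point are not recoverable, so
only the procedure is reproduced, not a specific sensitivity/specificity
pair.

### Junctions and copy-number segments

Junctions are *removed* when the footprint is under 70 bases, when fewer
than 10 discordant mate pairs support them, when they fall in
under-represented repeats, or when present in the baseline set. The
published filter sentence is directionally ambiguous ("filtered by
footprints smaller than 70 bases"); we read small footprint and weak
mate-pair support as removal criteria, since both are classic artifact
signatures. "Under-represented repeat" membership is taken as an input
flag, not recomputed.

A copy-number segment is high-confidence when it is large enough for
stable lesser-allele-fraction estimation (≥ 10 kb **and** ≥ 10
heterozygous SNPs), or highly altered (copy number 0, or ≥ 5 copies), or
junction-supported. This is a pure boolean rule and is tested against a
direct oracle on 10,000 random segments.

### Coverage-ratio CNV calling

Targeted sequencing yields a per-exon mean depth; dividing by the
sample's mean depth gives ratios where diploid exons sit near 1. Because
amplicon efficiency varies systematically between exons, ratios are
additionally divided by the per-exon cohort median before calling
(`normalize = TRUE`). Calls per sample and gene:

| call | rule | default |
|---|---|---|
| homozygous_deletion | gene-median ratio < `t_hom` | 0.2 |
| intragenic_duplication | ≥ 2 contiguous exons ≥ `t_dup` | 1.5 |
| hemizygous_deletion | ≥ 2 contiguous exons in [`t_hom`, `t_hemi`) | 0.7 |
| normal | otherwise | — |

Precedence is homozygous > duplication > hemizygous. The thresholds are
package defaults chosen to sit centrally between the copy-number states
they separate (0 vs 1 copy, 1 vs 2, 2 vs 3–4, at moderate purity);
published analyses of this design identified outliers visually rather
than numerically.

### Exon expression and loss calling

Exon RPKM is $(r \times 10^9)/(f \times R)$ for $r$ reads on an exon of
$f$ bases in a library of $R$ mapped reads. Values are logged as
$\log_2(\text{RPKM} + 1)$ — the offset handles zero counts; the published
formula states no offset rule, so this choice is recorded here. Each
feature is standardised against the 63-sample normal-tissue panel:
$z = (x - \mu_{\text{panel}})/\sigma_{\text{panel}}$. "Median-normalised
z-score" leaves the spread estimator open; we use the panel SD, and since
a z-score is invariant to the per-feature median shift, the median
normalisation and the standardisation commute. Zero-SD features are
masked, not divided.

Expression loss flags samples whose gene-median exon z is at or below
$\max(-2, \text{median}_{\text{mutant ref}} + 0.5)$: "loss" means
comparable to known truncating-mutant samples, and the reference can only
relax the −2 default upward, never tighten it. Contiguous exon loss
reports maximal runs of ≥ 2 consecutive exons at z ≤ −2; a run covering
the whole gene is reported as a whole-gene event, and an isolated single
low exon is reported distinctly as focal single-exon loss.

### Allele-specific expression

RNA VAF is $\text{alt}/(\text{ref}+\text{alt})$; reads supporting a third
allele are excluded from the denominator (a convention of this package —
the field has no fixed rule). The qualitative labels "exclusive" and
"preferential" mutant expression are given numeric boundaries 0.95 and
0.60, with 0.40 separating balanced from reference-skewed; the four
classes partition $[0,1]$ exactly. These boundaries are package choices:
0.95 leaves room for stray wild-type reads in a pure sample, and 0.60 is
safely above the binomial noise of a balanced site at typical RNA depth.

### Fusion frame and subtype

On a single designated transcript per gene, exon start phases obey
$\text{phase}_{i+1} = (\text{phase}_i + \text{cds}_i) \bmod 3$. A fusion
joining the donor after exon $e_5$ to the acceptor at exon $e_3$ is in
frame iff the donor's cumulative coding length through $e_5$, mod 3,
equals the acceptor exon's start phase; junctions without coding sequence
on either side are non-coding. Frame is conserved under splitting an exon
at constant total coding length, which the tests assert. Subtype labels
(type I, type II, …) are naming conventions, not biology, so they live in
an editable lookup table keyed by `(gene5, exon5, gene3, exon3)`;
unmatched TET×ETS junctions fall back to "other variant", all other
unmatched pairs to "non-TET-ETS" — the trigger for fusion-negative
handling downstream.

### Cohort integration and enrichment

The alteration matrix is a long evidence table, one row per (sample,
gene, evidence class). Samples lacking a TET-ETS fusion are kept in the
matrix but excluded from every frequency denominator, since they are
molecularly distinct from fusion-positive EFT. Per-gene denominators
honour the assay coverage recorded in the sample sheet (a sample tested
only for STAG2 counts in STAG2's denominator only). Percentages are
rounded to one decimal, half away from zero, as printed tables are.

Fisher enrichment reports the plain cross-product odds ratio
$(ad)/(bc)$ — Haldane's +0.5 is applied only when a zero cell occurs,
because the uncorrected cross-product is what published 2×2 odds ratios
print when all cells are positive. The two-tailed p-value uses the method
of small p-values: the sum of hypergeometric probabilities, over all
tables with the observed margins, no larger than the observed table's.
The tests check it against full enumeration and against an independent
reference implementation for tables up to N = 200.

```{r fisher}
# 4 K3326X carriers among 55 patients vs 12 among 1094 controls
fisher_enrichment(4, 51, 12, 1082)
```

### Clustering

`cluster_samples()` is `stats::hclust(method = "ward.D2")` on Euclidean
distances over median-normalised log2 expression — Ward's minimum-variance
criterion applied to Euclidean distances. Input order (and hence the
deterministic lowest-index tie-break) follows first appearance in the
data, i.e. sample-sheet order; relabelling samples permutes but does not
change the dendrogram topology.

## The synthetic cohort generator

`cohort_config()` + `simulate_cohort()` produce every input stream of the
cascade with known truth labels. The defaults are the study conditions
the package targets:

* **Burden**: total coding mutations per sample ~ Poisson(6) over a
  4×10⁷ bp coding target (0.15/Mb); planted drivers draw from this
  budget, passengers land in background genes across the target space.
* **Scores**: true calls ~ N(8, 3²), platform artifacts ~ N(−2, 3²) —
  overlapping enough that cutoff calibration is informative. Artifacts
  recur at a shared pool of 40 sites that doubles as the panel of
  normals.
* **STAG2**: truncating mutation (30 % of samples), intragenic
  duplication (5 %), multi-exon deletion with contiguous expression loss
  (5 %), and whole-gene expression loss without an identifiable mutation
  (7 %). Truncating transcripts retain `nmd_factor` = 0.25 of their
  expression (nonsense-mediated decay); the same retention is applied to
  truncating TP53 transcripts. X-linkage is modelled only as "one
  expressed allele": the RNA VAF of a STAG2 mutant is 1 − contamination,
  so cell lines (pure) show exclusive and tumours (contamination 0.20,
  within the > 70 % tumor-content criterion) preferential mutant
  expression with a median VAF near 0.8.
* **CDKN2A**: homozygous deletion in 25 % of samples with near-zero
  (5 %) residual coverage and near-zero expression.
* **TP53**: mutation in 28 % (half missense, half truncating).
* **Fusions**: cell lines are always fusion-positive; tumours are
  fusion-negative with probability 0.10. Positive samples draw
  EWSR1-FLI1 type I/type II/variant/ERG/FEV junctions at the published
  census proportions; negatives draw FUS-NFATc2, CIC-FOXO4, ETV6-NTRK3
  or no fusion. All shipped transcript models make the canonical
  junctions frame-compatible.
* **Expression structure**: a 24-gene fusion-signature block is
  up-regulated by 3 log2 units in fusion-positive samples. The block is
  deliberately wide: the fusion-driven profile spans a large gene set in
  real cohorts, and it must dominate the expression variance for a k = 2
  Ward cut to isolate a handful of fusion-negative samples rather than
  split the fusion-positive majority along the secondary
  STAG2 → TP53/CDKN1A axis (which the generator also plants: TP53 +1.8
  log2 and CDKN1A −2.2 in STAG2-deficient samples, mirroring p53-pathway
  dysregulation).
* **Conservation**: exon counts per sample are a single multinomial draw
  of exactly `library_size` (2×10⁷) reads, so library sizes are conserved
  to the read; a background bucket absorbs the off-panel transcriptome.
* **Reference panel**: 63 normal-tissue samples for both exon counts and
  gene-level log2 FPKM.

Everything is a deterministic function of `seed`: two runs with the same
configuration are byte-identical on disk (`write_cohort()` emits VCFs
without date lines for exactly this reason).

```{r cohort, eval = FALSE}
cohort <- simulate_cohort(cohort_config(n_tumors = 40, n_cell_lines = 10,
                                        seed = 1))
analysis <- analyze_cohort(cohort)
summarize_frequencies(analysis$matrix, "CDKN2A")
```

### What the generator does *not* emulate

Passing the recovery tests shows the cascade is correct against the
generator's statistical structure, not that it is calibrated for real
data. Known simplifications: no read-level simulation (no mapping or
duplication artifacts, no GC bias); stromal DNA admixture is not modelled
in the coverage channel (deleted exons are near-zero regardless of
purity, per the structure the caller assumes), while RNA allele fractions
*are* contamination-diluted; X-inactivation is reduced to "one expressed
allele"; germline variation is absent except the single BRCA2 K3326X
polymorphism; per-gene expression noise is homoscedastic log-normal; and
the toy gene panel carries invented coordinates and exon structures
(33 coding exons for STAG2, 11 for TP53, 4 for CDKN2A, 12 for BRCA2).

## Numerical choices and degenerate inputs

* Variant keys trim shared flanking bases (suffix first, then prefix,
  advancing the position) before panel-of-normals comparison; alleles are
  assumed left-aligned, since trimming alone cannot left-align without
  the reference.
* `exon_rpkm()` computes in double precision (`f × R` overflows 32-bit
  integers for real libraries) and matches independent evaluation to
  1e-9 relative error on 1,000 random triples.
* Calibration with single-class labels, empty contingency tables,
  groups of fewer than two observations, unordered CNV thresholds, and
  features missing from the reference panel are all rejected with errors
  naming the offender; two equal constant groups compare with p = 1 by
  convention.
* Zero-SD panel features are masked (z = NA) and reported via the
  `masked_features` attribute rather than producing infinities.

## Problem sizes

The test suite runs the full cascade on a seed-fixed cohort of 50 samples
(40 tumours, 10 cell lines) plus the 63-sample normal panel, property
checks on 10,000 random junction/segment records, Fisher enumeration on
random tables up to N = 200, and 1,000-triple RPKM oracles; the whole
suite completes in well under a minute. These sizes give every planted
alteration class at least a handful of events while keeping binomial
noise on recovery rates small.

## Reproducing the cohort-level numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes, from a fresh
run of the package, the K3326X enrichment odds ratio and exact p, the
per-gene mutational frequencies and three-gene union coverage on the
shipped synthetic findings sheet, and the end-to-end synthetic-cohort
diagnostics (mutation rate, planted-event recovery, allele-specific
expression, fusion census, clustering separation), writing them as JSON.
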