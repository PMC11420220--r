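---
title: "Methods: inferring chromosomal mosaicism from single-cell data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring chromosomal mosaicism from single-cell data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicscan)
library(dplyr)
```

mosaicscan infers chromosomal mosaicism — the coexistence of cells with
different karyotypes in one embryo or tissue — from three kinds of
single-cell evidence: low-pass single-cell whole-genome sequencing (scWGS)
binned read counts, single-cell RNA-seq expression plus allelic counts, and
pooled multicell biopsy copy-ratio profiles. This vignette explains each
model, its tunable parameters, and the design choices made where the
methodology was genuinely open.

## The scWGS copy-number model

A cell is represented by read counts in fixed genomic bins (1 Mb by
default) over 23 scorable chromosomes (chr1–22 + X; chrY is never scored
because female embryos lack it and the quality statistic is defined over 23
chromosomes). Low-pass amplified single-cell libraries carry two dominant
systematic artifacts:

* a smooth, unimodal multiplicative GC bias, and
* unreliable counts in low-mappability regions.

`correct_profile()` masks bins below a mappability floor (default 0.8),
divides counts by mappability, median-normalises, fits a robust loess trend
of normalised count against GC on the usable bins, divides the trend out,
and rescales so the median usable bin is exactly 1. The log2 copy ratio of
a bin is then `log2(corrected count)`: 0 for disomy, about +0.585
(`log2(3/2)`) for a trisomic bin, −1 for a monosomic bin.

### Quality control: the variability score

Chaotically amplified cells show inflated variance on *every* chromosome,
while a genuine aneuploidy shifts the level of only the affected
chromosomes. The variability score (VS) exploits this: it is the median,
across chromosomes, of the within-chromosome standard deviation of
corrected counts (`compute_vs()`). A genuine trisomy moves one of 23
SDs — the median barely moves; amplification chaos moves all of them.

`qc_filter()` offers two exclusion policies. The batch-adaptive default
excludes cells with VS above `mean(vs) + 3·sd(vs)` of the batch; a fixed
absolute cutoff (0.34 is a published operating point for this statistic at
~0.3× coverage and 1 Mb bins) is available when a batch is too small or a
fixed operating point is preferred. Both interpretations of a "3 SD" rule
are provided because the reference formulation is ambiguous; the
batch-adaptive reading is the default since it transfers across depths. A
minimum-total-count floor mirrors the practice of discarding cells below
~0.1× effective depth.

### Cutoff calibration

Pooled per-(cell, chromosome) mean log2 ratios of a batch typically show
three peaks: monosomy, disomy, trisomy. `calibrate_cutoffs()` first checks,
by kernel density, that modes exist near −1, 0 and +0.585 (each within
0.25). If so, it fits a three-component Gaussian mixture and places the
loss/gain cutoffs at the fine-grid minima of the *fitted* mixture between
adjacent components. The fitted mixture is used rather than the raw kernel
density because with well-separated peaks the empirical density underflows
to ~0 over a wide valley and its argmin is numerically meaningless; the
mixture's analytic valley is the statistically defined best partition. If
the three modes are not found, calibration falls back to the fixed
defaults (−0.45, +0.35), which are also the package-wide defaults when no
calibration is requested.

### Segmentation and calling

`call_cnvs()` decodes each chromosome's usable-bin log2 ratios with a
three-state (loss / neutral / gain) Gaussian hidden Markov model:
emission means `(loss_cutoff − 0.2, 0, gain_cutoff + 0.2)`, a shared
emission SD estimated from the cell's neutral bins (floored at 0.05 so
noise-free profiles cannot degenerate), self-transition probability
1 − 10⁻⁵, Viterbi decoding, and merging of same-state segments separated
by at most 2 neutral bins. A segment becomes a call only if its mean log2
ratio lies beyond the matching cutoff *and* its genomic span strictly
exceeds 10 Mb — at 1 Mb bins, sub-10 Mb events are dominated by noise, and
"larger than 10 Mb" is read strictly (a 10.0 Mb run is rejected). A call
covering at least 80% of its chromosome is `whole`, else `segmental`; the
80% fraction is a configurable convention, since no standard boundary
exists.

On noise-free profiles this caller provably reduces to exact
thresholded-run analysis, which the test suite verifies against an
independent brute-force oracle over hundreds of random planted
configurations.

## Embryo-level aggregation

**Meiotic vs mitotic.** A (chromosome, direction) is scored meiotic when at
least 95% of the embryo's QC-passed cells carry a whole-chromosome call of
that direction — a gamete-origin error is expected in essentially all
cells; the 5% complement absorbs caller noise. The comparison is exact on
fractions (19/20 qualifies, 18/20 does not). Meiotic chromosomes are
removed wholesale from every mitotic statistic, mirroring how a uniform
trisomy would otherwise masquerade as maximal mosaicism.

**Rates and categories.** The mitotic aneuploidy rate is the fraction of
QC-passed cells with at least one mitotic call. Aneuploid cells are
partitioned by direction (gain-only / loss-only / both) and scope
(whole-only / segmental-only / both).

**Complementary cells.** Reciprocal gain and loss of the same region in
two cells of one embryo is the signature of mitotic nondisjunction — and
cancels out in pooled biopsies. Whole-chromosome pairs need only the same
chromosome and opposite directions; segmental pairs additionally require
reciprocal overlap ≥ 0.5 (configurable; only whole-chromosome cases are
illustrated in the literature the default mirrors).

**The permutation null.** How surprising is it that k of n embryos harbour
complementary cells? No published construction exists for this null, so the
package documents its own: calls are first clustered into aberration
*events* (a clone's shared whole-chromosome loss is one event — one mitotic
error produced all of its calls, so the event is the exchangeable unit;
shuffling per-cell calls instead would let a clone's identical calls split
into artificial gain/loss pairs and destroy the null's meaning). Direction
labels are then shuffled among events on the same chromosome across
embryos, preserving each embryo's event count and each chromosome's
genome-wide gain/loss totals, and the number of embryos with at least one
complementary pair is recomputed. The p-value uses the add-one estimator.
On micro-instances the permutation distribution matches exhaustive
enumeration (tested).

**Lineage reconstruction.** Cells sharing identical aberration-event sets
form clades; clades nest by the subset relation (a daughter lineage
inherits its ancestor's aberrations), the euploid zygote is the root,
non-nested overlapping sets are left as flagged ambiguous siblings, and
complementary daughter clades are joined under a virtual nondisjunction
node. The division stage of an event is estimated from clade sizes as
`2^round(log2(n_total / n_carrying))`: with 33 cells of which 5 carry a
chr14 event, `2^round(log2(6.6)) = 8`, i.e. an ~8-cell-stage error. The
total QC-passed cell count proxies the embryo's cell number at sampling.

## Pooled biopsies and mosaic fraction

Pooling m cells averages copy number, so a trisomic fraction f yields
`r = log2((2 + f)/2)` on the affected region. `assess_biopsy()` inverts
this: `f = 2(2^r − 1)` for gains and `f = 2(1 − 2^r)` for losses, clipped
to [0, 1]. Aberrant regions are found by thresholded runs (after a
5-bin running median to bridge isolated noisy bins) at the log2 level
implied by the lower mosaic band, with the same strict 10 Mb floor.
Classification follows the intermediate-copy-number convention used in
clinical PGT-A reporting: euploid below 20%, mosaic 20–80%, aneuploid
above 80% (band edges configurable).

## RNA-based aneuploidy calling

Expression matrices are filtered cell-first (cells with strictly more than
2,000 expressed genes), then gene-wise on the retained cells (expressed in
≥ 3 cells and median expression strictly above 50 counts) — the cell-first
order matters because "expressed in ≥ 3 cells" is evaluated on retained
cells, and it is logged. Normalisation uses a fixed per-cell scale factor
of 100,000 counts before `log1p`.

Two per-(cell, chromosome) features drive the caller:

* `z_expr`: the cell's mean normalised expression of the chromosome's
  genes divided by the across-cell mean of that quantity, z-scored across
  cells per chromosome;
* `z_ai`: the deviation of the chromosome's aggregate oriented-allele
  fraction from its across-cell median, z-scored likewise.

Both are invariant to per-cell library scaling by construction. Z-scores
are robust (median centre, MAD scale) by default: the reference
distribution should be the euploid majority, and with plain moments a few
aberrant cells on one chromosome inflate the scale enough to mask each
other (`robust = FALSE` restores plain z-scores).

Calls use fixed dual-evidence thresholds: gain requires `z_expr > 5.6` and
`z_ai > 0.05`; loss requires `z_expr < −3.65` and `z_ai < −1.6`; a
chromosome must have more than 100 SNP split reads (allele-informative
reads) to be evaluable at all, and only whole-chromosome calls are made.
The thresholds are adopted verbatim from the published operating point
they instantiate. Their sign asymmetry is meaningful under the package's
orientation convention: the `a` allele column counts reads from the
haplotype whose dosage rises under a gain, so a trisomy shifts the
fraction mildly upward (1/2 → 2/3) while a monosomy of that haplotype
collapses it (1/2 → 0) — hence a permissive positive gate for gains and a
stringent negative gate for losses. What "SNP split reads" denotes is not
defined in the source literature; this package implements it as the total
allele-informative read count per chromosome.

`validate_against_dna()` treats matched DNA calls as the gold standard:
the false-positive rate is the fraction of RNA-called aberrations not
confirmed in DNA, the false-negative rate the fraction of RNA-negative
chromosomes not confirmed euploid. With 27 called / 25 confirmed and 361
negative / 353 confirmed these are 2/27 ≈ 7.41% and 8/361 ≈ 2.22%.

## The synthetic-data generator

Every stage is exercised on synthetic data with coupled ground truth, so
the pipeline is testable without restricted raw data.

* **scWGS counts** (`simulate_embryo()`): expected count in bin b of cell
  i is proportional to `cn(i,b)/2 × gc_curve(gc_b) × mappability_b`, with
  negative-binomial overdispersion. The NB count model reflects the heavy
  amplification overdispersion of MALBAC/MDA-style chemistry — precisely
  what the VS must detect; the true noise spectrum of any given chemistry
  is not characterised, so the dispersion default (0.02, giving VS ≈ 0.12
  at 2,000 reads/bin — comfortably under the 0.34 operating point) was
  chosen once for testability, not fidelity. "Chaotic" QC-test cells
  inflate dispersion (×10) rather than adding CNVs, so QC separation is a
  pure noise-vs-signal test. The GC curve is quadratic in GC on the log
  scale. Clone membership is deterministic (`round(fraction × n)` cells in
  declaration order), which makes planted rates exactly recoverable.
* **Genome model** (`genome_model()`): 23 chromosomes with
  hg38-proportional lengths (~3,030 1 Mb bins at full scale); a `scale`
  argument shrinks it for fast tests (most tests run at scale 0.1,
  ~313 bins; the parameter-recovery check runs at full scale). Its GC and
  mappability tracks are smooth deterministic patterns, not real genome
  tracks.
* **RNA cohorts** (`simulate_rna()`): NB expression with a bimodal gene
  mean distribution (informative high-expression genes pass the median
  filter; a low-expression mass is removed by it), lognormal library
  sizes, gains scaling resident genes ×1.5 and losses ×0.5, allele counts
  binomial around the copy-configuration fraction, and NB SNP depths
  (mean 500) that naturally produce not-evaluable chromosomes below the
  100-read floor.
* **Biopsies** (`simulate_biopsy()`): pooled log2 ratios equal the
  closed-form mixture value plus Gaussian noise shrinking with the number
  of pooled cells; the sampled aberrant fraction is recorded as truth.

What the generator does **not** emulate: real GC/mappability tracks,
replication-timing or strand artifacts, segmental-duplication breakpoint
hotspots, sub-clone phylogenies deeper than one event set per clone,
dosage compensation or imprinting in expression, and phasing errors in
allele counts. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not calling accuracy on any
particular real dataset.

## Numerical choices and degenerate inputs

* log2 ratios floor corrected counts at 2⁻⁸ so empty bins cannot produce
  infinities; the floor is far below the monosomy level.
* The HMM emission SD floor (0.05) keeps noise-free profiles decodable.
* Chromosomes with fewer than 2 usable bins are excluded from the VS
  median with a warning; all-zero cells are flagged unusable, never
  silently dropped; cells failing QC are reported with the threshold used.
* The calibration falls back to fixed cutoffs on any degenerate density.
* Problem sizes in the test suite (genome scale, replicate counts,
  permutation counts) are the package's own choices balancing statistical
  resolution against a fast default test run; each check states its size.

## Known limitations

* The three-state model cannot represent genome-wide haploidy/tetraploidy
  or allele-specific states; copy numbers beyond 1–3 are folded into
  gain/loss.
* The stage estimator assumes near-complete cell recovery; heavy cell loss
  biases `n_total` and hence the inferred division stage.
* The permutation null conditions on the observed event geometry; embryos
  whose pair chromosome carries no other cohort events contribute
  unbreakable pairs and make the test conservative.
* RNA calls are whole-chromosome only, and the allelic-imbalance channel
  requires externally oriented allele counts.
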