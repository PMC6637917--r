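---
title: "Detecting supercoiling-sensitive genes, clusters and promoter architecture"
author: "topoclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting supercoiling-sensitive genes, clusters and promoter architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoclust)
```

## The problem and the model

Bacterial chromosome topology is held in balance by topoisomerase I
(TopA), which relaxes negative supercoils, and gyrase, which introduces
them. Perturbing that balance — acutely with a gyrase inhibitor such as
novobiocin, or chronically by depleting or inducing TopA — changes the
transcription of *supercoiling-sensitive genes* (SSGs). In GC-rich
bacteria with linear chromosomes (Streptomyces being the motivating
system: ~8.7 Mbp, 72% GC, ~7,900 genes partly organized in operons) three
empirical signatures are of interest:

1. genes whose transcript level changes at least 2.83-fold
   (|log2 FC| > 1.5) at p < 0.05 when supercoiling is perturbed;
2. the clustering of those genes along the chromosome into
   supercoiling-sensitive regions, including one maximally dense
   "hypersensitive" region; and
3. elevated AT content just upstream of the start codons of
   relaxation-induced genes, with a GC-rich block roughly 100–200 bp
   further upstream.

This vignette describes the statistical procedures the package implements
for each signature, the synthetic data generator used to exercise them,
and the design choices that were genuinely open.

## Differential expression and SSG classification

**Normalization.** Each sample is scaled by the upper quartile of its
*nonzero* counts. We use a no-interpolation order statistic: the smallest
nonzero count whose empirical CDF strictly exceeds 0.75, i.e.
`sorted[floor(0.75 n) + 1]` capped at the maximum (for counts 10, 20, 30,
40 the upper quartile is 40). Columns are rescaled to the median upper
quartile across samples so values stay count-like; zeros stay zero. The
normalization is invariant to per-sample scale factors (library size) by
construction. Its known limitation: like any global scaling method it
assumes most genes are unchanged — if a large fraction of the
transcriptome moves in one direction, the upper quartile moves with it and
effects are attenuated. The synthetic designs keep planted effects below
~20% of genes for this reason, which matches the study system (at most 7%
of genes affected).

**Fold change.** `log2FC = log2((mean_T + pc) / (mean_C + pc))` with
induction under treatment positive. The pseudocount `pc` is 0 when both
condition means are positive; genes expressed in exactly one condition
fall back to `pc = 1` and are flagged; genes silent in both are reported
missing. This keeps the headline fold changes exact while avoiding
infinite values for on/off genes.

**Significance.** The original analysis relied on an alignment tool's
internal test statistics, which are not part of this package's scope; we
substitute a two-sided Welch t-test on `log2(normalized + 1)` across
biological replicates and say so in the output metadata. It is
replicate-honest, robust to unequal variances, and degenerates sensibly
(both groups constant and equal gives p = 1). Benjamini–Hochberg q-values
are computed and reported, but classification uses the raw p < 0.05, as
the thresholds above were defined on raw p-values; q is available to the
user. Exact reproduction of the study's gene lists is therefore not
claimed — the classification rule, not the test, is the contract.

**Classification.** `up` if log2FC > 1.5 (strictly) and p < 0.05, `down`
symmetrically; genes on the exemption list (nucleoid-associated proteins
and topoisomerases, whose biologically meaningful changes are small) are
classified by p-value alone with direction from the sign of the fold
change.

## Cluster scanning

Affected genes are mapped to transcription-unit (TU) start positions: the
`start` of the first transcribed gene for plus-strand units, the `end`
for minus-strand units; a unit is affected if any member is, and
contributes one deduplicated position. Windows of 250 kbp are slid in
125-kbp steps from position 1, clipped at the chromosome end (the linear
chromosome's arms carry genes too, so the final partial window is kept).
Each window's percentage of affected TUs is computed with the TU count as
denominator; a configuration switch to a per-gene denominator exists
because the phrase "percent of affected genes" is ambiguous between the
two. Windows strictly above 5% qualify; qualifying windows whose spans
overlap or abut merge into one cluster call (half-overlapping steps make
neighbouring windows non-independent, so merging is the only coherent
reading). Up and down directions are scanned separately and independently.

`densest_region()` searches for the fixed-width interval (30 kbp by
default) containing the most affected genes, anchoring candidate
intervals at gene start positions — an exhaustive scan, verified in the
test suite against an independent double-loop enumeration. Ties go to the
larger affected fraction, then to the leftmost interval.

Window anchoring at position 1 is an assumption (the original description
does not state the anchor); since windows overlap two-fold, a different
anchor shifts cluster boundaries by at most half a step.

## Promoter composition

For each gene with sufficient flank, a 960-bp window — 750 bp upstream of
the translation start codon plus 210 bp downstream — is read 5'→3' on the
coding strand, so the start codon always begins at position 751.
AT content is computed in 100-bp windows at 1-bp steps (861 positions) and
plotted against the window's *first* base. `N` bases count as non-AT so
every window keeps an exact denominator of 100. Genes with insufficient
flank are excluded rather than clipped, keeping all windows exactly
960 bp. Two control sets mirror the study: random gene promoters
(uniform, without replacement, among eligible genes) and random genomic
960-bp sequences on either strand.

Positional tests report, per tested window-start position, Shapiro–Wilk
normality p-values for both sets and a two-sample t-test. Welch's t is
the default (the original description says only "t-test"; unequal
variances are the safer assumption) with an `equal_var` switch for the
pooled-variance form. When either set fails normality at 0.05 a
Mann–Whitney p-value is reported alongside, but the t-test is never
silently replaced. The canonical positions 340 and 660 are plain user
parameters: the source material internally contradicts itself about which
one is "the promoter region" and which "the GC-enriched region", so the
package attaches no semantic label to either.

## qPCR quantification

The comparative ΔΔCt method with amplification efficiency fixed at 2:
technical replicates are averaged at the Ct level within a sample, ΔCt is
the condition mean of target minus reference Ct, ΔΔCt subtracts the
calibrator condition, and the relative level is `2^−ΔΔCt` (the calibrator
is exactly 1). Replicate dispersion uses replicate-matched reference Cts
so that per-sample plate offsets cancel; it is reported as a standard
deviation and labelled as such. Efficiency calibration and melt-curve QC
are out of scope.

## The synthetic-data generator

`synthetic_design()` fixes the study conditions the generators emulate:

| parameter | default | meaning |
|---|---|---|
| `genome_length` | 1 Mbp | desk-scale chromosome (full scale 8.7 Mbp is supported but not the default) |
| `gc_fraction` | 0.72 | i.i.d. base composition; realized AT converges to 28% within 0.2 points at 1 Mbp |
| `n_genes` | 900 | keeps the study's ~0.9 genes/kbp density at desk scale |
| `operon_fraction`, `operon_size` | 0.4, 3 | runs of adjacent same-strand genes grouped into fixed-size operons |
| `conditions` | control ×4, novobiocin ×3, topA_down ×4, topA_up ×3 | 2–4 biological replicates per condition, four for the control and depletion arms |
| `baseline_mean`, `nb_dispersion` | 200, 0.05 | negative-binomial counts with gene-shared dispersion; 0 degenerates to Poisson |
| `planted_clusters` | 6 up + 2 down, 40 kbp, effect log2 = 3, fraction 0.5 | spatial effects for the long-term contrast; only half the member genes are affected, as real clusters contain unaffected genes |
| `n_induced_promoters` | 66 | induced TUs for the rapid-relaxation contrast, matching the study's 66 analyzed transcription units |
| `promoter_at_boost` | +3 points over window positions 600–760 | the observed 2–3-point AT elevation near the start codon |
| `promoter_gc_boost` | +3 points GC over positions 340–460 | the GC-rich block 100–200 bp upstream of it |

The replicate-level dispersion of the study's counts is not published;
0.05 is a typical bulk RNA-Seq value and a free parameter of the
emulation, not an estimate of the study data. Promoter boosts are planted
by resampling the interval's bases with the background AT probability
shifted by the boost, so the realized difference fluctuates around the
nominal value exactly as a composition signal would; a boost of zero
leaves the genome untouched. Every generator draws from a substream
derived from the global seed, so each stage is individually reproducible
and the whole demo is byte-identical across runs.

`make_demo()` writes the complete input bundle plus truth tables. Its
configuration scales the scan window to 50 kbp / 25 kbp: the full-scale
250-kbp window is a quarter of the demo chromosome and would merge all
planted clusters into one call; 50 kbp (5% of the chromosome, versus 2.9%
in the study system) keeps the planted clusters separable while exercising
the identical code path. Function defaults remain the full-scale values.

**What the simulation does not emulate:** sequence-dependent expression,
GC-skew and strand asymmetries, operon-level count correlation, overdispersion
heterogeneity across genes, partial topological domain boundaries, and the
alignment/counting process itself. Passing recovery tests on this
generator therefore demonstrates that the statistics behave as specified
under their own assumptions — not that real libraries satisfy those
assumptions.

## Numerical choices and degenerate inputs

- Quantile definition: the no-interpolation order statistic above;
  deterministic, library-independent, and matched by an enumeration
  oracle in the tests.
- Welch test with both groups constant: p = 1 if the means agree, else 0.
- Windows with no TUs have undefined (NA) percentage and never qualify.
- Threshold comparisons are strict (`> 1.5`, `> 5%`), so boundary values
  do not pass.
- Densest-region ties: larger affected fraction, then leftmost start.
- All coordinates are 1-based inclusive throughout (the GFF3 convention);
  conversion happens nowhere internally.

## Problem sizes

The test suite and the acceptance script run the desk-scale design
(1 Mbp, 900 genes, 14 samples); oracle-equivalence suites use instances
of up to 200 genes with brute-force recomputation; power and calibration
of the positional t-test use 500 simulations at n = 66 sequences per set.
These sizes were chosen to characterize the estimators' behaviour
(sensitivity, false-positive rate, test size and power) with tight Monte
Carlo error while remaining convenient to re-run.
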