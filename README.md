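# topoclust

Downstream analysis of bacterial transcriptional responses to chromosome
supercoiling imbalance, written for GC-rich linear chromosomes such as the
~8.7-Mb *Streptomyces coelicolor* chromosome. When the balance between
topoisomerase I (which relaxes DNA) and gyrase (which introduces negative
supercoils) is perturbed — acutely with the gyrase inhibitor novobiocin, or
chronically by tuning *topA* expression — the transcript levels of
*supercoiling-sensitive genes* (SSGs) shift, and those genes are not spread
evenly along the chromosome: they group into supercoiling-sensitive
clusters. This package implements the downstream statistics of that
analysis for anyone with a genome, an annotation and a replicate count
matrix; no read alignment is performed.

## What it computes

- **SSG classification** (`run_diffexpr()`). Counts are normalized by the
  upper quartile of each sample's nonzero counts (`UQ_s`, rescaled to a
  common reference), per-gene fold changes are computed as
  `log2FC = log2(mean_treatment / mean_control)`, and significance by a
  two-sided Welch t-test on `log2(x + 1)` across replicates with
  Benjamini–Hochberg q-values reported alongside. A gene is an SSG when
  `|log2FC| > 1.5` (i.e. at least a 2.83-fold change) and `p < 0.05`;
  genes on an exemption list (nucleoid-associated proteins and
  topoisomerases) are classified on the p-value alone.
- **Cluster calling** (`map_tss()`, `window_scan()`, `call_clusters()`).
  Each affected transcription unit is mapped to the start position of its
  first transcribed gene; the percentage of affected units is computed in
  a 250-kbp window slid in 125-kbp steps, and regions where it strictly
  exceeds 5% are merged into cluster calls, separately for up- and
  down-regulated genes. `densest_region()` finds the fixed-width (30 kbp)
  interval containing the most affected genes — the hypersensitive-cluster
  search.
- **Promoter composition** (`promoter_windows()`, `at_profile()`,
  `compare_positions()`). 960-bp windows (750 bp upstream of the start
  codon + 210 bp downstream) are profiled for AT content in 100-bp windows
  at 1-bp steps and compared with random-promoter and random-genomic
  controls; per-position differences are tested with Shapiro–Wilk and a
  two-sample t-test.
- **qPCR quantification** (`ddct()`). Comparative ΔΔCt with an endogenous
  control gene: `ΔCt = Ct_target − Ct_ref` per condition,
  `ΔΔCt = ΔCt − ΔCt_calibrator`, relative level `2^−ΔΔCt`.
- **Synthetic data** (`synthetic_design()`, `make_demo()`). A simulator
  for linear GC-rich genomes, operon-structured annotations,
  negative-binomial replicate counts with spatially planted log2 effects,
  promoter AT/GC architecture, and Ct tables — with truth tables, so every
  stage of the pipeline can be exercised and scored offline.
- **Orchestration** (`run_all()`). One YAML configuration runs all stages
  in order and writes TSV outputs with reproducible metadata headers;
  identical configurations give byte-identical outputs. A thin CLI wrapper
  is installed under `inst/scripts/topoclust`.

## Worked example

```r
library(topoclust)

demo <- make_demo(seed = 1, outdir = file.path(tempdir(), "demo"))
cm <- read_counts(demo$paths$counts, demo$paths$samples)
cm
#> <count_matrix> 900 genes x 14 samples (control, novobiocin, topA_down, topA_up)

d <- run_diffexpr(cm, "topA_down", "control",
                  exemption_list = readLines(demo$paths$exempt))
d
#> <diff_result> topA_down vs control: 900 genes (111 up, 36 down)
```

147 of 900 genes pass the SSG thresholds under the simulated long-term
topoisomerase-depletion contrast (the design plants six up- and two
down-regulated 40-kbp clusters affecting about half the genes they cover).
Mapping them to transcription-unit starts and scanning the chromosome:

```r
genes <- read_gff3(demo$paths$gff)
operons <- read_operons(demo$paths$operons)
mt <- map_tss(d, genes, operons)
up <- mt$affected[mt$affected$direction %in% c("up", "both"), ]
sc <- window_scan(up$tss_position, mt$tu$tss_position, 1e6,
                  window_size = 50000, step = 25000)
call_clusters(sc, up$tss_position, mt$tu$tss_position, 5, "up", "chr")[, 1:7]
#>  chrom_id  start    end direction peak_window_percent n_affected n_total
#>       chr  25001 125000        up            43.47826         11      49
#>       chr 175001 275000        up            50.00000         12      50
#>       chr 325001 425000        up            50.00000         15      52
#>       chr 475001 575000        up            52.17391         12      47
#>       chr 625001 725000        up            48.27586         14      56
#>       chr 775001 875000        up            56.52174         13      46
```

All six planted up-regulated clusters are called, each covering its planted
40-kbp interval, with peak window densities of 43–57% affected
transcription units (the demo scales the window to 50 kbp / 25 kbp for its
1-Mbp chromosome; the defaults are the full-scale 250 kbp / 125 kbp). The
qPCR arm recovers the planted relative transcript levels:

```r
ddct(read_ct_table(demo$paths$ct), "tgtA", "hrdB",
     calibrator_condition = "control")
#> <relative_levels> tgtA vs control (reference-normalized)
#>   condition delta_delta_ct relative_level   level_sd
#>     control      0.0000000       1.000000 0.03594097
#>  novobiocin     -1.0891337       2.127463 0.09084862
#>   topA_down     -2.0664086       4.188427 0.33806099
#>     topA_up     -0.5384225       1.452384 0.06069600
```

The planted truth was 1 / 2 / 4 / 1.5 with 0.1 cycles of Ct noise.
`run_all(demo$paths$config, outdir)` runs every stage — including the
promoter AT profiles with their positional tests — from the written
configuration file.

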