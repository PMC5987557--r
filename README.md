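# twindmr

Sliding-window differential DNA-methylation analysis for a
disease-discordant monozygotic twin pair, with genomic annotation of the
resulting regions and the statistics of a clinical validation cohort.

Monozygotic twins discordant for a congenital disease are a natural
experiment that separates epigenetic from genetic variation: the genomes are
(near-)identical, so methylation differences between the co-twins become the
candidate disease mechanism. `twindmr` implements the complete comparison
for per-cytosine bisulfite data (RRBS/WGBS), aimed at epigenomics analysts
who have bismark-style cytosine reports for two samples and want
differentially methylated regions (DMRs), their promoter/TFBS context, and a
cohort-level follow-up — plus a fully seeded synthetic-data generator for
benchmarking every step.

## The method

**DMR calling.** A window of width *w* = 100 bp slides along each
chromosome in steps of *s* = 50 bp. Within a window, the CpG sites covered
by at least 10 reads in *both* samples contribute paired methylation levels
`m_i = meth_i / (meth_i + unmeth_i)`. The two level vectors are compared
with a two-sided Wilcoxon rank-sum test — exact (full enumeration of group
assignments over mid-ranks) when `n1 + n2 <= 12`, tie-corrected normal
approximation otherwise. A window is a differentially methylated window
(DMW) when

* `p < 0.01`,
* it holds `>= 5` usable CpG sites, and
* the absolute difference of window means is `>= 0.10`.

Overlapping or abutting DMWs of the same sign are unioned into DMRs
(direction `hyper`/`hypo` = sample 1 higher/lower; region p-value = minimum
constituent p). With 5 sites per group the exact rank-sum can reach
`p = 2/252 ≈ 0.0079 < 0.01`, so the 5-CpG minimum and the 0.01 threshold
are mutually consistent.

**Annotation.** Each DMR receives exactly one of seven genomic categories —
`upstream` (within 2 kb 5' of a TSS, the promoter proxy), `UTR5`, `exonic`,
`intronic`, `UTR3`, `downstream`, `intergenic` — by a promoter-first
priority over all gene-model features it overlaps by >= 1 bp, plus the full
many-to-many gene/TSS links and overlaps with a TF-binding-site track.

**Validation statistics.** For a case/control cohort assayed by clone
bisulfite sequencing (>= 20 clones per sample), the package summarises each
clones-by-CpG binary matrix, calls per-sample promoter hypermethylation,
tests the association of calls with disease status by a two-sided Fisher's
exact test (probability-mass definition, exact hypergeometric enumeration),
and correlates promoter methylation with relative expression (Pearson, t
test on n − 2 df).

## Worked example

```r
library(twindmr)

cfg  <- simulation_config(seed = 7, n_chroms = 2, chrom_length = 150000,
                          n_dmrs = 10)
sim  <- simulate_methylome_pair(cfg)          # two methylomes + ground truth
scan <- call_dmrs(sim$sample1, sim$sample2, dmr_params(), sim$chrom_sizes)
scan
#> DMR scan of sample1 vs sample2
#>   windows tested:      3671
#>   significant windows: 18
#>   DMRs:                10 (4 hyper, 6 hypo)

tidy(scan)
#> # A tibble: 10 × 10
#>   chrom  start    end direction n_windows n_cpgs  p_value mean_s1 mean_s2  delta
#> 1 chr1   30000  30150 hypo              2     10 0.000349   0.217   0.649 -0.432
#> 2 chr1   58000  58100 hyper             1      7 0.00175    0.866   0.487  0.379
#> ...
```

All 10 planted regions are recovered with the right direction. The tested
windows sit on the fixed 50 bp grid; each region's p-value is the minimum
over its constituent windows. Annotation and the cohort arm continue in the
same style:

```r
genes <- simulate_gene_models(cfg, n_genes = 15,
                              truth_regions = sim$truth$regions,
                              n_promoter_coupled = 3)
summarize_categories(classify_dmrs(scan$dmrs, genes,
                                   chrom_sizes = sim$chrom_sizes))
#> promoter DMRs: 3 (3 TSSs, 3 genes)

coh <- simulate_cohort(cfg)                   # 15 cases / 5 controls, 20 clones
validate_cohort(coh$clones, coh$cohort)
#> Cohort validation
#>         hyper not_hyper
#> case        9         6
#> control     0         5
#> Fisher exact p = 0.03793
#> methylation-expression r = -0.919 (p = 1.08e-08, n = 20)
```

The per-sample means come from each clone matrix; the 2×2 table crosses
disease status with the hypermethylation call; expression decreases with
promoter methylation, hence the strongly negative r. QC helpers
(`sample_correlation()`, `methylation_distribution()`,
`plot_methylation_distribution()`, `autoplot()` methods) show the bimodal
level histogram and the high inter-sample concordance expected of replicate
methylomes (here r = 0.972 at >= 10× sites).

`run_pipeline("run.yaml")` chains simulate → call-dmrs → annotate →
validate, writes every intermediate file and a JSON run report, and is a
pure function of (config, seed). A shell wrapper with the same subcommands
lives at `inst/scripts/twindmr.R`.

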