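---
title: "Methods: sliding-window DMR calling and cohort validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sliding-window DMR calling and cohort validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twindmr)
```

`twindmr` compares the CpG methylomes of two individuals — designed around
the disease-discordant monozygotic twin setting, where the genomes are
essentially shared and methylation differences are the signal of interest —
and carries the resulting regions through genomic annotation and a
clinical-cohort validation. This vignette documents the statistical model,
every tunable that matters, the numerical conventions, and what the
synthetic-data generator does and does not emulate.

## The window test

The unit of testing is a fixed 100 bp window advanced in 50 bp steps from
coordinate 0 of each chromosome (trailing windows that would cross the
chromosome end are not emitted, and with step = window/2 every CpG is seen
by exactly two windows). Within a window, only CpG sites covered by at
least `min_depth` reads in *both* samples contribute; each contributes its
methylation level `meth / (meth + unmeth)`.

The two per-site level vectors are compared with a two-sided Wilcoxon test.
The default is the **two-group rank-sum (Mann–Whitney) form**, treating the
two vectors as independent groups. The alternative — pairing levels by site
and using the signed-rank statistic — is available via
`dmr_params(test = "signed_rank")`, but is not the default for an
attainability reason: the exact two-sided signed-rank test cannot fall
below `2/2^n`, so with the 5-CpG window minimum (n = 5, minimum p = 1/16)
no 5-site window could ever reach the 0.01 threshold, which would make the
declared site minimum and the significance threshold mutually
contradictory. The rank-sum form at 5 vs 5 attains `2/252 ≈ 0.0079 < 0.01`,
so the two defaults are consistent with each other.

Numerically:

* for `n1 + n2 <= 12` the null is enumerated exactly over all
  `choose(n1 + n2, n1)` group assignments of the mid-ranks; the two-sided
  p-value is the probability of a rank-sum at least as far from its null
  mean as observed (equivalently the doubled tail — the permutation
  distribution over mid-ranks is symmetric). A tolerance of `1e-9` on the
  rank-sum scale guards against floating-point ties.
* above that size, the tie-corrected normal approximation is used without
  a continuity correction (methylation levels at equal depth tie
  constantly, and the tie correction dominates the half-unit continuity
  term at these window sizes);
* identical (all-tied) inputs are defined as `p = 1`; a window is tested
  whenever it holds at least one shared deep site.

## Window retention and merging

A tested window is retained when all three gates pass: `p < alpha`
(default 0.01, strict), `n_cpgs >= min_cpgs` (default 5), and
`|mean_1 - mean_2| >= min_delta` (default 0.10). The retention rule is the
conjunction — a window must clear the site minimum *and* the effect-size
minimum — because the alternative reading (discard only when both fail)
would keep single-CpG windows with large differences, defeating the purpose
of a region-level test. Both thresholds are independently configurable, and
an optional Benjamini–Hochberg mode (`adjust = "BH"`) thresholds adjusted
p-values instead of raw ones.

Retained windows are merged into DMRs per chromosome and per direction
(sign of the mean difference, `hyper` meaning sample 1 higher): maximal
runs of windows that overlap *or abut* (zero gap) are unioned. Opposite
directions never merge even when they overlap. A merged region reports the
minimum constituent p-value, the number of constituent windows, and means
over the *distinct* CpG sites it covers (sites shared by overlapping
windows count once). Windows with a mean difference of exactly zero cannot
pass `min_delta > 0`, so their direction label never matters in practice;
they are grouped with `hyper` for determinism.

## Annotation conventions

All coordinates are 0-based half-open internally; the 1-based positions of
cytosine reports are converted on read and back on write. Overlap always
means at least one shared base pair, so bookended intervals do not overlap
— the behaviour of the standard interval-intersection tools this mirrors.

Each transcript contributes: a strand-aware upstream flank
`[TSS - 2000, TSS)` on `+` / `[TSS, TSS + 2000)` on `-` (the promoter
proxy; width configurable, clipped at chromosome bounds), a downstream
flank at the other end, coding-exon portions (whole exons for non-coding
transcripts), 5'/3' UTRs derived from the coding span, and introns. A DMR
collects every feature it overlaps and is assigned the single
highest-priority category present, with the priority
`upstream > UTR5 > exonic > intronic > UTR3 > downstream > intergenic`.
One category per region keeps the proportions interpretable; promoter-first
reflects the analytical emphasis on promoter methylation. The full
many-to-many gene/TSS links are kept alongside, so nothing is lost by the
single label. Promoter summaries deduplicate: distinct upstream DMRs,
distinct linked TSSs, distinct gene symbols.

## Validation statistics

Clone bisulfite sequencing gives a clones × CpG binary matrix per sample.
The per-sample mean averages over all non-missing entries; per-CpG means
use per-column denominators (a fully missing column reports an absent
mean). A sample is called hypermethylated when its mean *strictly* exceeds
a threshold. The threshold itself is not something the underlying assay
defines, so it is an explicit parameter: the default is the midpoint 0.5,
and `rule = "max_control"` instead calls samples exceeding the largest
control mean — useful when controls are not near zero.

The association between disease status and the call is tested with a
two-sided Fisher's exact test in the **probability-mass (minimum
likelihood) definition**: conditioning on the margins, sum the
hypergeometric probabilities of all tables no more probable than the
observed one, with a relative tolerance of `1e-7` for probability ties.
For the archetypal validation table — 15 cases of which 12 called, 5
controls of which 0 — this gives 0.0036 (to four decimals), and the
definition coincides with the one-sided tail there because no
opposite-tail table is as improbable. Methylation–expression association
is the Pearson correlation with the usual two-sided t test on n − 2
degrees of freedom.

## What the generator emulates

`simulate_methylome_pair()` produces the full input side of the pipeline
with these components, all driven by one integer seed:

* **CpG placement**: a two-state renewal process — background gaps with
  mean `1/cpg_rate` (default 100 bp) and CpG-island episodes (entry
  probability 0.02, mean 15 CpGs at mean 10 bp spacing). Clustered
  placement matters because it makes window CpG counts vary realistically
  around the 5-site gate; uniform placement would make that filter almost
  deterministic.
* **Baseline levels**: a three-component mixture — weight 0.4 on
  `Beta(1, 15)` (near 0), 0.5 on `Beta(15, 1)` (near 1), 0.1 on
  `Beta(2, 2)` — giving the strongly bimodal genome-wide histogram
  characteristic of somatic methylomes, with a small intermediate
  fraction. Slightly more methylated than unmethylated mass reflects
  blood-derived DNA.
* **Depth**: negative binomial per site per sample (default mean 30,
  size 5), whose overdispersion produces the realistic fraction of sites
  failing the 10× gate in one sample but not the other; depth 0 leaves a
  site present-but-uncovered, as in real cytosine reports.
* **Planted regions**: `n_dmrs` non-overlapping runs of `dmr_n_cpgs`
  island-spaced CpGs whose true levels differ by exactly `±dmr_delta`
  between samples; the shared base level is drawn so the shift never
  clips, keeping the planted effect size exact. Read counts are then
  binomial in the true level, so observed window differences scatter
  around the planted value.
* **Gene models / TFBS / cohort**: non-overlapping multi-exon transcripts
  with valid UTR structure (optionally anchored so that chosen truth
  regions fall in a promoter flank), short named intervals with optional
  fold-enrichment inside given regions, and a 15-case / 5-control cohort
  with 20 clones per sample, per-clone Bernoulli methylation (defaults
  0.8 affected / 0.1 otherwise, penetrance 0.8 ≈ 12 of 15 affected) and
  expression `exp(1 − 3·mean + N(0, 0.3))`, i.e. log-linear decreasing
  with lognormal noise.

What it deliberately does **not** emulate: read-level artifacts (bisulfite
conversion failure, mapping bias, PCR duplicates), fragment-based coverage
correlation between neighbouring CpGs, non-CpG methylation structure,
chromosome-scale features (CNVs, imprinted domains), and biological
between-region variance heterogeneity. Tests passing on these simulations
therefore demonstrate the *statistical machinery* — calibration of the
window test, correctness of the filters, merging, annotation and cohort
statistics — not robustness to every artifact of real RRBS libraries.

## Test and benchmark scales

The packaged checks run the caller on two-chromosome genomes of 400 kb
(about 10,000 CpGs and 10,000 tested windows) with 50 planted regions for
sensitivity, and a matched signal-free pair for the null rate; smaller
40–150 kb genomes back the unit tests. These sizes give stable Monte-Carlo
estimates (binomial standard error on the null rate ≈ 0.001) while keeping
the whole suite fast; the caller itself is linear in the number of tested
windows and has no size-dependent logic, so behaviour at genome scale
differs only in runtime.

## Known limitations

* The rank-sum window test treats sites as exchangeable and ignores
  depth differences between sites; no beta-binomial dispersion model is
  fitted (explicitly out of scope).
* Exactly-tied alternative readings of "adjacent" merging (e.g. allowing
  small positive gaps) are not offered; adjacency means overlap-or-abut.
* The per-sample hypermethylation call rule is a parameter, not an
  estimate; cohort conclusions can depend on it, which is why both the
  midpoint and max-control rules are provided and the chosen cut is
  reported in the result object.
* `sample_correlation()` and the QC histogram describe CG-context sites
  only; CHG/CHH records are parsed and retained but excluded from testing
  by default, matching the CpG-focused design.
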