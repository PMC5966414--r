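---
title: "Calling tissue-specific and postnatally demethylated regions with postdmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling tissue-specific and postnatally demethylated regions with postdmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postdmr)
```

## The problem

Tissue-specific enhancers are marked by local loss of DNA methylation. In
several mouse tissues a sizeable fraction of these hypomethylated regions
is not established in the embryo but only during the first weeks of
postnatal life, and this demethylation (driven by TET enzymes and, for the
latest wave, by hormonal signals such as insulin and growth hormone) is
coupled to the postnatal induction of nearby genes. `postdmr` implements
the corresponding analysis as a reusable pipeline: from per-cytosine
bisulfite counts to tile methylation, tissue-specific and postnatal DMR
calls, a permutation significance test, genomic annotation and an
expression-association test, together with a ground-truth simulator used
to validate every stage.

## The model and its rules

**Tiles.** CpG calls (methylated reads / total reads per cytosine) are
strand-merged (a minus-strand cytosine at p belongs to the CpG at p−1) and
pooled into fixed, genome-anchored tiles (100 bp for RRBS-style data,
200 bp for WGBS). Tile methylation is the read-weighted pooled percentage
`100 * sum(meth) / sum(total)`, not a mean of per-CpG ratios, so the
downstream count-based test and the tile value are consistent. A tile is
reported in a sample only when it reaches a minimum number of pooled CpG
read observations (10 for 100-bp tiles, 15 for 200-bp tiles). The phrase
"minimum coverage of N CpGs" is ambiguous between pooled observations and
distinct sites; the pooled interpretation is the default because it is the
common RRBS tiling convention, and a strict distinct-sites mode is
available via `tiling_params(strict_sites = TRUE)`.

**Tissue-specific tiles.** A tile is specifically hypomethylated in the
target tissue when at least 5 non-target tissues of the panel are each at
least 50 percentage points more methylated (inclusive threshold); de novo
methylation is the mirrored rule. Both thresholds are absolute
percentage-point differences, matching heatmap scales and standard DMR
practice; a relative mode exists behind `relative_delta`. The nine-tissue
panel includes the target, so the comparison set is the other eight
tissues; the "5 of 9" count is therefore applied to non-target tissues and
both numbers are parameters. Tiles whose target mean is missing, or with
fewer informative comparison tissues than the discrimination minimum, are
untestable and reported separately (RRBS sparsity should be auditable, not
silently dropped).

**Postnatal timing.** Among tissue-hypo tiles of the target tissue, a tile
is postnatally demethylated when its replicate-mean methylation drops by
at least 35 points from newborn (1 week) to adult (15 weeks) *and* a
per-tile test is significant at p < 0.05. The timing is `early_postnatal`
when the 35-point drop is already achieved at the 3-week boundary,
`late_postnatal` otherwise, and `prenatal` when the tile is already below
5% in newborns. De novo calls mirror every comparison on
`100 − methylation`. The per-tile test is not specified beyond "p < 0.05"
in the source analysis; the default here is a two-sided Fisher exact test
on replicate-pooled 2×2 counts (counts are the primitive observable and
replicate numbers are small), with a Welch t-test on replicate percentages
as an option (`tile_test = "ttest"`). The delta is applied to replicate
means while the test uses pooled counts. No multiple-testing correction is
applied by default, to match the plain p < 0.05 rule; `fdr = TRUE`
switches to Benjamini–Hochberg.

**Permutation significance.** The size of a tissue-specific DMR set is
tested by label replacement: in each permutation the k target samples are
replaced by k samples drawn without replacement from the non-target pool,
the drawn samples simultaneously leave the comparison panel, and the
identical caller is re-run; the p-value is the add-one quantile
`(1 + #(permuted ≥ observed)) / (n_perm + 1)`, which never returns zero —
when no permutation reaches the observed count the value is reported as an
upper bound. Whether replaced target samples should rejoin the comparison
panel is not defined by the original description; here the true target
samples are excluded entirely from permuted datasets, which keeps the
permuted panel the same shape as the original and avoids leaking target
signal into the null. Permutation operates on tissue labels over the tile
matrix (tile means are recomputed per permutation, vectorized across
permutations as matrix products); reads are never re-tiled.

**Annotation.** Promoter = strand-aware [TSS − 1 kb, TSS + 100 bp];
intragenic = gene body extended 1 kb beyond the TES; everything else
intergenic; promoter takes precedence. Nearest-TSS distances are signed
positive downstream in the gene's orientation, with ties broken by the
lexicographically smaller gene id. Gene assignment keeps multi-gene
overlaps (collapsing to a nearest gene would silently drop association
links); "adjacent to genes" is not quantified in the source, so the
default adjacency is exactly promoter ∪ intragenic, with a TSS-window
mode as the alternative.

**Association.** The fraction of gene-assigned DMRs whose genes are
postnatally upregulated is compared with the same fraction for random
segments that are length-matched per DMR (sampling the observed length
distribution removes length bias) and pass through the byte-identical
assignment code. The statistic is the pooled-variance two-proportion
z-test `z = (p1 − p2) / sqrt(p(1−p)(1/n1 + 1/n2))`. Upregulation is taken
from a precomputed differential-expression table when one is supplied;
otherwise a stand-in rule (fold ≥ 1.5 and Welch-t p < 0.05 on
log2 values) is applied, since upstream RNA-seq quantification is outside
this package's scope.

## The synthetic-data generator

`simulate_methylomes()` emulates the statistical structure the analysis
assumes: 9 tissues × ages {1, 3, 15} weeks × 3 replicates; 20,000 100-bp
tiles, each with 5–15 CpG sites at fixed positions; read depth per site
1 + Poisson(29); per-site methylation probabilities Beta-distributed
around the tile's true mean (concentration 60); per-tile true means drawn
Beta around 0.85 for background (concentration 30), with a 10% fraction of
constitutively hypomethylated "island" tiles near 8%; RRBS sparsity as a
20% per-(tile, sample) dropout. Planted classes in the target tissue: 60
prenatal tiles (3% at all ages), 70 early-postnatal and 70 late-postnatal
tiles switching from 85% to 25% (a 60-point effect) at or after the 3-week
boundary, and 50 constitutive de novo tiles (target high, panel low).
`dko_mode` freezes the target tissue at its newborn state at every age
(emulating Tet2/Tet3 loss at birth, which prevents all postnatal
demethylation); `insr_mode` freezes only the late class (insulin-receptor
loss blocks specifically the demethylation occurring after 3 weeks). Both
modes share the genome layout and truth table with the wild type of the
same seed, so matched comparisons are possible. Half of the planted hypo
tiles are placed inside distinct gene bodies; `simulate_expression()`
gives those genes a 3-fold induction from their class onset age (early:
3 weeks, late: 15 weeks, prenatal: from birth) over log-normal baselines
with 0.15 log-SD replicate noise, attenuated to half the log fold-change
in `dko_mode`. All of these distributions and effect sizes are generator
choices — the source analysis specifies none of them — and every one is
exposed in `sim_config()`.

What the generator does *not* emulate: genome sequence and realistic CpG
clustering, within-tile heterogeneity beyond the Beta noise (no bimodal
allele-specific patterns), chromosome-scale covariates, batch effects, or
hydroxymethylation. Passing recovery tests on this generator therefore
demonstrates that the caller implements its rules correctly and has the
claimed operating characteristics under the generative model — not that
those characteristics transfer quantitatively to any real dataset.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open everywhere internally; 1-based input
  dialects are converted on read, so a given cytosine has one coordinate
  regardless of source format.
- Calls with zero total reads are dropped with a warning (they carry no
  information and occur in real exports); methylated > total is an error.
- All thresholds are inclusive (`>=` for deltas, `<` for alpha).
- A missing 3-week sample makes the early/late split undecidable;
  postnatal calls are then labeled `early_or_late_unknown` rather than
  silently assigned.
- The add-one permutation estimator returns 1/(n_perm+1) with an
  upper-bound flag when no permutation reaches the observed count, and
  exactly 1 when the observed count is 0.
- In the two-proportion z-test a degenerate pooled proportion (0 or 1)
  implies equal group proportions for valid inputs, and z is defined as 0.
- Random segments are redrawn (bounded rounds) when they hit an exclusion
  set; an infeasible exclusion raises an error instead of looping.
- Seeds: every stochastic entry point takes an integer seed, child seeds
  for pipeline stages are derived deterministically and kept within the
  32-bit integer range, and seeded code restores the caller's RNG state.

## Validation strategy and problem sizes

The test suite validates each operation against independent brute-force
oracles (hypergeometric enumeration for the exact test, an O(n·m) scan for
nearest-TSS, direct formula evaluation for the z-test, per-tile summation
for the tiling), property-style invariants (read conservation, monotone
suppression, direction symmetry between hypo and de novo, add-one
estimator identity, reproducibility under fixed seeds), and study-scale
recovery: on the default generator the caller attains ≥ 0.9 sensitivity
and ≥ 0.95 precision for planted hypo tiles with ≥ 85% correct early/late
timing, the 10,000-permutation test bounds p below 10⁻⁴ with at most a
handful of permuted calls, and 200 independent null datasets (600 tiles,
adult panel only, 1,000 permutations each) show the permutation p-value is
conservative at α ∈ {0.01, 0.05, 0.1} with a per-tile false-call rate
below 1%. These sizes — 20,000 tiles for the study-scale checks, 600-2,000
tiles for repeated calibration and sweep checks — were chosen so the whole
suite runs comfortably on a laptop while keeping every assertion at the
scale stated above. One caveat worth knowing: under the stringent 50-point
rule the null distribution of permuted DMR counts is degenerate at zero,
so null-calibration p-values concentrate at 1; the calibration check is
therefore a one-sided validity bound, not a uniformity test. On generator
self-consistency, tiles that survive dropout in only one replicate carry a
~3-point binomial standard error at depth 30, so the "within 5 points of
truth" envelope is asserted for tiles observed in at least two replicates
(99%) and relaxed to 95% over all tiles.

## Known limitations

- The caller is threshold-based by design fidelity; it does not model
  biological dispersion (no beta-binomial shrinkage, no smoothing or HMM
  segmentation), so its error rates on real data depend on the thresholds
  in a way the simulation can only illustrate.
- The internal upregulation rule is a deliberate stand-in; serious use
  should supply a differential-expression table from a dedicated tool.
- The permutation test evaluates the tissue-specific rule only (postnatal
  classification is conditioned on it), matching the original procedure.
- Fisher's exact test on replicate-pooled counts treats replicates as
  exchangeable sequencing of one pool and, at high depth, can declare
  small deltas significant; the 35-point delta filter is what keeps calls
  biologically meaningful, and the replicate-level t-test option trades
  power for robustness to replicate variance.
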