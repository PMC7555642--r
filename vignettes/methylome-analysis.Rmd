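---
title: "Methods: paired-condition WGBS methylome analysis with methylowp"
author: "methylowp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-condition WGBS methylome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylowp)
library(data.table)
```

## Scope and model

`methylowp` analyses whole-genome bisulfite sequencing (WGBS) methylomes in
a paired stress/control design, with the low- versus high-phosphorus soybean
root comparison as the motivating system. The pipeline starts where
alignment ends: its atomic observation is one cytosine with a strand, a
sequence context (CG, CHG or CHH, where H is A, C or T, read from the two
bases 3' of the cytosine on its own strand), a methylated read count and a
total read count — the shape of BSMAP's `methratio` output. All internal
coordinates are 0-based half-open; GFF3 and the 1-based cytosine TSV dialect
are converted at the I/O boundary, which confines off-by-one risk to two
functions (`read_annotation`, `read_cytosine_table`) that are round-trip
tested.

The methylation level of any set of cytosines is the *weighted* fraction
`sum(methylated reads) / sum(total reads)` — the mCG/CG-style quantity — not
the mean of per-site fractions. The weighted form is robust to coverage
heterogeneity and is what every summary in the package (global levels,
profile bins, region levels, DMR levels) reports. Levels condition on
covered cytosines: a context with no covered site reports `NA`, never 0.
Cytosines whose context cannot be determined (chromosome ends, Ns) are
annotated `UNKNOWN` and excluded from all statistics, because every
denominator in this analysis is context-conditional.

Symmetric CG positions are *not* merged across strands: `methratio`-style
inputs report strands separately, and downstream arithmetic is agnostic to
the choice as long as it is consistent.

## Calling methylated cytosines

The binary "methylated cytosine" call feeds the DMR criteria. A site is
testable when covered by at least 4 reads; its one-sided binomial p-value
against the bisulfite conversion failure rate (estimated from the
unmethylated lambda spike-in, `conversion_efficiency()`) is
Benjamini–Hochberg corrected across all testable sites, and sites with
q < 0.01 are called methylated. The 4-read floor matches the coverage rule
the DMR definition uses; the genome-wide BH correction at 0.01 keeps the
genome-wide false-call rate low without a per-site coverage-dependent
threshold. Both knobs are exposed (`min_cov`, `alpha`).

## The DMR caller

`call_dmrs()` implements a six-criterion region definition per context
between two samples:

1. at least 5 methylated cytosines in at least one sample,
2. every member cytosine covered by >= 4 reads in both samples,
3. region length between 40 bp and 10 kb,
4. adjacent member cytosines less than 200 bp apart,
5. pooled methylation level change of at least two-fold,
6. uncorrected Pearson chi-square p <= 0.05 on the pooled 2x2 read-count
   table, with BH FDR < 0.05 across tested regions per context.

Design choices a maintainer should know about:

* **Qualifying sites and chaining.** Sites with adequate coverage in both
  samples that are called methylated in *at least one* sample are chained
  while consecutive gaps stay under 200 bp. The stricter "methylated in
  both samples" reading is available (`require_both_samples`). Chains longer
  than 10 kb are split at their largest internal gap, recursively, which
  preserves dense cores; on genomes whose CG/CHG methylation is pervasive
  this reproduces window-like tiling, while CHH regions resolve to discrete
  islands.
* **The tested counts are the region's, not the discovery set's.** The 2x2
  table pools *all* adequately covered same-context cytosines in the region
  span. Pooling only the sites whose calls triggered discovery conditions
  the statistic on a one-sample-high selection event and produces
  winner's-curse false positives on null data (we measured ~8% of calls on
  a null background before adopting the region-wide pooling); the region's
  "average methylation level" is a property of the region.
* **No continuity correction.** The test is Pearson's chi-square; a Yates
  correction would change calls near the threshold.
* **Fold change** uses the weighted levels; when one pooled level is 0 a
  pseudocount of 0.5 reads per cell guards against infinite folds.
* **FDR pooling is per context**, matching per-context DMR reporting.
* `audit_dmrs()` re-verifies every emitted DMR from the raw tables through
  an independent code path (including `chisq.test` for the statistic); the
  test suite requires 100% audit agreement on benchmark calls.

Monotonicity (raising `min_fold` or lowering `p_cut` never adds a DMR),
antisymmetry (swapping samples flips every direction at identical
coordinates) and the audit are enforced by tests.

## Metagene profiles and methylation–expression association

One binning engine (`bin_positions()`) maps positions onto an
upstream-flank / body / downstream-flank coordinate system: 2-kb flanks in
fixed 100-bp bins, the body in 20 equal *relative* slices (the standard
metagene convention for variable-length bodies; the fixed-width 100-bp rule
applies to the flanks, whose length is constant). Cytosines are weighted by
fractional overlap with body slices, so genes shorter than the bin count
are retained rather than dropped; minus-strand features are flipped so bin
0 is always 5'. Bin values pool reads across features (weighted); an
unweighted per-feature mean is available (`average = "features"`). The
siRNA TE profile uses the same engine in point mode with read midpoints,
and a test asserts the two routes agree bin-for-bin.

Expression analysis partitions genes into a non-expressed class
(FPKM < 0.1) plus four ascending expression groups; methylated genes are
separately split into five ascending quintiles by promoter or gene-body
level, with genes lacking any called methylated cytosine in the region
forming an `unmethylated` class. Methylation–expression association is
Spearman's rho between region levels and `log10(FPKM + 1e-3)`; the
pseudocount only de-degenerates zeros and cannot affect ranks among
positive values.

## Differential expression

FPKM is `counts * 1e9 / (length * library size)` with library sizes the
column sums. Differential calls use an exact two-sided binomial test on
pooled counts per gene (condition share against the library-size
proportion), BH correction, and the joint gate |log2 fold| >= 1 (boundary
inclusive) with q < 0.05, the fold computed on mean FPKM with a 0.1
pseudocount. Negative-binomial replicate noise makes the naive pooled
binomial grossly anticonservative for well-expressed genes, so the test is
moderated: a common NB dispersion is estimated from the replicates by
method of moments (`estimate_nb_dispersion()`) and the pooled counts are
deflated by the per-gene variance-inflation factor `1 + alpha * mean`
before the exact test — a quasi-binomial effective-sample-size correction,
not a reimplementation of NB regression machinery. With a single replicate
per condition the moderation degrades gracefully to the plain binomial
test (`dispersion = 0` forces it). DEG sets from this statistic are
method-comparable with NB-based callers, not method-identical.

## Integration and enrichment

A DMR is associated with every gene whose body or strand-aware 2-kb flank
it overlaps by at least 1 bp, and with every TE it overlaps. The single
reported location class takes the largest overlap, with ties broken by the
precedence gene_body > upstream > downstream > TE (the multi-overlap rule is
a package convention — the class percentages one reads in such analyses do
not define it — and both the precedence and a minimum-overlap alternative
are arguments). Term enrichment is the exact hypergeometric upper tail with
BH across terms; terms with fewer than 3 universe genes are skipped by
default for stability. Expression of hyper-/hypomethylated gene classes is
compared against all genes with a two-sided Wilcoxon rank-sum test
(exact by enumeration up to a combined n of 12, normal approximation with
tie and continuity correction beyond).

## The synthetic-data generator

Every pipeline stage is exercised on generated data with recorded truth;
a `sim_config()` (including its seed) fully determines every output, and
byte-identical regeneration is tested. The generator emulates the
statistical structure of a low-P root methylome experiment:

* **Genome**: random sequence at GC 0.35; TEs placed to occupy a configured
  fraction (class I majority, LTR/Gypsy-dominated), genes in the remaining
  space; a 48.5-kb unmethylated "lambda" chromosome is appended for
  conversion-efficiency estimation.
* **CG/CHG levels** are uniform bases (0.665 / 0.436) plus TE boosts, a
  gene-body CG boost, a per-gene lognormal CG modifier (the methylation
  latent used for expression coupling) and linear dips within 300 bp of
  TSS/TES.
* **CHH is structured, not uniform**: a background at 0.002 — deliberately
  *below* the 0.004 conversion-failure rate, so background cytosines are
  statistically indistinguishable from unmethylated space and
  methylated-site chains terminate there — plus a TE compartment
  (per-TE lognormal intensity around 0.10) and discrete intergenic islands
  (~0.45, 400–1200 bp), mirroring RdDM-targeted methylation concentrated in
  islands over near-zero background. A uniform low CHH level would make
  ~10% of the dense CHH sites individually callable, the called sites would
  sit closer than the 200-bp chaining gap, and the caller would fuse the
  genome into 10-kb windows — boundary-resolved CHH DMR benchmarking would
  be impossible and un-plant-like.
* **Calibration**: each context's site-level mean is iteratively rescaled so
  the genome-wide HP mean equals the configured base level exactly; the
  observed weighted estimator is then unbiased for it (after
  conversion-error correction), which is what the parameter-recovery
  checks verify at 3 standard errors.
* **Coverage** is marginally NB (mean 30, dispersion 0.2) via a per-position
  Gamma propensity *shared across samples* with per-sample Poisson draws.
  Real WGBS coverage is strongly positionally correlated between libraries
  (mappability, GC); modelling that also matters statistically — with
  fully independent coverage, sample-specific re-weighting of
  level-heterogeneous windows inflates the pooled chi-square to ~7.5% at
  p <= 0.05 on null data, where the shared-propensity model sits near
  nominal.
* **Conditions**: LP adds a small global shift (+0.01 per context,
  "slightly higher under stress") and multiplies each TE's CHH level by a
  per-TE lognormal factor with mean < 1, so hypomethylated TEs outnumber
  hypermethylated ones in CHH without being unanimous — both directions
  occur, as in real comparisons.
* **Spiked DMRs** (benchmark preset `sim_config_dmr_benchmark()`): 50 CHH
  regions of 200–2000 bp shifted by ±0.4 in LP only, 60% hyper. Hyper
  spikes sit in clean intergenic background; hypo spikes consume existing
  islands, so both directions produce >= 2-fold regional changes. Truth
  features keep >= 600-bp margins from other methylated features (3x the
  chaining gap): with smaller margins a single chance-called background
  cytosine can bridge a spike to a neighbour, merging calls and voiding
  reciprocal-overlap accounting. The preset switches the global LP shift
  and the TE CHH reduction off so the spikes are the only true
  between-condition differences and false-discovery accounting is exact.
* **Expression**: a per-gene latent drives promoter+body CG levels; a
  correlated latent decides silencing (fraction 0.25, tilted towards
  methylated genes) and, for expressed genes, log2 expression (latent
  correlation `-coupling_strength`, default 0.25, with the methylation
  latent). This makes the generating coupling a recoverable rank target:
  the acceptance checks compare the measured Spearman against the
  *realized* truth (true promoter level vs true expression) among expressed
  genes, where the target is identifiable — the silent class is a tied
  block in truth whose measured-FPKM ranks are noise, so only the sign is
  checked on all genes. Replicate counts are NB with dispersion 0.05
  (replicates are pools of several plants, so between-pool variance is
  low); 100 genes receive a 4-fold LP shift with random sign, drawn from
  genes with expected counts >= 25 so the spiked truth is detectable.
* **siRNA**: per-TE read numbers proportional to the TE's CHH intensity
  (times the TE's LP factor under LP), positions decaying exponentially
  from TE boundaries, 55% of reads 24 nt, plus a uniform background.

What passing these tests shows — and what it does not: the synthetic data
reproduce the *statistical* structure of the motivating system
(per-context levels, TE hypermethylation, boundary dips, coupling signs,
24-nt dominance), so a green suite certifies the arithmetic, the
algorithmic contracts and truth recovery under that structure. It does not
certify behaviour under features the generator omits: sequence-driven
coverage bias beyond the shared propensity, mapping artefacts,
partially-methylated epialleles, copy-number variation between cultivars,
or biological replicate structure in the methylomes (single methylome per
condition, as in the motivating design).

## Problem sizes

The heavyweight checks use, by design: a 1-Mb two-chromosome genome at
coverage 30 for the DMR benchmark; 200 independent 60-kb single-chromosome
null pairs for calibration (regions pooled across replicates); a 30-Mb,
5000-gene genome at coverage 10 for expression coupling and the
expression-group/quintile patterns; 4-Mb genomes for differential-TE
counts (the CHH hypo/hyper TE excess is a ~1.4:1 ratio, so a few hundred
TEs are needed for a stable sign — the acceptance script pools three such
genomes). These sizes are stated here so users rescaling the experiments
know what the reported numbers were computed on.

## Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates every dataset
from the seed and recomputes: the four mapped ratios, DMR recovery /
false-discovery / null-calibration percentages, the maximum deviations of
the statistical primitives from brute-force oracles, recovered global
levels and conversion efficiency, the true and recovered
methylation–expression Spearman, DEG power and false discovery, and the
qualitative pattern indicators, writing them as flat JSON. The README shows
a worked end-to-end example with the numbers it prints.
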