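---
title: "Models and methods behind pancankit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pancankit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pancankit packages the gene-centric analyses of a multi-layer pan-cancer
cohort — differential expression, correlation with mutational burden and the
immune microenvironment, survival, enrichment — together with a synthetic
cohort generator that makes every one of them testable by parameter
recovery. This vignette documents the models, the defaults and why they are
set where they are, and the limits of what the tests demonstrate.

```{r setup}
library(pancankit)
```

## The cohort model and preparation rules

A cohort aligns expression, clinical annotation, TMB, MSI, immune-cell
ratios, immune scores and promoter methylation by sample barcode. Three
preparation rules are applied at ingest and hold as invariants afterwards:

* duplicated samples — several aliquots of one (patient, group, cancer)
  class — are reduced to one, chosen by a seeded uniform draw over the
  lexicographically sorted duplicates. Random removal is made reproducible
  deliberately: the seed is recorded in the bundle manifest, so two ingests
  of the same files agree byte for byte;
* genes with TPM 0 in every sample are dropped, and values are stored as
  log2(TPM+1) from then on — every "expression" in this package is on that
  scale;
* promoter methylation is the per-gene mean beta over probes annotated to
  the TSS1500 region *and* a CpG island. The mean (rather than median, or a
  most-variable-probe rule) is our documented choice where the convention
  is genuinely open; `aggregate_promoter_methylation(fun = "median")`
  exposes the alternative.

Pairing is defined through the barcode grammar (patient = first three
fields; sample-type codes 01–09 tumor, 10–19 normal; codes ≥ 20 are
rejected rather than silently grouped, to keep controls out of the normal
pool). Paired analyses require **strictly more than 20 pairs** per cancer;
`list_cancers()` applies the same strict rule to its eligibility flag.
Layers are aligned lazily — each analysis intersects sample ids at run
time — so partial cohorts are legal inputs.

## The statistics core

Group comparisons behind boxplots use rank tests: Mann–Whitney for
unpaired tumor/normal, Wilcoxon signed-rank for pairs, Kruskal–Wallis for
three or more groups. Exact p-values are computed by full enumeration when
it is cheap (labelings at min(n) ≤ 8, sign patterns at n ≤ 12, no ties);
otherwise the normal approximation with tie and continuity corrections is
used. The test suite pins both branches to independent brute-force oracles.
Stars follow the conventional strict thresholds (ns at p ≥ 0.05, then
\*, \*\*, \*\*\*, \*\*\*\* at 0.05, 0.01, 0.001, 0.0001).

Cox regression maximizes the Efron partial likelihood by Newton–Raphson
(tolerance 1e-9 on the log-likelihood change, at most 50 iterations, step
halving on overshoot). Monotone likelihoods — perfect separation — are
reported as errors rather than returning a boundary estimate. In the
pan-cancer forest the gene is standardized within each cancer, so hazard
ratios are per expression SD and comparable across cancers; that is a
deliberate divergence from per-unit-expression HRs and is stated in the
output metadata. Age adjustment adds age as a second continuous covariate;
the reported HR remains the gene's.

Survival splits (expression or methylation) are at the median, ties to the
low group — a deterministic rule, chosen because the cutoff convention is
genuinely open; optimal-cutpoint scanning is out of scope. The same
median/ties-low rule drives the high/low DEG screen, whose effect size is
the difference of log2 means (equivalently the log2 fold change of
geometric means of TPM+1).

The ROC curve is traced over all distinct thresholds and its trapezoid
area equals the midrank Mann–Whitney identity U/(n₁n₀) exactly, ties
included — an identity the tests verify to 1e-12 on a thousand random
fixtures.

Single-sample enrichment orders a sample's genes by decreasing expression
(ties broken by symbol, so scoring is deterministic), walks the list adding
normalized rank weights (N−i+1)^α (α = 0.25) for set members and a uniform
penalty otherwise, and sums the running difference — a statistic that
depends only on the expression ranking, hence invariant to monotone
transforms. Stromal and Immune scores are this statistic over the two
signature sets; ESTIMATE is their sum by construction.

Preranked GSEA uses the weighted KS running statistic (weight exponent 1 on
|metric|) with a seeded gene-label permutation null — phenotype permutation
is not possible for preranked input. The p-value is two-sided on |ES| with
the +1 correction, p = (1 + #{|ES₀| ≥ |ES|})/(B+1); we chose the two-sided
count over a sign-restricted one because the latter concentrates below
~0.5 under the null, while this definition is calibrated (label-permuted
rankings give near-uniform p, which the suite checks with a KS test across
200 seeds). NES divides ES by the mean |null ES| of matching sign.
Over-representation uses the upper-tail hypergeometric with BH across
terms, and its background is always the genes actually tested — not a
genome — to keep the null honest.

## The synthetic cohort and what it shows

`generate_cohort()` draws per-gene baselines from a normal on the log2
scale (mean 4, SD 1.5 across genes — a realistic spread for log2(TPM+1) in
bulk data) with unit within-gene noise, clamped at 0. Planted effects:

* differential expression — a constant shift on tumor samples;
* TMB/MSI coupling — a Gaussian copula on the standardized gene value,
  mapped linearly (TMB ~ 10 ± 3 mutations/Mb, MSI ~ 1 ± 0.3, clamped at 0),
  so the planted Pearson r is recovered without attenuation;
* methylation coupling — the same copula pushed through a logistic link to
  keep betas in [0,1]; the link attenuates |r| but preserves sign, which is
  what the recovery checks assert;
* hazards — exponential survival with log hazard = planted log-HR ×
  standardized expression, censored by independent uniform administrative
  censoring whose horizon is solved numerically to hit the requested rate
  (default 30%), keeping the KM/Cox assumptions exactly true;
* immune coupling — a coupled shift on the immune-signature genes, so the
  association with the Immune score arises mechanistically through the
  scoring function rather than being painted onto the score table.

The reference fixture (seed fixed in code) uses 4 cancers — 400/60/50/40
tumors, two cancers above the 20-pair threshold — and 500 genes, sizes
chosen so planted effects are recovered with comfortable margins while the
full suite stays fast. The generator emulates layer structure and planted
monotone associations; it does **not** emulate count overdispersion,
batch effects, subtype mixtures, or realistic marginal distributions of
real cohorts, so passing recovery tests demonstrates correctness of the
analysis machinery, not robustness to real-data pathologies.

## Numerical and design notes

* All stochastic procedures take an explicit seed; there is no hidden
  global randomness, and generation restores the caller's RNG state.
* Correlation analyses use tumor samples only (normals would confound
  microenvironment questions); minimum group sizes are 3 for tests and 5
  for correlations per cancer, logged in the result metadata.
* Age groupings: the two-group split is at 65 years; the three-group split
  uses rank tertiles (deterministic, sizes within 1). Both are arguments,
  not constants. Stage labels collapse sub-stages (IIA → II) and discard
  non-tumor stage strings ("Stage X" → missing); analyses report how many
  samples were dropped for missing grouping data.
* GSEA ranks DEGs by log2FC (not signed p) — configurable through the
  ranking you pass to `preranked_gsea()` directly.
* Catalogs (GO/KEGG or custom) are user-supplied GMT files; the fixture
  ships toy catalogs. Shipping annotation databases is out of scope.
* q columns are always BH over exactly the p column of the table they
  appear in.
* Rendering never recomputes statistics: plots read effects, stars and CIs
  from the payload tables, and network layouts are seeded, so a figure is a
  pure function of (payload, seed).

## Known limitations

Rank tests are unmoderated (no limma/DESeq2-style shrinkage), Cox has no
time-dependent covariates, KM uses a fixed median cutoff, and the
single-sample scores are our own implementation of the rank-weighted
statistic — consistent and monotone-invariant, but score magnitudes are
not interchangeable with other tools' outputs. Figure aesthetics
approximate the usual publication palettes rather than reproducing any
specific theme.
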