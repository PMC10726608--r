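# pancankit

Integrative pan-cancer analysis of multi-layer tumor cohorts, for
bioinformaticians who want the standard battery of TCGA-style gene-centric
analyses — differential expression, immune and mutational-burden
correlations, survival, enrichment — as tested, scriptable R functions that
run end to end on synthetic data, with no multi-gigabyte download.

## What it does

A **cohort** aligns seven data layers by sample barcode: expression
(stored as log2(TPM+1)), clinical annotation (age, gender, stage, overall
survival), tumor mutational burden (TMB, mutations/Mb), microsatellite
instability (MSI), immune-cell ratios, ssGSEA-based Stromal/Immune/ESTIMATE
scores, and promoter methylation (mean beta over TSS1500 CpG-island
probes). Barcodes follow the TCGA grammar: the first three dash-delimited
fields identify the patient and the 4th field's two digits encode the
sample type (01–09 tumor, 10–19 normal), which is what makes tumor/normal
*pairing* well defined. Paired analyses include only cancers with strictly
more than 20 tumor–normal pairs.

On top of a hand-written statistics core — Mann–Whitney and Wilcoxon
signed-rank tests (exact by enumeration at small n), Kruskal–Wallis,
Benjamini–Hochberg, Pearson/Spearman correlation with t-based p-values,
Kaplan–Meier, the log-rank test, Cox proportional hazards with Efron tie
handling (HR = e^β per expression SD, Wald 95% CI), ROC/AUC (trapezoid,
equal to the midrank U/(n₁n₀) identity), single-sample rank-weighted
enrichment (weight (N−i+1)^α, α = 0.25), preranked GSEA (weighted KS
statistic, seeded gene-label permutations, p = (1 + #{|ES₀| ≥ |ES|})/(B+1))
and hypergeometric over-representation — the package exposes the analyses a
pan-cancer study reports:

* `pan_expression()` — tumor vs normal per cancer (unpaired, paired, tumor-only)
* `pan_metric_correlation()` — expression vs TMB or MSI per cancer (radar payload)
* `pan_family_heatmap()` — correlation grids against immune gene families
* `pan_immune_correlation()` — vs immune-cell ratios or immune scores
* `pan_cox_forest()` — per-cancer hazard ratios with CIs
* `grouped_expression()`, `diagnostic_roc()`, `deg_and_gsea()`,
  `gene_gene_correlation()`, `gene_methylation_correlation()`,
  `coexpression_panel()`, `survival_by_level()`, `term_network()` —
  cancer-type-specific analyses

Both single genes and GMT gene sets (scored as the member mean) flow
through the same code paths. Every result is a tibble (or carries tidy()/
glance() methods), every result type has an `autoplot()` method, and a thin
CLI (`cli_run()`, launcher in `inst/cli/pancankit`) mirrors the analyses as
kebab-case subcommands.

The synthetic-cohort generator (`cohort_spec()` / `generate_cohort()`)
plants recorded effects — log2 fold changes, Gaussian-copula metric
correlations, per-SD log hazards, logistic-linked methylation coupling —
and returns the truth table alongside the cohort, so every analysis is
validated by parameter recovery.

## Worked example

```r
library(pancankit)
fx <- reference_fixture()   # 4 cancers, 625 samples, 500 genes, all layers
cohort <- fx$cohort

list_cancers(cohort)
#> # A tibble: 4 × 5
#>   cancer_type n_tumor n_normal n_pairs pair_eligible
#>   <chr>         <int>    <int>   <int> <lgl>
#> 1 SYNA            400       30      25 TRUE
#> 2 SYNB             60       35      30 TRUE
#> 3 SYNC             50       10       8 FALSE
#> 4 SYND             40        0       0 FALSE

pan_expression(cohort, "KLF7", "unpaired")
#> # A tibble: 3 × 8
#>   cancer_type  effect  stat        p    n1    n2        q stars
#>   <chr>         <dbl> <dbl>    <dbl> <int> <int>    <dbl> <chr>
#> 1 SYNA         1.96   10834 1.81e-13   400    30 5.42e-13 ****
#> 2 SYNB        -0.386    811 6.58e- 2    60    35 9.86e- 2 ns
#> 3 SYNC         0.0105   247 9.60e- 1    50    10 9.60e- 1 ns
```

`effect` is the tumor-minus-normal difference of group means on the log2
scale; `stars` follows the usual legend (ns, \*p<0.05, \*\*p<0.01,
\*\*\*p<0.001, \*\*\*\*p<0.0001). The fixture plants a log2FC of 2 for
KLF7 in SYNA only — recovered as 1.96 — and the generator's truth table
(`fx$truth`) records every planted effect for comparison. The Cox forest
recovers the planted per-SD log hazard of 0.7:

```r
pan_cox_forest(cohort, "KLF7")
#> # A tibble: 4 × 9
#>   cancer_type    hr ci_low ci_high        p     n n_events        q stars
#> 1 SYNA        1.91   1.67     2.18 1.64e-21   400      277 6.55e-21 ****
#> 2 SYNB        0.905  0.684    1.20 4.83e- 1    60       42 4.83e- 1 ns
#> ...
autoplot(pan_cox_forest(cohort, "KLF7"))   # forest plot
```

From the shell, against a cohort bundle on disk:

```sh
Rscript inst/cli/pancankit simulate --out work --bundle work/cohort
Rscript inst/cli/pancankit pan-boxplot --cohort work/cohort --gene KLF7 \
    --palette jco --legend right --out work
Rscript inst/cli/pancankit pan-forest --cohort work/cohort --gene KLF7 --adjust --out work
```

Each analysis subcommand writes `<command>.tsv`, a figure, and a
`<command>.log.yaml` with the seed and config hash; `get-*` subcommands
stream TSV to stdout.

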