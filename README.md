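# xreact

Allele-specific analysis of X chromosome reactivation.

In female mouse cells one X chromosome is silenced (X chromosome
inactivation). In an F1 hybrid between Cast/EiJ and C57BL/6, strain SNPs
assign RNA-seq reads to the inactive-X (cast) or active-X (Bl6) allele, so
each gene's inactive-X expression can be measured as the allelic ratio
`cast / (cast + Bl6)`. When silencing is perturbed (*Xist* knockdown plus
DNMT1 inhibition), some genes reactivate from the inactive X. xreact is for
analysts of such experiments: it classifies X-linked genes from allelic
count tables and relates the calls to genomic and epigenomic context.

The core statistic is a per-gene beta-binomial likelihood-ratio test of
allelic imbalance. With cast counts *k* and totals *n* per replicate,

- H0: one cast fraction *p* shared by control and treated,
- H1: free fractions per condition,

with *k* ~ BetaBin(*n*, *p*, ρ) and a single moment-based overdispersion ρ
shared across genes. 2(ℓ₁ − ℓ₀) is referred to χ²(1), p values are BH
adjusted, and a gene is called **reactivated** when FDR < α and its pooled
treated-minus-control ratio difference is positive. Around the test sit an
informative-coverage filter (mean allelic reads ≥ 10 per condition),
an escapee call (control cast ratio ≥ 0.10), per-gene features (promoter CpG
counts, SINE/LINE landscape in ±100 kb, distance to the nearest escapee,
metagene profiles), a per-TAD two-sided exact binomial enrichment test of
reactivated genes, MeD-seq-style promoter methylation analysis, and
gene-list overlap statistics.

A synthetic-data generator (`simulate_xci()`) plants a known class
structure — 2,612 X-linked genes, 447 informative, 45 escapees, 86
reactivated, a mid-ranking reference gene ("Mecp2") with 7 stronger
effects, 16 hypomethylated reactivated promoters, 4 reactivation-enriched
TADs and 1 depleted TAD — so the entire pipeline can be exercised and
validated without external data.

## Worked example

```r
library(xreact)

config <- xcr_config(seed = 1)          # the default synthetic study
bundle <- simulate_xci(config)

classes <- classify_genes(bundle$counts, bundle$genes)
glance(classes)
#> # A tibble: 1 × 9
#>   n_genes n_informative n_escapees n_reactivated n_non_reactivated alpha method
#>     <int>         <int>      <int>         <int>             <int> <dbl> <chr>
#> 1    2612           447         45            86               316  0.05 betabi…
```

Of 2,612 annotated genes, 447 carry enough allelic coverage to interpret;
45 of those escape inactivation (cast ratio ≥ 0.10 already in the control),
86 reactivate in the treated condition at FDR 0.05, and 316 stay silenced.
Per-gene detail comes from `tidy()`:

```r
dplyr::filter(tidy(classes), status == "reactivated")
#> # A tibble: 86 × 9
#>   gene_id name   status      control_cast_ratio treated_cast_ratio delta_ratio
#>   <chr>   <chr>  <chr>                    <dbl>              <dbl>       <dbl>
#> 1 XG0019  XG0019 reactivated            0.00120             0.123       0.122
#> 2 XG0020  XG0020 reactivated            0.00123             0.0977      0.0964
#> 3 XG0023  XG0023 reactivated            0                   0.112       0.112
#> ...
```

A reactivated gene moves from essentially zero cast expression to an
appreciable share (here 8–12% of total) in the treated population.
Ranking the calls against the planted reference gene:

```r
rank_reactivated(classes, bundle$truth$reference_gene)$n_above_reference
#> [1] 7
```

seven genes reactivate more significantly than the reference. TAD-level
spatial clustering:

```r
tads <- run_tad_enrichment(classes, bundle$genes, bundle$tads)
glance(tads)
#> # A tibble: 1 × 5
#>   n_tads n_enriched n_depleted    p0 alpha
#>    <int>      <int>      <int> <dbl> <dbl>
#> 1    112          4          1 0.214  0.05
```

Against the chromosome-wide reactivated fraction p0 = 0.214, four TADs are
significantly enriched for reactivated genes and one is significantly
depleted. `autoplot(classes)`, `autoplot(tads)`, `plot_feature_violin()`
and `plot_metagene()` produce the matching ggplot figures, and
`xcr_run_pipeline(config, out_dir)` runs every stage end to end, writing
TSV/BED/bedGraph outputs with a content-hash manifest.

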