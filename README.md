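# driverlens

Integrated prioritization of putative cancer driver genes.

Tumour genomes carry many somatic mutations, most of them passengers fixed
without any role in tumorigenesis. Frequency-based driver discovery finds
genes that recur across cohorts but misses rare drivers and is confounded
by gene length (long genes collect passengers faster). driverlens is for
cancer genomicists who want the complementary, property-based route: in
tumours *without* a mutated-and-expressed known cancer gene, it nominates
mutated genes whose properties resemble those of known cancer genes.

A gene in a retained sample is called a putative driver when it passes, in
order:

1. **expression** — called expressed in that sample: at least half of its
   probes have detection *p* < 0.05;
2. **mutation effect** — frameshift / nonsense / splice-site, or missense
   with a 2-of-3 predictor consensus (SIFT > 0.95 on the damage-oriented
   scale, PolyPhen > 0.9, MutationTaster "disease causing");
3. **length/recurrence** — coding length < 4,450 bp (bottom 95% of human
   genes), or if longer, mutated in fewer than five cancer types;
4. **systems-level properties** — at least 2 of 4: central hub (strictly
   above the 75th percentile of both degree and unnormalized betweenness
   in the protein-interaction network), direct interactor of a known
   cancer protein, ancient/metazoan/vertebrate evolutionary origin,
   singleton (no human paralog).

Samples where a known cancer gene is mutated and expressed are set aside
first (a likely driver is already known), as are samples whose mutated
genes all lack expression data. Every (sample, gene) pair keeps a full
filter trace, so each call is auditable.

The package also scores pooled shRNA silencing screens — per probe *i*,
cell line *h*, with *m* line and *n* pool replicates,

    log2ratio_shRNA(h,i) = log2( mean_j score(h,i,j) / mean_k score(DNA,i,k) )

collapsed per gene to the top-scoring probe — and provides the group
statistics used throughout (2×2 chi-squared volcano comparisons, Fisher
exact breadth-class enrichment, Wilcoxon rank-sum with Shapiro–Wilk
reporting). A seeded synthetic-cohort generator with planted drivers and
planted screen suppressors supports benchmarking end to end.

## Worked example

```r
library(driverlens)
library(dplyr)

cohort <- simulate_cohort(synthetic_config(n_samples = 40, n_genes = 500,
                                           seed = 42))
cohort
#> <synthetic_cohort> seed 42
#> <cohort_bundle>
#>   genes:      500 (10 known cancer genes)
#>   mutations:  774 in 40 samples
#>   expression: 40 contexts x 500 genes
#>   network:    500 nodes, 997 edges
#>   truth: 8 planted driver calls in 4 clean samples; 50 screen suppressors

report <- run_pipeline(cohort$bundle, pipeline_config())
report
#> <driver_report>
#>   samples: 40 total, 4 retained, 36 discarded
#>   drivers: 10 calls of 10 unique genes in 4 samples
```

36 of 40 samples (90%, the configured fraction) carry a mutated and
expressed known cancer gene and are discarded. In the 4 retained samples
the cascade calls 10 drivers — the 8 planted ones plus 2 damaging, short,
systems-passing passengers:

```r
evaluate_recovery(report, cohort$truth$drivers)$sensitivity
#> [1] 1

tidy(report) |> count(failure_stage)
#> # A tibble: 4 × 2
#>   failure_stage     n
#>   <chr>         <int>
#> 1 damaging         31
#> 2 expression       34
#> 3 systems           1
#> 4 <NA>             10
```

`failure_stage` is the first stage each mutated gene failed (`NA` = called
as a driver). `tidy(report)` returns the full trace, `glance(report)` the
summary counts, `autoplot(report)` the stage histogram; `plot_volcano()`,
`autoplot()` on a length trend and `plot_silencing_groups()` cover the
other result types.

A thin command-line wrapper is included at `inst/cli/driverlens.R`
(subcommands `run`, `simulate`, `recover`) for running the pipeline from
files (MAF or simple mutation tables, probe-detection TSV, edge-list TSV,
gene-annotation TSV, GCT 1.2 screens, YAML configs).

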