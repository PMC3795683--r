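# crossmark

Cross-platform consensus discovery of cell-population marker transcripts,
and subtype-aware evaluation of a marker's prognostic value in tumor
cohorts.

## The problem

Distinguishing infiltrating monocytes/macrophages from tissue-resident
microglia in brain tumors needs transcripts that separate the two
populations robustly — robustly enough that a call does not depend on
which sequencing or microarray analysis pipeline produced it. And once a
candidate surface marker is in hand, its association with patient
survival is only convincing if it survives adjustment for molecular
subtype, because immune-related genes track the subtypes that themselves
carry prognosis.

crossmark implements both steps as a tested, fully seeded pipeline:

1. **Consensus discovery.** Four differential-expression channels — two
   on the count platform (Welch t on log2(CPM + 0.5); an exact
   permutation test on mean log2(CPM + 1) differences) and two on the
   intensity platform (a variance-shrunk pooled t; Welch t on
   quantile-normalized log2 intensities) — each give per-gene log2 fold
   change, p, and Benjamini–Hochberg q. Genes are ranked within each
   direction by |log2FC| per channel; the consensus statistic is the
   **mean fold-change rank** across the four channels, and a gene passes
   when **at least 3 of 4** channels call it significant at q < 0.05.
2. **Prognosis.** Cohort samples are assigned to molecular subtypes by
   10-nearest-neighbor matching against a labeled reference over shared
   (Entrez-matched, per-gene z-scored) signature genes. Marker
   expression is dichotomized at the cohort median; the package computes
   Kaplan–Meier curves, the log-rank test, and univariate plus
   subtype-adjusted Cox proportional-hazards models (Efron ties,
   Newton–Raphson, Wald inference), reporting the marker hazard ratio
   HR = exp(β) with 95% CI, each subtype contrast against a reference
   level, and an overall subtype block test.

Synthetic-data generators (`simulate_two_population_expression()`,
`simulate_survival_cohort()`) produce every input with known ground
truth, so the whole pipeline is exercisable and testable offline.
Auxiliary statistics used around such studies — ΔΔCT qPCR fold changes,
Welch t, Kruskal–Wallis with Dunn post-hoc, Grubbs outlier exclusion —
are included.

## Worked example

Discovery on a simulated two-population, two-platform experiment:

```r
library(crossmark)
sim <- simulate_two_population_expression(
  two_pop_sim_config(n_genes = 2000, n_marker_per_direction = 50, seed = 7))
channels <- lapply(c("A", "B", "C", "D"),
                   function(ch) run_channel(sim$channels[[ch]], ch))
mean_rank_aggregate(fold_change_ranks(channels))
#> consensus_table: 1442 genes, 94 pass (>= 3 of 4 channels q < 0.05)
#>    entrez_id direction  fc_A  fc_B  fc_C   fc_D       q_A     q_B       q_C
#> 1     100040      pop1 9.949 9.874 11.55 10.978 9.782e-05 0.05008 7.543e-10
#> 2     100048      pop1 9.810 9.723 11.30 10.293 1.204e-04 0.05008 6.629e-10
#> ...
```

The top rows are planted markers recovered with mean fold-change rank
1.25, 2.25, …; their channel-B q-values sit at ~0.05 because an exact
permutation test at three replicates cannot go lower — consensus rests
on the other three channels (see the methods vignette).

Prognosis on a simulated 159-sample cohort (marker generated with a true
High-vs-Low hazard ratio of 1.57):

```r
coh <- simulate_survival_cohort(cohort_sim_config(seed = 3))
assign <- assign_subtypes(coh$expression, coh$reference, k = 10)
mean(assign$subtype == coh$truth$subtype[assign$sample])
#> [1] 1

marker <- coh$expression$values["50848", ]
uni <- univariate_marker_analysis(coh$clinical$time, coh$clinical$event, marker)
uni$logrank$p                      #> 0.00904
uni$cox_dichotomized$hr[[1]]       #> 1.60

subtype_adjusted_analysis(coh$clinical$time, coh$clinical$event, marker,
                          assign$subtype[match(coh$clinical$sample, assign$sample)])
#> Subtype-adjusted Cox analysis (dichotomized marker, reference Mesenchymal)
#>                        term     hr ci_lower ci_upper        p unstable
#> 1       marker High vs. Low 1.8170   1.2599   2.6206 0.001392    FALSE
#> 2         Subtype (overall)     NA       NA       NA 0.011150    FALSE
#> 3 Classical vs. Mesenchymal 0.5445   0.3438   0.8623 0.009560    FALSE
#> 4    Neural vs. Mesenchymal 1.5394   0.8001   2.9619 0.196381    FALSE
#> 5 Proneural vs. Mesenchymal 0.7159   0.4509   1.1365 0.156414    FALSE
```

Read: every simulated tumor was assigned its generating subtype; high
marker expression roughly halves median survival (univariate HR 1.60,
log-rank p = 0.009), and the association persists after subtype
adjustment (HR 1.82, p = 0.0014) — one draw around the generating
HR of 1.57.

A staged command-line run over TSV artifacts is available through
`run_pipeline()` (stages `simulate`, `de`, `consensus`, `subtype`,
`survival`, `stats`, `report`) or the thin wrapper
`inst/scripts/crossmark.R`. GEO series-matrix files are read directly by
`read_expression()`, so the survival arm can be pointed at a real
expression/clinical pair when one is available.

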