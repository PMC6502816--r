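# mtfe — organelle fold-enrichment scoring for paired-fraction proteomics

Whole-lysate protein quantification misses a class of disease signal:
proteins that *relocate* between compartments (cytosol ↔ mitochondria)
while their total abundance barely moves. Given two matched log2
quantification matrices from the same samples — a total cellular lysate
`L` and a mitochondria-enriched fraction `M`, as produced downstream of
DIA/SWATH protein inference — the per-protein, per-sample
**fold-enrichment score** is

```
mtFE(p, s) = log2 M(p, s) − log2 L(p, s)
```

The score responds both to abundance change and to subcellular
redistribution, and it cancels any factor shared by the two fractions of a
sample (overall expression level, genotype effects on abundance, loading),
which makes it robust to confounders that dominate conventional abundance
analysis. `mtfe` implements the score and the complete biomarker-discovery
workflow around it, for any paired total-lysate / organelle-enriched
design:

* **io** — TSV matrix / metadata / GMT marker-panel readers and writers,
  fraction alignment, presence filtering (`read_quant_matrix`,
  `align_fractions`, `filter_by_presence`, `read_marker_panels_gmt`)
* **enrichment & QC** — `compute_mtfe`, marker-panel means
  (`panel_stats`), replicate CVs (`replicate_cv`), Spearman correlograms
  (`cross_dataset_correlation`), `qc_report`
* **differential** — per-protein one-way ANOVA + Tukey–Kramer post hoc
  tests with Benjamini–Hochberg adjustment (`anova_tukey`, `bh_adjust`),
  significant-set and Venn accounting (`significant_sets`, `set_overlap`),
  paired and pooled-variance t-tests for validation cohorts
* **clustering** — Manhattan-distance hierarchical clustering of samples
  with adjusted-Rand agreement against condition/genotype labels
  (`hclust_manhattan`, `partition_agreement`)
* **classification** — single-feature logistic-regression and Gaussian
  naive-Bayes ranking by cross-validated AUC, LR/NB consensus top-k,
  direct-value ROC validation (`rank_features`, `consensus_top_k`,
  `roc_auc`, `evaluate_markers`)
* **synthetic** — a ground-truth cohort generator implementing the
  ten-scenario condition-effect taxonomy, organelle fraction offsets,
  genotype confounding and calibrated replicate noise, plus recovery
  evaluation (`sim_config`, `generate_cohort`, `scenario_catalog`,
  `evaluate_recovery`)
* **cli** — a subcommand front-end (`mtfe_cli`; wrapper in
  `inst/cli/mtfe.R`) and a one-shot pipeline summary (`run_report`)

## Worked example

Simulate a discovery cohort (two conditions × two genotypes, 8/8/6/6
samples; a genotype confounder on 30% of proteins; 20 planted proteins per
condition-effect scenario) and run the whole pipeline:

```r
library(mtfe)

cfg    <- sim_config(n_proteins = 1000L, scenario_counts = c(0L, rep(20L, 9L)))
cohort <- generate_cohort(cfg, seed = 42)
report <- run_report(cohort$mito, cohort$lysate, cohort$meta, seed = 42)
print(report)
#> mtfe_report
#>   shared proteins: 1000 (0 mito-only, 0 lysate-only), samples: 28
#>   significant proteins (union of comparisons): lysate=362, mito=372, mtfe=142
#>   shared by all data types: 40
#>   clustering lysate ARI condition -0.04, ARI genotype 1.00
#>   clustering mito   ARI condition -0.04, ARI genotype 1.00
#>   clustering mtfe   ARI condition 1.00, ARI genotype -0.04
```

The report reads: lysate and mito abundances flag many proteins (most of
them genotype effects) and their sample clusterings follow *genotype*
perfectly (ARI 1.0); the enrichment score flags a smaller, more specific
set and clusters the same samples perfectly by *cancer state* — the
confounder cancels in the ratio.

Recovery against the generator's ground truth:

```r
rec <- evaluate_recovery(cohort$truth, report$differential)
subset(rec$rates, scenario %in% c(1, 2, 6))
#>  scenario           name   n lysate  mito  mtfe
#>         1           none 820  0.327 0.332 0.061
#>         2        up_both  20  1.000 1.000 0.100
#>         6 redist_to_mito  20  0.400 0.350 0.800
round(rec$type1, 3)
#> lysate   mito   mtfe
#>  0.056  0.044  0.047
```

Concordant abundance changes (`up_both`) are seen by both fractions but
not by the score (mtFE 0.10 ≈ its false-positive level, because the score
is the *difference* of two equal shifts). Pure redistribution
(`redist_to_mito`: moderate opposite shifts, ±1 technical noise sd per
fraction) is detected by the score with power 0.80 while each fraction
alone mostly misses it. The high `none`-scenario rates for lysate/mito are
genuine genotype detections, not false positives: type-I error on
fully-null proteins sits at α = 0.05 for all three data types.

## Command line

```sh
Rscript inst/cli/mtfe.R simulate --config cfg.json --seed 7 --out sim/
Rscript inst/cli/mtfe.R compute  --mito sim/mito.tsv --lysate sim/lysate.tsv \
                                 --meta sim/meta.tsv --out sim/mtfe.tsv
Rscript inst/cli/mtfe.R diff     --input sim/mtfe.tsv --meta sim/meta.tsv --out sim/diff.tsv
Rscript inst/cli/mtfe.R report   --mito sim/mito.tsv --lysate sim/lysate.tsv \
                                 --meta sim/meta.tsv --panels sim/classes.gmt --out sim/report/
```

Exit codes: 0 success, 2 validation error, 3 runtime error. Logs go to
stderr, results to files only; every summary embeds its resolved settings
and seed.

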