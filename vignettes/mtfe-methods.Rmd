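---
title: "Organelle fold-enrichment scoring: model, simulation world, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organelle fold-enrichment scoring: model, simulation world, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The score and what it measures

Tissue biomarker discovery usually compares protein abundances between case
and control groups in a whole-tissue lysate. But proteins act in subcellular
compartments, and disease frequently *relocates* proteins (e.g. between
cytosol and mitochondria) without changing their total abundance much. Such
redistribution is invisible to whole-lysate quantification.

Given two matched log2 quantification matrices from the same samples — a
total lysate and a mitochondria-enriched fraction obtained by differential
centrifugation — the per-protein, per-sample fold-enrichment score is

$$\mathrm{mtFE}_{ps} = \log_2 M_{ps} - \log_2 L_{ps},$$

the log2 ratio of the protein's abundance in the enriched fraction to its
abundance in the lysate. Two properties make this score useful:

1. **It is sensitive to redistribution.** If a condition moves a protein
   from cytosol into mitochondria, the lysate value barely changes (total
   protein is conserved) while the enriched-fraction value rises; the score
   moves by the *difference* of the two shifts, even when each shift alone
   is sub-threshold.
2. **It cancels shared variation.** Any multiplicative factor that affects
   both fractions of a sample equally — overall expression level of the
   protein in that animal, a genotype effect on abundance, loading
   differences — subtracts out. Confounders that dominate abundance-based
   clustering therefore largely disappear from the score.

Both properties are exact algebraic identities of the definition
(antisymmetry under fraction swap, shift equivariance), and the test suite
asserts them exactly.

A crude mitochondrial pellet is not pure: peroxisomes, ER and other
organelles co-purify to different degrees. A well-behaved enrichment score
should therefore *grade* marker panels — mitochondrial markers highest,
then peroxisome, ER, and progressively negative scores for cytosol, nucleus
and spliceosome. The package's panel QC (`panel_stats()`) checks exactly
this ordering, and the synthetic world encodes it as class offsets.

## The workflow around the score

`run_report()` chains the full discovery pipeline; each stage is exported
on its own:

* **Alignment and QC** — `align_fractions()` restricts both matrices to
  shared proteins/samples (lexicographic canonical order, so outputs are
  platform-independent), reporting fraction-exclusive proteins instead of
  imputing them. `replicate_cv()` (CVs on linear intensities),
  `panel_stats()` and `cross_dataset_correlation()` (Spearman, average
  ranks for ties) form the QC block.
* **Differential analysis** — per protein, a classical one-way
  fixed-effects ANOVA over the four `condition.genotype` groups, followed
  by Tukey HSD in the Tukey–Kramer form because group sizes differ (8/8/6/6
  in the emulated design). ANOVA p-values are BH-adjusted across proteins;
  a protein/comparison is *flagged* only when both the adjusted ANOVA p and
  the comparison's Tukey p fall below α.
* **Clustering** — samples are clustered on Manhattan distance of the
  row-z-scaled significant-protein submatrix (complete linkage by
  default), and the partition is scored against condition and genotype
  labels by the adjusted Rand index plus per-cluster purity.
* **Classifier ranking** — each protein is evaluated alone: logistic
  regression on the standardized feature and Gaussian naive Bayes, under
  stratified five-fold cross-validation; proteins are ranked by the mean of
  the two pooled out-of-fold AUCs; the LR/NB top-k consensus is the
  shortlist.
* **Validation** — candidate markers are re-tested in an independent
  cohort with a paired t-test (tumor vs matched adjacent tissue) or a
  pooled-variance two-sample t-test, and a ROC computed *directly on the
  marker's values* (no refitting), oriented so the case group maps to
  positive scores.

## The synthetic world

`sim_config()` / `generate_cohort()` emulate the *processed* output of a
DIA/SWATH two-fraction experiment, not the raw acquisition. The generative
model, per protein $p$ and sample $s$ (log2 scale throughout):

$$L_{ps} = \beta_p + b_{p,\mathrm{subj}(s)} + \gamma_p[\mathrm{KO}] +
  \delta^L_p[\mathrm{case}] + \varepsilon_{ps}$$
$$M_{ps} = \beta_p + o_{c(p)} + b_{p,\mathrm{subj}(s)} +
  \gamma^M_p[\mathrm{KO}] + \delta^M_p[\mathrm{case}] + \varepsilon'_{ps}$$

with independent technical noise $\varepsilon,\varepsilon'$ and a
between-subject biological deviation $b$ *shared by both fractions*, which
therefore cancels in the score. Defaults, with units and rationale:

| parameter | default | why |
|---|---|---|
| proteins | 2500 | the emulated discovery matrix has ~2500–2800 proteins |
| group sizes | 8/8/6/6 (condition × genotype) | the emulated cohort design |
| class offsets $o_c$ (log2) | mito 1.62, perox 0.82, ER 0.27, cytosol −1.03, nucleus −1.12, spliceosome −1.27 | the observed graded panel means of a crude mitochondrial pellet |
| class proportions | 0.24/0.03/0.10/0.38/0.17/0.08 | ~24% of quantified liver proteins are mitochondrial; remainder split realistically |
| baseline $\beta_p$ | N(14, 2²) log2 units | typical DIA protein intensity range |
| technical noise sd | 0.12 log2 | gives a linear replicate CV of ≈8%, inside the reported 6–11% band |
| biological sd $b$ | 0.30 log2 | ≈25% between-animal CV, typical for tissue proteomes; the term the score cancels |
| genotype effect $\gamma$ | 0.8 log2 on 30% of proteins | a liver-wide genetic perturbation that dominates abundance clustering |
| unequal-genotype minority | 5% of affected proteins hit mito only | small genuine compositional differences that leak into the score |
| main condition effect | 1.0 log2 | a conventional 2-fold abundance change |
| moderate (redistribution) effect | 1 technical noise sd | deliberately sub-threshold for lysate tests at these group sizes |
| missingness | 0 | processed matrices with requantification are essentially complete; raise to emulate sparser pipelines |

Condition effects follow the ten-scenario taxonomy of
`scenario_catalog()`: no change; concordant up/down (score unchanged);
one-fraction changes in each direction; pure redistribution in both
directions (positions 6 and 10); and a combined induction-plus-enrichment
pattern. The mapping from position to pattern is this package's own
declaration — the source taxonomy is graphical — and the per-scenario
effects are recorded per protein in the generated `truth` table, so
`evaluate_recovery()` can compute detection and false-positive rates
against ground truth.

**What the generator does not emulate**, hence what a green test does not
establish: proteins are independent (no co-regulation, no complexes), noise
is Gaussian and homoscedastic on log2 scale, missingness (when enabled) is
completely at random rather than intensity-dependent, and there are no
batch effects, peptide-level errors or normalization artifacts. Power and
type-I results transfer to real data only to the extent these assumptions
approximate it.

## Detection criteria and why `evaluate_recovery()` defaults to raw p

Recovery rates are the *operating characteristics* of the tests: the type-I
error of the raw ANOVA p must sit at α on null proteins, and power is
measured on the same scale. Multiplicity-corrected criteria (`"bh"`, and
`"flag"` = adjusted ANOVA ∧ Tukey) are available because they are what a
discovery analysis actually reports, but they depend on the cohort's signal
density and so are not comparable across configurations.

## Numerical choices

* **Degenerate variance.** Zero within-group variance with equal means
  gives F = 0, p = 1 (same for t-tests); zero variance with unequal means
  reports the numeric underflow floor and a `degenerate` flag rather than
  an error.
* **Sparse proteins.** A group with fewer than two observations for a
  protein is dropped from that protein's model; proteins retaining fewer
  than two groups are skipped and listed, never silently imputed.
* **Logistic fit.** No regularization on a single standardized feature;
  the linear predictor is capped at ±30 so separable folds return
  probabilities instead of overflowing. Naive Bayes uses a relative
  variance floor. A training fold with a constant feature yields 0.5
  probabilities and a flag.
* **Cross-validation.** Folds are stratified and deterministic given the
  seed; leave-one-out is seed-free. AUC pools out-of-fold probabilities
  into one curve (well-defined for LOO too) — but note that *pooled LOO*
  probabilities are strongly pessimistically biased under the null (each
  held-out sample's training set is depleted of its own class), which is
  one reason five-fold is the default for a 28-sample cohort.
* **Ties.** Spearman uses average ranks; AUC counts ties as ½; ranking
  ties break by average accuracy then protein id; equal-height cluster
  merges are made deterministic by processing columns in lexicographic
  order.
* **Missing-data distances.** Manhattan distances use pairwise-complete
  coordinates rescaled by the shared-coordinate count; a sample pair with
  no shared observed protein is an error, not a guess.
* **Seeding.** Internally seeded helpers save and restore the global RNG
  state, so calling them never perturbs the caller's random stream.

## Open design points, decided

* **Panel means are protein-first** (mean over samples, then over
  proteins), so heavily observed proteins do not dominate a panel; the
  alternative ordering differs only under missingness, and QC tolerances
  absorb the difference.
* **CVs are computed on linear intensities** (2^log2), the standard
  reproducibility metric in proteomics QC.
* **The multiple-testing procedure is BH** — conventional in proteomics —
  with Bonferroni/Holm as options; adjustment is applied across proteins
  to the ANOVA p only, not to Tukey p (the post hoc test already controls
  its family per protein).
* **Row scaling before clustering and complete linkage** follow the
  common centered-heat-map practice; both are recorded in the result and
  configurable.
* **The presence filter is optional** (`filter_by_presence()`, default
  threshold 10%) because processed matrices may already be complete.
* **Validation ROCs use raw marker values**, not model scores: no
  refitting is described for validation cohorts, and direct-value ROC is
  the assumption-light choice.

## Limitations

The score requires a paired fractionation per sample, doubling acquisition
effort; it inherits the impurity profile of the crude pellet (peroxisome
and ER co-enrichment are features of the score, not bugs, but must be kept
in mind when interpreting single proteins); proteins quantified in only one
fraction have no score and are surfaced separately; and the statistical
layer is per-protein fixed-effects — no mixed models, covariates or
peptide-level inference.
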