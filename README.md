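# endokit

Endotype discovery and quantitative scoring for pediatric critical-illness
transcriptomics.

Critically ill children admitted to intensive care share whole-blood immune
response patterns — *endotypes* — that cut across the clinical cause of
illness (sepsis, respiratory failure, cardiac disease, trauma). `endokit`
implements the complete analysis workflow for deriving and interpreting two
such endotypes from a genes × samples log2 expression matrix and a
per-sample clinical table:

1. **Preprocessing** — quantile normalization, probe collapsing (mean per
   gene), removal of genes with zero expression status, selection of the
   top-15% most variable genes.
2. **Endotype discovery** — cluster-number diagnostics (within-cluster sum
   of squares W_k, mean silhouette, gap statistic with the
   one-standard-error rule Gap(k) ≥ Gap(k+1) − s_{k+1}), Hartigan–Wong
   k-means with restarts, label convention *endotype 1 = smaller cluster*,
   and internal validation (stratified 2/3–1/3 split and nested
   cross-validation with an elastic-net logistic classifier).
3. **BASICq** — a continuous endotype score: the first nontrivial
   diffusion-map component (Gaussian kernel, median-distance bandwidth,
   α = 1 density normalization), oriented toward endotype 1 and min-max
   scaled to [0, 1].
4. **Interpretation** — empirical-Bayes moderated-t differential expression
   (scaled-F variance hierarchy with prior df d0 and prior variance s0²,
   BH adjustment), preranked GSEA (weighted running-sum ES, gene-label
   permutation null, sign-matched NES), and ν-SVR immune-cell deconvolution
   against a signature matrix with per-cell-type association to BASICq.
5. **Signature panels** — forward-selection PLS (greedy selection with
   rank-one deflation and Bonferroni stopping) down to 10 genes, then
   exhaustive 1/2/3-gene combination search with ROC/Youden-optimal
   thresholds.
6. **Clinical associations** — ventilator-free days at day 30
   (VFD-30 = 30 − ventilation days, 0 on death or ventilation ≥ 30 days),
   descriptive tables, rank-sum/Kruskal–Wallis comparisons, the adjusted
   linear model for VFD-30, and adjusted Cox proportional-hazards models
   (Breslow ties), with PIM2 entering on the logit scale.

Because the clinical half of real cohorts of this kind is confidential, the
package ships a **synthetic cohort generator** (`simulate_cohort()`) that
emulates the assumed statistical structure — two latent endotypes at
31.9%/68.1% prevalence, endotype-specific Dirichlet cell mixtures, planted
marker genes, scaled inverse-chi-square gene variances, age-group
confounding, a −3.7-day VFD-30 deficit in endotype 1 and 4.2% mortality —
with full ground truth, so every stage is testable as a recovery problem.
See `vignettes/endotyping-methods.Rmd` for the models, parameters and
design choices.

## Worked example

The analysis workflow lives in `analysis/01_simulate.R` …
`analysis/09_clinical_associations.R`; each script is a thin driver over
the package functions and writes its tables under `results/`. Running the
first four stages:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_endotypes.R
Rscript analysis/04_basicq.R
```

prints (seed 20251):

```
cohort: 382 children, 2000 genes
planted endotype 1: 128 (33.5%)
VFD-30 by endotype: 19.1 vs 23.2 days (marginal diff -4.08)
30-day mortality: 4.5%
2000 genes in -> 2000 after expression filter -> 300 features (top 15%)
gap statistic selects k = 2
endotype sizes: 128 / 254 (endotype 1 = smaller)
split accuracy 1.000 | nested-CV accuracy 1.000
adjusted Rand index vs planted endotypes: 1.000
BASICq median (IQR): endotype 1 0.92 (0.91-0.94), endotype 2 0.04 (0.03-0.05)
rank-sum p between endotypes: 2.52e-57
```

The gap statistic picks two clusters; k-means recovers the planted
endotypes exactly (adjusted Rand index 1.0); and the continuous BASICq
score separates them with endotype-1 children scoring near 1. The later
stages flag the planted marker genes (`05`), enrich the planted marker
sets while leaving all 20 decoy sets null (`06`), recover the planted
neutrophil-down / naive-CD4-up fraction directions against BASICq (`07`),
reduce the flagged genes to small panels with perfect in-sample AUROC
(`08`), and estimate the adjusted VFD-30 deficit of endotype 1 (`09`).

The same stages are available behind one orchestrator with logging and a
run manifest:

```r
library(endokit)
run_pipeline(default_config(out_dir = "results/run", seed = 1))
```

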