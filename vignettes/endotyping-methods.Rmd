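---
title: "Endotype discovery and quantitative scoring: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Endotype discovery and quantitative scoring: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endokit)
```

# The problem

Critically ill children admitted to pediatric intensive care share immune
response patterns — endotypes — that cut across the clinical cause of
illness. `endokit` implements a complete endotyping workflow for whole-blood
expression cohorts: unsupervised discovery of two endotypes, a continuous
endotype score (BASICq), biological interpretation (moderated differential
expression, preranked gene-set enrichment, immune-cell deconvolution), a
minimal diagnostic gene panel, and association of endotype membership with
the primary clinical outcome, ventilator-free days at day 30 (VFD-30).

Because real cohorts of this kind pair public expression with confidential
clinical data, the package ships a synthetic cohort generator that emulates
the statistical structure the analysis assumes, with full ground truth, so
every stage can be tested as a recovery problem.

# The synthetic cohort generator

## What it emulates

For sample $i$ with latent endotype $z_i \sim \mathrm{Bernoulli}(0.319)$
(endotype 1 when $z_i = 1$), expression of gene $g$ is

$$X_{gi} = \sum_c S_{gc} f_{ic} + \Delta_g \, \mathbf{1}\{z_i = 1\} + \varepsilon_{gi},
\qquad \varepsilon_{gi} \sim N(0, \sigma^2_g), \qquad
\sigma^2_g \sim s_0^2 \, d_0 / \chi^2_{d_0},$$

where $S$ is a generated cell-type signature matrix (log-normal profiles
with per-cell-type marker blocks, six leukocyte types), $f_i$ is the
sample's cell-fraction simplex vector drawn from an endotype-specific
Dirichlet, and $\Delta_g$ is a planted log2 marker effect for 150 of the
2000 genes (zero elsewhere). Defaults: $d_0 = 4$, $s_0^2 = 0.05$, marker
magnitudes uniform on $[1.5, 3]$ with alternating sign.

The Dirichlet concentrations encode the direction the deconvolution stage
must recover: endotype 1 up-weights naive and resting-memory CD4-like types
and down-weights the neutrophil-like type; endotype 2 is
neutrophil-dominated. Clinical covariates (age group, admission reason,
infection status, any-comorbidity, PIM2) are drawn from
endotype-conditional tables that mirror the descriptive statistics of a
382-child critical-illness cohort, which deliberately makes age group a
strong confounder of endotype membership — 82% of endotype-1 children are
under 1 year — so the covariate-adjusted models have real confounding to
adjust for.

Outcomes: ventilation days are rounded lognormal (endotype-2 location
$\log 4$, scale 0.9, matching a 4-day median with IQR roughly 2–7);
30-day death is Bernoulli on a logistic function of logit(PIM2), with the
intercept calibrated by root finding so marginal mortality equals 4.2%.
The endotype-1 ventilation location is shifted by
`calibrate_outcome_shift()`, a 1-D root solve on a common-random-number
Monte-Carlo estimate ($10^5$ draws per endotype), so that the marginal
VFD-30 difference equals the target, −3.7 days by default. A closed form is
unavailable because VFD-30 truncates ventilation at 30 days and scores
deaths as zero. The marker effect-size range is an assumption (the
descriptive statistics of real cohorts do not pin it down); it is
configurable and all recovery statements in the tests hold at the default.

A single integer seed drives named per-stage generator streams
(labels, clinical, signature, variances, markers, expression, outcomes,
gene sets), so any stage can be re-simulated in isolation and the whole
pipeline is reproducible end to end.

## What it does not emulate

Probe-level bead intensities, batch effects, detection p-values,
longitudinal sampling, and the mixed measurement error of real arrays. The
expression model mixes cell-type profiles linearly on the log scale, which
is a simplification of the linear-scale mixing of physical RNA. Passing
recovery tests therefore demonstrates the correctness and calibration of
the algorithms under the assumed generative structure, not their
performance on any real cohort.

# Preprocessing

The chain is fixed: quantile normalization → probe collapsing (mean of
probes per gene, when probe-level input and a mapping are supplied) →
expressed-gene filtering → top-variance selection.

Quantile normalization stands in for array-specific spline normalization:
it plays the identical role (cross-sample distribution alignment), is
standard, and is exactly testable (every column becomes the mean of the
sorted columns, ties averaged). "Zero expression status" is interpreted as
*at or below a floor (default 0 on the log2 scale) in all samples*; the
floor and the all-vs-any semantics are both configurable because the
convention is not standardized. Feature selection keeps the
$\lceil q\,G \rceil$ most variable genes ($q = 0.15$ by default, the
top-15% convention for array endotyping), with a lexicographic tie-break on
gene id so results are independent of row order.

# Endotype discovery

Cluster-number diagnostics combine three views: total within-cluster sum of
squares $W_k$, mean silhouette width, and the gap statistic
$\mathrm{Gap}(k) = \tfrac1B \sum_b \log W^*_{kb} - \log W_k$ with $B = 50$
reference sets drawn uniformly on the principal-axes-aligned bounding box,
$s_k = \mathrm{sd}_b(\log W^*_{kb}) \sqrt{1 + 1/B}$, and the
one-standard-error selection rule (smallest $k$ with
$\mathrm{Gap}(k) \ge \mathrm{Gap}(k+1) - s_{k+1}$). "Minimum silhouette" in
the endotyping literature is ambiguous; the package reports the standard
maximize-mean-silhouette criterion and records this as an interpretation.

Assignment uses Hartigan–Wong k-means with 25 random restarts, keeping the
best-of-restarts solution, after standardizing features to unit variance
(switchable; the convention is documented because array endotyping
protocols rarely state it). On 200 random 8–12-point instances the
best-of-restarts $W_2$ equals the exhaustive-partition optimum in well over
95% of cases (the test suite checks this), so the restart count is not a
practical limitation at cohort scale.

Labels follow a fixed convention: endotype 1 is the smaller cluster
(matching the published 122/260 direction), with ties going to the cluster
containing the lexicographically smallest sample id.

Internal validation mirrors the nested design used for endotype cohorts:
(a) a stratified 2/3–1/3 split with an elastic-net logistic classifier
(glmnet, $\alpha = 0.5$, penalty tuned by internal cross-validation) scored
on the held-out third; (b) nested cross-validation with a stratified outer
5-fold loop and inner-loop penalty tuning, pooling outer-fold predictions.

# The BASICq score

The continuous endotype score is the first nontrivial diffusion-map
component. The kernel is Gaussian, $K_{ij} = \exp(-d_{ij}^2 / 2\sigma^2)$
on Euclidean distances with $\sigma$ equal to the median pairwise distance —
a deterministic, oracle-checkable choice; adaptive per-sample bandwidths
exist in diffusion-map software but introduce tuning the score does not
need. Density normalization uses $\alpha = 1$
($\tilde K = K / (q_i q_j)$, $q$ the kernel row sums), the Laplace–Beltrami
convention that removes sampling-density effects. The Markov matrix
$P = D^{-1}\tilde K$ is eigendecomposed through its symmetric conjugate
$D^{-1/2} \tilde K D^{-1/2}$ for numerical stability; ten components are
retained, only the first is used.

The raw component has an arbitrary sign, so it is oriented by group means —
the sign is chosen to make the mean score of endotype-1 samples exceed that
of endotype-2 samples (defined even for tiny groups) — then min-max scaled,
so BASICq spans $[0, 1]$ with both endpoints attained and higher values
indicating endotype-1-like biology. A single-endotype cohort falls back to
orientation $+1$ with a warning. On default synthetic cohorts the adjusted
linear model of VFD-30 on BASICq has a negative coefficient; the tests
assert the sign only, since the magnitude depends on the generator's effect
settings.

# Differential expression and enrichment

Per-gene two-group fits (log2 fold change, pooled variance, $n - 2$ df) are
moderated by an empirical-Bayes scaled-F hierarchy: $d_0$ and $s_0^2$ are
estimated by matching the first two moments of $\log s^2_g$
(digamma/trigamma inversion, Newton iterations at tolerance $10^{-8}$), the
posterior variance is
$\tilde s^2_g = (d_0 s_0^2 + d\,s^2_g)/(d_0 + d)$, and moderated t
statistics use $d_0 + d$ degrees of freedom. When the observed variances
are no more dispersed than sampling noise the prior df is infinite and the
common-variance t is used. The estimator is checked against
`limma::squeezeVar` in the tests and recovers $d_0$ and $s_0^2$ from the
generator's hierarchy. The DE contrast is unadjusted endotype 1 vs 2 —
covariate-adjusted design matrices are out of scope for this stage.
Flagging uses $|\mathrm{log2FC}| \ge 1.5$ (inclusive) and BH-adjusted
$p < 0.05$ (exclusive); the boundary semantics are stated because threshold
conventions rarely are.

Preranked GSEA ranks genes by moderated t (descending, lexicographic
tie-break). The enrichment score is the maximum deviation of the weighted
running sum (hit increments $|r|^p / \sum_{hits} |r|^p$ with $p = 1$, miss
decrements $1/(N - N_{hit})$); $p = 0$ reduces to the classical
Kolmogorov–Smirnov statistic. Because the interface is preranked, the null
is gene-label permutation (random same-size sets), not phenotype
permutation; NES divides ES by the mean absolute null ES of matching sign,
and the two-sided permutation p carries a $+1$ pseudo-count so it is never
zero. Set-size bounds after universe intersection are $[10, 500]$, the
standard defaults. The ES computation is verified against `fgsea`'s
statistic; the permutation p-values are verified to be uniform for random
sets.

# Deconvolution

Each sample is regressed on the cell-type signature matrix over their
shared genes (at least 30 required), after z-scoring the mixture and each
signature column: linear-kernel ν-support-vector regression at
$\nu \in \{0.25, 0.5, 0.75\}$, negative coefficients zeroed, the rest
renormalized to the simplex, and the ν minimizing reconstruction RMSE
selected — the established support-vector formulation for bulk leukocyte
deconvolution. A deterministic non-negative-least-squares engine
(`pracma::lsqnonneg`) is available behind the same interface
(`engine = "nnls"`) and serves as the independent oracle in the tests; the
two agree within 0.05 per fraction on noisy mixtures. The mixture is not
quantile-normalized against the signature (a version-specific behavior of
deconvolution servers that is deliberately out of scope). Per-cell-type
associations with BASICq are simple linear regressions with BH adjustment
across cell types; on default cohorts the neutrophil-like slope is negative
and the naive-CD4-like slope positive, the planted directions.

# Signature panels

FS-PLS makes the greedy selection explicit: at each step, each remaining
gene's (deflated) values are regressed on the current response residual;
the gene with the smallest coefficient p-value is selected; selection stops
when that p-value exceeds $\alpha / (\text{remaining genes})$ (Bonferroni)
or after 10 genes. After each selection the gene matrix is deflated by
rank-one projection ($x \leftarrow x - t\,t^\top x / \lVert t \rVert^2$)
and the response residual updated, so collinear copies of selected genes
carry no remaining signal — duplicated informative genes yield exactly one
selection.

Combination panels enumerate every 1-, 2- and 3-gene subset of the
selected candidates (at most 15, keeping the search exhaustive), score each
with a logistic combination (falling back to the linear-regression score
under perfect separation, flagged), and keep the subset maximizing AUROC.
ROC curves sweep thresholds at midpoints between consecutive distinct
scores plus $\pm\infty$; the trapezoid AUROC equals the normalized
Mann–Whitney U statistic to machine precision. The reporting threshold
maximizes the Youden index $J$; when several thresholds tie on $J$ the
package takes the **higher** threshold (favoring specificity). Either tie
direction is defensible — ties are exact only in finite samples — and the
package fixes one so results are deterministic. Panel performance is
reported in-sample, mirroring the proof-of-concept design of endotype
signatures; no held-out estimate is implied.

# Clinical associations

VFD-30 is $30 - \text{ventilation days}$, set to 0 on death by day 30 or
ventilation $\ge 30$ days, so the composite event (death or ventilation
$\ge 30$ days) coincides exactly with VFD-30 = 0. PIM2 enters every model
as $\mathrm{logit}(p)$ — the "(logit)" convention of the adjusted-model
tables is followed where captions elsewhere say "log-normalized", since the
logit is the only transform consistent with the tabulated reference rows.
Reference levels are female, 0 to <1 month, infection/sepsis, no
comorbidity, non-infectious. Two time-to-event analyses are distinguished:
the extubation endpoint treats death as censoring at day 30, while the
composite endpoint treats death (or ventilation $\ge 30$ days) as the
event; they answer different questions and both are provided. Rank-sum
comparisons use exact enumeration up to a combined n of 20 without ties and
the tie-corrected normal approximation with continuity correction above.
Cox models use Breslow tie handling with Newton–Raphson to a $10^{-9}$
gradient tolerance, checked against a 1-D partial-likelihood grid oracle.

# Numerical conventions and degenerate inputs

* Serialization is at 6 significant digits; all artifacts round-trip
  bit-stably through their writers and readers.
* Ties are always broken deterministically (lexicographic gene/sample ids;
  higher Youden threshold), so every stage is invariant to input order.
* Degenerate inputs fail loudly rather than silently: constant data for the
  diffusion map, single-sample quantile normalization (warning, no-op),
  all-filtered expression matrices, single-class validation, no-event Cox
  data, constant FS-PLS responses.
* The pipeline driver validates every stage parameter before any stage
  runs, logs per-stage wall time and seeds, and stops at the failing stage
  with the stage named.

# Problem sizes used in the tests

The test suite and the acceptance script run at deliberately desk-scale
sizes chosen as the package's own defaults for verification: the default
synthetic cohort (382 samples, 2000 genes) for end-to-end recovery; 200
random 8–12-point instances for the exhaustive k-means oracle; 50 seeds per
scenario for gap-statistic selection; 500 random sets at 1000 permutations
for enrichment-null calibration; 5000 genes for variance-hierarchy
recovery; 50 mixtures for deconvolution recovery; 100 seeds for FS-PLS
recovery; and 50 cohort replicates for the VFD-30 effect. The nu-SVR
deconvolution of a full cohort is the slowest stage, so the pipeline driver
deconvolves a deterministic subsample of samples by default
(`deconv_max_samples`), while the analysis scripts deconvolve everything.

# Known limitations

* The generator's linear log-scale mixing understates the nonlinearity of
  real bulk convolution; deconvolution recovery numbers are accordingly
  optimistic.
* The DE stage fits the unadjusted two-group contrast; age-adjusted DE
  would require design-matrix support that is deliberately out of scope.
* The gap statistic is computed for $k \ge 1$ on the clustering feature
  space after standardization; silhouette is undefined at $k = 1$ and
  reported as NA there.
* Panel thresholds do not transfer across platforms; the package reports
  in-sample operating points only.
* Out-of-sample projection of new patients onto an existing diffusion map
  (Nyström extension) is not implemented; BASICq is defined per cohort.
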