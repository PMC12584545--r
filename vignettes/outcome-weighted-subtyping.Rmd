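---
title: "Outcome-weighted subtyping of multimodal radiomic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outcome-weighted subtyping of multimodal radiomic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Conventional clustering of tumor feature matrices — k-means or hierarchical
clustering on radiomic blocks such as contrast-enhanced T1 (CE-T1) and
T2FLAIR — optimizes geometric compactness, not clinical relevance. When most
features carry no prognostic information, the subtypes it finds often show no
survival difference. `owclust` implements outcome-weighted integrative
clustering: the survival outcome enters the metric itself, so that features
unrelated to survival are down-weighted before any clustering happens, and
the subtypes that emerge are prognostic by construction of the geometry, not
by post hoc selection.

## The model

For each feature block $X_m$ ($N$ samples $\times$ $p_m$ features,
z-scored), every feature $x_j$ is fit in a univariable Cox proportional
hazards model
$h(t \mid x_j) = h_0(t) \exp(\beta_j x_j)$,
and its weight is $w_j = |\hat\beta_j|$, the absolute log hazard ratio.
The baseline hazard cancels in the partial likelihood and is never
estimated. The weighted distance between samples $a$ and $b$ within a block
is

$$d_w(a, b) = \sqrt{(a-b)^\top W (a-b)}, \qquad W = \mathrm{diag}(w_1, \dots, w_{p_m}),$$

and the integrated distance averages the blocks with equal mixing weights,
$I_w = \sum_m \gamma_m D_m$ with $\gamma_m = 1/M$. Features with no outcome
relevance have $\hat\beta_j \approx 0$ and contribute almost nothing to the
metric; separating a modality's metric from the integration keeps one large
block from dominating another.

$I_w$ is clustered by k-means. Since k-means needs coordinates, the package
embeds $I_w$ by classical multidimensional scaling (double-center
$-\tfrac12 I_w \circ I_w$, eigendecompose, keep components with eigenvalue
above $10^{-8}$). When $I_w$ is Euclidean-embeddable the embedding is exact;
averaging Euclidean metrics generally leaves a small negative tail in the
spectrum, which is discarded — a warning is raised only when the discarded
energy exceeds 1% of the positive energy. k-means uses k-means++
initialization, 100 random restarts, and declares convergence when every
centroid moves less than $10^{-5}$ between iterations.

Because the survival outcome is used to build the metric, evaluating
survival separation on the same labels would overfit. The fit is therefore
cross-validated: in each of 3 folds, weights are estimated on the training
folds only, all samples are embedded under those weights, centroids are fit
on training rows, and held-out samples are assigned to the nearest centroid.
A round's labeling is the union of held-out assignments; 50 such rounds are
aligned to the first round by the label permutation maximizing agreement
(exact assignment search, $k \le 8$) and combined by per-sample majority
vote, ties toward the smaller label index. The per-sample agreement fraction
is reported as a stability diagnostic.

## Choosing the number of clusters

Two criteria are computed over a grid (default $k = 2,\dots,8$):

* **Clustering prediction index (CPI)** — repeated 50/50 train/test splits;
  the full weighted pipeline is fit on the training half, test samples are
  assigned to the nearest training centroid, and the criterion is the
  average over splits of $\sum_{x \in \text{test}} \lVert x - C(x)\rVert^2$.
  Smaller is better: the true cluster count generalizes best.
* **Gap statistic** — $\log$ pooled within-cluster dispersion
  ($\sum_r \frac{1}{2 n_r}\sum_{i,i' \in C_r} d^2_{ii'}$, which equals the
  within-cluster sum of squares) compared against its mean over $B = 50$
  reference datasets drawn uniformly over the bounding box of the embedding
  coordinates. Larger is better.

The selection rule is the maximum of the *sum* of the two criteria. A raw
prediction error and a raw gap live on incommensurable scales and point in
opposite directions, so the package negates the CPI and min–max rescales
both criteria to $[0, 1]$ over the grid before summing; ties go to the
smaller $k$. Raw values are always retained in the result so the selection
can be audited. This normalization is this package's design choice — summing
an error-scale CPI directly with a gap cannot be maximized meaningfully —
and the min–max form makes the selection invariant to affine rescaling of
either criterion, which the test suite asserts.

## Downstream evaluation

Subtypes are evaluated with the field's standard toolkit, wrapped behind a
uniform tabular interface:

* contingency tables by Pearson chi-square, with the Yates continuity
  correction for 2×2 tables (the convention the published baseline tables
  follow — the corrected statistic reproduces them, the uncorrected one does
  not);
* continuous variables by the tie-corrected Kruskal–Wallis H test, with
  degrees of freedom equal to groups − 1;
* Kaplan–Meier curves and the log-rank test after administrative censoring
  at a five-year cutoff (60 months by default, configurable): times beyond
  the cutoff are truncated and their events recoded as censored;
* a multivariable Cox model (Efron tie handling) adjusted for clinical
  covariates, reporting $\mathrm{HR} = e^B$ with
  $\mathrm{CI} = e^{B \pm 1.96\,SE}$, the Schoenfeld residuals test
  (Kaplan–Meier time transform by default) and events per variable.

Feature-level screening uses per-feature Kruskal–Wallis tests with
Benjamini–Hochberg adjustment within each modality. Enrichment follows a
Z-score rule: an entry is over-expressed when its cohort-level z-score is
at least 0.6 and under-expressed at or below −0.6 (the boundary is treated
inclusively and is configurable). Per subtype, feature and direction, an
upper-tail hypergeometric test asks whether flagged samples concentrate in
the subtype, BH-adjusted within each subtype × direction family; a feature
is *representative* of a subtype when the adjusted p is below 0.05, at
least 2/3 of the subtype is flagged, and less than 1/3 of every other
subtype is.

## Biomarker prediction

The binary marker (methylated MGMT promoter combined with mutant IDH,
versus all others) is predicted from differential features in two stages.
Stability selection repeats a stratified 80/20 split 100 times; each
training part is fit with L1-penalized logistic regression, the penalty
chosen by 10-fold cross-validated binomial deviance over 100 log-spaced
values spanning the data-driven $\lambda_{\max}$ down to $10^{-4}$ of it;
features selected in at least 10% of splits survive. The benchmark then
repeats stratified splits (1000 by default) across logistic regression,
random forest (500 trees), radial SVM with Platt-scaled probabilities, and
5-nearest-neighbours, scoring eight metrics per split (AUC by the
Mann–Whitney rank statistic; Se, Sp, ACC, Youden, F-measure, MCC and
G-means from the confusion matrix at probability 0.5). Splits whose test
part is single-class are excluded from summaries and counted. Per-split
AUCs are compared by one-way ANOVA followed by Dunnett many-to-one
comparisons against the best-mean model. The harness exposes a pluggable
classifier slot (`extra_models`) so additional models — e.g. kernel
partial-least-squares variants — can join the same protocol.

The operating point of 0.5 and the stratification of splits are this
package's choices: the protocol being mirrored does not state an operating
point, and unstratified 20% test sets of small cohorts frequently lose a
class entirely.

## Pathway activity

Expression preprocessing averages duplicate genes and samples, removes
genes and then samples with more than 30% zeros, and applies
$\log_2(x+1)$; the result is flagged so the transform is idempotent. Given
a pathway–gene weight matrix (with optional per-pair p-values, of which the
top 100 genes per pathway are retained), each sample's expression vector is
regressed on all weight columns jointly (OLS with intercept); the slope
t-values are the activity scores, positive meaning activation. Because the
design matrix is shared, the normal equations are solved once for all
samples. Between-subtype differences per pathway use a Welch t-test of the
per-sample scores (non-reference minus reference), BH-adjusted across
pathways; this contrast interpretation of a single reported t per pathway
is a documented choice, as is taking the gene universe from the supplied
weight input rather than a differential-expression pre-filter.

## The synthetic cohort generator

`simulate_cohort()` produces the structure the pipeline assumes and is the
basis of every recovery test: Gaussian feature blocks where only
`n_informative` columns per block are shifted between latent subtypes (by
`effect_size` standard deviations, with random per-feature sign);
exponential event times with per-sample rate
$\exp(\text{log-HR}_{g})/\text{baseline\_scale}$, which satisfies
proportional hazards exactly — the assumption the weighting stage relies
on; independent exponential censoring whose rate is found by bisection so
the expected censored fraction equals `censor_rate`; and a binary marker
generated as a subtype-linked Bernoulli flipped with probability
$1-\text{marker\_assoc}$, with five designated noise columns of the first
block additionally shifted by 1.5 SD in marker-positive samples so sparse
selection has a recoverable target.

Defaults describe the validation conditions used throughout the package:
200 samples, two blocks of 100 features with 20 informative each, effect
size 2, subtype log hazards (0, 1), baseline scale 60 months, and a
censored fraction of 0.65 — the realized censoring of the kind of cohort
the method targets (about one-third of patients deceased at analysis).
What the generator deliberately does not emulate: the heavy-tailed,
correlated, redundant distributions of real radiomic features, batch
effects between scanners, and informative censoring. Passing recovery
tests therefore demonstrates correctness of the machinery under the
model's own assumptions, not performance on real images.

## Numerical choices and degenerate inputs

* Univariate Cox fits that fail or separate get weight 0
  (`converged = FALSE`); finite estimates are capped at $|\beta| \le 10$ so
  one quasi-separating feature cannot dominate the metric.
* Zero-variance and ≥95%-zero columns are removed before standardization;
  standardization refuses zero-variance columns by name.
* An all-zero distance matrix (all samples coincident) embeds to a single
  zero coordinate rather than failing, so degenerate CPI cases evaluate
  to 0.
* Empty k-means clusters are re-seeded at the point farthest from its
  centroid; nearest-centroid ties go to the smaller cluster index.
* The CPI uses 20 splits of 50% and 25 k-means restarts, and the gap
  reference uses 10 restarts; the final consensus clustering keeps the
  full 100 restarts. These are stability/precision trade-offs chosen at
  the package's default problem sizes (a few hundred samples, a few
  hundred features) and are all configurable.
* Every stochastic routine takes an explicit seed, restores the caller's
  RNG state, and derives internal seeds additively, so whole-pipeline runs
  are reproducible bit for bit.

## Known limitations

Only continuous feature blocks are supported (no binary mutation-matrix
distances). The cluster count search is bounded at $k \le 8$ by the exact
permutation alignment. The Gap statistic's uniform-box reference is used
with its simplest null; PCA-aligned references are not implemented. The
Welch-contrast reading of pathway-level group differences is one of several
defensible interpretations. EPV and Schoenfeld diagnostics report model
reliability but the package deliberately stops short of competing-risks or
time-varying-covariate models.
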