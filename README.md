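# owclust

Outcome-weighted integrative clustering of multimodal radiomic feature
matrices, for discovering tumor phenotypic subtypes that differ in
survival — plus the downstream toolkit such a study needs: cluster-number
selection, subtype evaluation statistics, feature-enrichment rules, a
biomarker-prediction harness, and pathway-activity scoring.

`owclust` is aimed at biostatisticians and imaging researchers who have
per-patient feature blocks (for example CE-T1 and T2FLAIR radiomic
matrices), a right-censored survival outcome, and optionally molecular
labels (such as combined MGMT-promoter-methylation / IDH-mutation status)
or expression data. Conventional clustering of such blocks optimizes
geometry, not prognosis; here the outcome shapes the metric itself.

## The method

For each standardized feature $x_j$, a univariable Cox model
$h(t\mid x_j) = h_0(t)\,e^{\beta_j x_j}$ provides a weight
$w_j = |\hat\beta_j|$ (the absolute log hazard ratio). Distances within a
modality are outcome-weighted Euclidean,

$$d_w(a,b) = \sqrt{(a-b)^\top W (a-b)}, \qquad W = \mathrm{diag}(w_1,\dots,w_p),$$

modalities are averaged, $I_w = \sum_m \gamma_m D_m$ with
$\gamma_m = 1/M$, and $I_w$ is clustered by k-means (k-means++
initialization, 100 restarts, centroid-displacement tolerance $10^{-5}$)
after classical MDS embedding. Because survival is used to build the
metric, labels come from 3-fold cross-validation — feature weights are
estimated on training folds only, held-out samples are assigned to the
nearest training centroid — and 50 such rounds are combined by
majority-vote consensus after exact label alignment. The number of
clusters is chosen by the maximum of the (rescaled) sum of the clustering
prediction index and the gap statistic. See the methods vignette
(`vignettes/outcome-weighted-subtyping.Rmd`) for every modelling choice.

## Worked example

```r
library(owclust)

cohort <- simulate_cohort(n_samples = 200, seed = 1)  # built-in generator
cohort
#> <synthetic_cohort> 200 samples, 2 modalities (100 + 100 features), k_true = 2
#>   events: 75 (62% censored), marker positive: 99

blocks <- lapply(cohort$features, standardize_features)
fit <- survclust(blocks, cohort$survival, k = 2, n_rounds = 10, seed = 1)
fit
#> <survclust> k = 2, 200 samples, 10 rounds x 3 folds
#> subtype
#>   1   2
#> 102  98
#> mean agreement 1.000, WSS 1869.20

km_logrank(cohort$survival, tidy(fit)$consensus_label) |> glance()
#> # A tibble: 1 × 3
#>   statistic    df p_value
#>       <dbl> <int>   <dbl>
#> 1      10.8     1 0.00104
```

The two recovered subtypes split the cohort 102/98 with unanimous
consensus votes, and the five-year log-rank test separates their survival
(chi-square 10.8 on 1 df, p ≈ 0.001) — the planted subtype hazard ratio is
$e^1 \approx 2.7$. Contingency statistics follow the same interface; for a
2×2 table the Yates continuity correction is applied automatically:

```r
chi_square_test(matrix(c(35, 16, 44, 67), 2))
#> # A tibble: 1 × 4
#>   statistic    df p_value correction_applied
#>       <dbl> <int>   <dbl> <lgl>
#> 1      10.6     1 0.00112 TRUE
```

Every fitted object has `tidy()`, `glance()` and `autoplot()` methods;
`run_pipeline()` chains the stages (select k → cluster → evaluate →
enrich → stability-select → predict) and writes each stage's tables to an
output directory.

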