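# smdvariants

Standardized mean differences (SMDs) are supposed to make treatment effects
comparable across trials that used different rating scales. In practice the
SMD is not one estimator but a family: the between-group difference can be
taken at endpoint or as change from baseline, and it can be standardized by
the pooled baseline, change-score, or endpoint SD — and the change-score SD
is not even observable from aggregate data without assuming a pre-post
correlation *r*. `smdvariants` implements this whole family for
aggregate-data meta-analysis and quantifies how strongly the variants
diverge on the same set of trials.

The package is aimed at meta-analysts of randomized trials with continuous
outcomes (its defaults are tuned to depression-psychotherapy trial corpora,
but nothing in the machinery is specific to that field).

## What it computes

For each trial comparison with arm-level summaries
(n, mean, SD at baseline and endpoint), four Hedges-corrected SMD variants:

- **SMD_EP/EP** — endpoint mean difference / pooled endpoint SD,
  `g = J(m) (Ȳ_int − Ȳ_ctrl) / SD_EP`, `m = n_int + n_ctrl − 2`;
- **SMD_CS/BL**, **SMD_CS/CS**, **SMD_CS/EP** — difference in mean pre-post
  change standardized by the pooled baseline, change-score, or endpoint SD,
  where the arm-level change SD is reconstructed from an imputed pre-post
  correlation, `SD_CS,a = sqrt(SD_Y² + SD_X² − 2 r SD_Y SD_X)`.

Change-score variants are computed over a grid of assumed correlations
(default r ∈ {0.2, 0.4, 0.6, 0.8}, i.e. 13 effect sizes per comparison),
each with its sampling variance (unbiased estimator for EP/EP, a
delta-method form for CS/CS and CS/EP, the Morris pre-post-control form for
CS/BL).

Each (variant, r) cell is pooled under the models used in comparative
SMD-methods research: a three-level correlated-and-hierarchical-effects
(CHE) model with an assumed within-study sampling correlation (ρ = 0.6) and
CR2 cluster-robust errors with Satterthwaite degrees of freedom; REML
inverse-variance pooling with the Knapp-Hartung adjustment after
within-study pre-aggregation; best-case / worst-case effect selection; and
pooling after leave-one-out influence screening. Divergence between the
endpoint and each change-score variant is then quantified by a bivariate
random-effects model with unstructured between-study covariance **T**; the
divergence slope `β = T[EP,CS] / T[EP,EP]` should be exactly 1 when variants
agree, and a Wald test flags deviations. Study-level moderators of the
divergence (attrition, baseline imbalance, risk-of-bias domains, control
and treatment type) are screened by Δ-difference meta-regression.

A synthetic-trial generator with known ground truth (true SMD, between- and
within-study heterogeneity, pre-post correlation, multiple correlated
instruments, missing-summary patterns) makes every stage testable without
any external download.

## Worked example

```r
library(smdvariants)

cfg <- run_config(
  input  = simulation_config(k_studies = 60, theta = 0.5,
                             rho_prepost = 0.5, seed = 3),
  models = c("che", "aggregate")
)
bundle <- run_full_analysis(cfg)
bundle
#> SMD-divergence bundle: 60 studies, 111 comparisons, 1443 effects
#>   pooled table: 26 rows (che, aggregate)
#>   bivariate fits: 12; slopes 0.586..1.605

subset(bundle$pooled, variant %in% c("EP_EP", "CS_CS") & model == "che",
       select = c(variant, assumed_r, smd, se, i2, tau2_total, nnt))
#>   variant assumed_r   smd    se   i2   tau2_total  nnt
#>   EP_EP      NA      0.483 0.038 47.8  0.046       6.26
#>   CS_CS      0.2     0.425 0.027  0.0  0.000       7.23
#>   CS_CS      0.8     0.829 0.051 87.0  0.157       3.39
```

These trials were generated with one true effect (0.5) and a true pre-post
correlation of 0.5, yet the pooled change-score SMD swings from 0.42 to 0.83
purely with the imputed correlation: at r = 0.8 the reconstructed change SD
`sqrt(2 (1 − r)) σ` is small, inflating every study's SMD by ≈ 1/sqrt(0.4).
The endpoint variant sits in between and does not depend on r at all. The
bivariate slopes tell the same story:

```r
subset(bundle$bivariate, variant == "CS_CS",
       select = c(assumed_r, slope, slope_se, p_vs_one))
#>   assumed_r slope slope_se p_vs_one
#>   0.2       0.586 0.172    0.019
#>   0.4       0.719 0.161    0.087
#>   0.6       0.983 0.164    0.916
#>   0.8       1.605 0.213    0.006
```

True change-score effects diverge from true endpoint effects (slope ≠ 1)
whenever the assumed correlation is far from the data-generating one, and
`summarize_divergence(bundle)` condenses this into pooled-SMD ranges, deltas
to the endpoint variant, and flagged slopes.

To analyze a real aggregate-trial CSV instead, pass its path plus a column
mapping (`metapsy_mapping()` ships as the default for Metapsy-style
deposits; any layout can be described via `read_mapping_yaml()`), and the
same pipeline applies after `filter_eligible()` drops comparisons lacking
complete baseline/endpoint summaries.

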