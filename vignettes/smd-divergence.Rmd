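---
title: "How standardized mean difference variants diverge, and how smdvariants models it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How standardized mean difference variants diverge, and how smdvariants models it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smdvariants)
```

## The problem

A randomized trial with a continuous outcome measured at baseline (X) and
endpoint (Y) admits three classical estimates of the treatment effect: the
ANCOVA coefficient from regressing Y on treatment and X, the between-arm
difference in mean change Y − X, and the between-arm difference in endpoint
means. Under equal baseline/endpoint variances, equal arm sizes and a common
pre-post correlation ρ, the three are linked exactly:

θ̂_ANCOVA = ρ θ̂_CS + (1 − ρ) θ̂_EP,

and the standardizing SDs satisfy SD_EP² = SD_CS² / (2(1 − ρ)). The second
identity is the crux for meta-analysis: the same mean difference divided by
a change-score SD instead of an endpoint SD is inflated by 1/sqrt(2(1 − ρ))
when ρ > 0.5 and shrunk when ρ < 0.5. Aggregate-data meta-analysts rarely
observe ρ and must impute it, so a "standardized" effect can move by half
its magnitude purely through that choice. `smdvariants` computes the four
variants in use — SMD_EP/EP, SMD_CS/BL, SMD_CS/CS, SMD_CS/EP — over a
correlation grid, pools them, and estimates how far the implied true effects
drift apart.

## Effect sizes and their variances

All variants are bias-corrected with the exact Hedges factor
J(m) = Γ(m/2)/(sqrt(m/2) Γ((m−1)/2)), evaluated in log-gamma space, with
m = n_int + n_ctrl − 2 for every variant (the same degrees of freedom are
used for CS/BL; Morris's derivation shares this df). Arm-level change SDs
are reconstructed from the imputed correlation as
SD_CS,a = sqrt(SD_Y² + SD_X² − 2 r SD_Y SD_X); per-arm change SDs are pooled
across arms with the usual (n−1)-weighted formula, paralleling endpoint-SD
pooling. The same r is assumed in both arms. Sign convention: outcomes are
symptom scales where lower is better, so effects are oriented so that
positive SMDs favor the intervention; `higher_is_better = TRUE` flips this
per dataset.

Sampling variances:

- EP/EP: the unbiased estimator
  (n1+n2)/(n1 n2) + (1 − (m−2)/(m J(m)²)) g².
- CS/CS and CS/EP: the delta-method form
  J(m)² (2(1−r)(n1+n2)/(n1 n2) + g²/(2m)).
- CS/BL: the Morris pre-post-control form
  2 J(m)² (1−r) A (m/(m−2)) (1 + g²/(2(1−r)A)) − g², A = (n1+n2)/(n1 n2).
  Its g² coefficient is J(m)² m/(m−2) − 1 > 0, so the closed form is always
  positive; a defensive floor/error guard exists but is unreachable for
  valid inputs.

A caveat the test suite makes explicit: the delta-method form with the
2(1−r) factor is the true sampling variance of estimators whose denominator
is a raw-score SD (endpoint or baseline). Applied to CS/CS — whose
denominator is itself the change SD — it systematically over-/under-states
the Monte-Carlo sampling variance by roughly the factor 2(1−r) (about ±60%
at r = 0.2/0.8, exact at r = 0.5). We retain the form for CS/CS regardless,
because the comparative results this package exists to reproduce were
produced with exactly this convention, and because swapping it would change
the pooling weights and heterogeneity estimates of the CS/CS rows away from
the published analysis. The acceptance checks report the discrepancy rather
than hiding it; the corresponding Monte-Carlo expectations for EP/EP, CS/EP
and CS/BL hold within 3% at n = 50 per arm (the delta method degrades below
roughly n = 25, where its error can exceed 3%).

## Pooling models

- **CHE (three-level)**: effect sizes cluster in studies; within-study
  sampling covariances are fixed at ρ_s sqrt(v_i v_j) with ρ_s = 0.6 by
  default; REML estimates between-study (τ²_B) and within-study (τ²_W)
  components (via `metafor::rma.mv`). The pooled effect's SE uses a CR2
  cluster-robust estimator implemented in this package: adjustment matrices
  A_j = Φ_j^{1/2} (Φ_j^{1/2} S_j Φ_j^{1/2})^{-1/2} Φ_j^{1/2} with
  S_j = Φ_j − X_j B X_j' (the exact working-model residual covariance),
  which reduces to the familiar (1−h)^{-1/2} in the scalar case, plus
  Satterthwaite degrees of freedom from the full residual projection. When a
  cluster's S_j is numerically singular the estimator falls back to CR1
  scaling with a warning.
- **Aggregate**: within-study pre-aggregation (mean of effects; variance
  (1/p²) Σ_ij ρ_ij sqrt(v_i v_j), ρ_s = 0.6), then REML with Knapp-Hartung.
  We use the unmodified (non-truncated) KH scaling with a t(k−1) reference —
  matching the standard implementation — which means the KH interval is
  *usually* but not *always* wider than the Wald interval (about 92% of
  small meta-analyses in our simulations; the non-truncated form can
  shrink).
- **Best/worst case**: highest or lowest effect per study (ties broken by
  instrument label, lexically), then REML + KH.
- **Outlier-excluded**: pre-aggregate, then leave-one-out influence
  screening with the usual rules of thumb (|DFFITS| > 3 sqrt(1/(k−1)),
  Cook's D above the χ²₁ median, hat > 3/k, or a studentized deleted
  residual beyond 1.96 combined with any of those; thresholds
  configurable), then REML + KH on the survivors.

Every result row carries the pooled SMD, SE, 95% CI, I² (for CHE the
multilevel total I², with the Higgins-Thompson typical sampling variance),
τ² components and total, a 95% prediction interval (t with k−2 df on
sqrt(τ²_total + SE²)), and a number needed to treat. The NNT uses the
Furukawa-Leucht normal-response conversion
NNT = 1/(Φ(d + Φ⁻¹(CER)) − CER) with CER = 0.2 by default; the assumed
control event rate is exposed in the configuration because published tables
rarely state it, and d ≤ 0 yields a signed number-needed-to-harm rather
than an error unless requested.

## The bivariate divergence model

For each change-score variant and correlation, studies contributing both an
endpoint and a change-score estimate (pre-aggregated within study at
ρ_s = 0.6) enter a bivariate random-effects model: observed pair ~
N(μ + u_i, diag(v_EP, v_CS)), u_i ~ N(0, T) with T unstructured. The two
within-study variances are treated as conditionally independent (sampling
covariance 0), which keeps the model estimable from aggregate data. REML
estimation profiles the means by GLS and optimizes the three T parameters
as (log τ_EP, log τ_CS, atanh r_T), making positive semidefiniteness
automatic; 2×2 inverses are closed-form, and three starting points
(moment-based plus two fixed) guard against local optima.

The divergence slope is defined as β = T[EP,CS]/T[EP,EP] — the regression
of true change-score effects *on* true endpoint effects. The alternative
direction (T[EP,CS]/T[CS,CS], exposed in the diagnostics) cannot produce
the characteristic slope inflation at high r, because the change-score
variance then sits in the denominator; only the EP-denominator definition
reproduces the empirically observed pattern of slopes far above one at
r = 0.8, so it is the primary definition here. The slope's SE comes from
the delta method over the observed information of the T parameters
(finite-difference Hessian of the restricted likelihood); the test of
H0: β = 1 is a two-sided Wald test, which holds its nominal 5% size within
[0.02, 0.09] in our null simulations. If the information matrix is singular
at a boundary optimum (e.g. degenerate T), the p-value falls back to a
seeded parametric bootstrap (2,000 replicates by default).

Moderation of divergence is implemented as a Δ-difference meta-regression:
Δ_i = y_CS,i − y_EP,i with variance v_EP,i + v_CS,i, regressed on the
covariate with REML + KH (per-level pooled Δ and an omnibus test for
categorical covariates). A fully parameterized moderated bivariate
likelihood would be an alternative, but the Δ formulation is identifiable
from aggregate inputs, matches the way subgroup divergence tables are
reported, and requires no extra assumptions; this choice is deliberate and
documented rather than forced. Studies missing the covariate are dropped
with a reported count; below 80% coverage the analysis refuses to run.

## Synthetic data: what it emulates and what it does not

The generator draws, per study, a true effect θ_i = θ + N(0, τ_B²), per-arm
sample sizes log-normal around a median of 40 (floored at 10), baseline
scores N(24, 8²) — plausible for a BDI-like depression scale — and endpoint
scores via Y = α + βX + ε with β = ρ σ_Y/σ_X and Var(ε) = σ_Y²(1−ρ²), so
the pre-post correlation and endpoint variance are exact by construction.
Control arms improve by 4 scale points on average. Multiple instruments per
study (1–3 by default) are correlated re-measurements sharing a latent
subject factor with loading sqrt(0.6), so within-study effect estimates are
correlated at about 0.6 — deliberately matching the sampling correlation the
CHE model assumes — and each instrument carries its own effect shift
N(0, τ_W²). Missing-summary patterns (change-scores-only reporting, missing
baseline SDs) are injected at configurable rates to exercise the
eligibility filter. Study-level covariates (risk-of-bias count, attrition
via randomized-vs-analyzed counts, control/treatment type) are drawn
independently of effects.

Defaults (θ = 0.5, τ_B = 0.2, τ_W = 0.1, ρ = 0.5, k = 200) describe a
moderately heterogeneous corpus of mid-sized trials; they were fixed once as
realistic field values and are not tuned per analysis. What the generator
does **not** emulate: floor effects and entry-criterion truncation of
baseline scores (which compress baseline SDs in real trials and are one
substantive reason CS/BL runs high), non-normal outcomes, correlation
between study quality and effect size, and attrition that biases rather
than merely shrinks samples. Tests passing on this generator therefore
validate the estimators and models, not the claim that real corpora behave
this way.

## Numerical choices

- REML for the univariate and CHE models is delegated to metafor
  (`rma`/`rma.mv`, tolerance tightened to 1e-9); an independent grid-search
  restricted-likelihood maximizer in the test suite agrees to 1e-4 on
  random fixtures.
- The bivariate REML optimizer is `nlminb` with bounds log τ ∈ [log 1e-4,
  log 50], |atanh r_T| ≤ atanh(0.9999), relative tolerance 1e-12,
  three starts.
- Attrition is 1 − (Σ n_EP)/(Σ n_randomized) when randomized counts exist,
  else missing — the only definition computable from the available
  denominators.
- Eligibility requires both arms' n, baseline mean/SD and endpoint mean/SD;
  comparisons reporting only change summaries are dropped with reason
  `change_only`. The filter is idempotent, and when a trial has several
  control arms all contrasts are retained as given (splitting samples is
  not attempted; the drop report makes multiplicity visible).
- Missing-value tokens accepted in CSVs: empty cell, `NA`, `NaN` (any
  case); anything else non-numeric is surfaced in a load report rather
  than silently dropped.
- Determinism: one master seed with per-study substreams (study i uses
  seed (s·1000003 + 7919 i) mod 2³¹−19), so enlarging k never reshuffles
  earlier studies, and identical configurations produce byte-identical
  outputs.

## Problem sizes used in the checks

The automated checks run the blend identity on 50,000 subjects per arm, the
variant-ratio identity on 200-study meta-analyses, variance comparisons on
200,000 Monte-Carlo replicates per scenario, CHE recovery on 100 three-level
studies, and the slope test's size on 500 null meta-analyses of 60 studies —
sizes chosen so that Monte-Carlo error is well below each tolerance while
the whole suite stays quick on a single CPU.

## Known limitations

- The CS/CS sampling-variance convention (above) is faithful to the
  comparative literature but is not the estimator's true sampling variance
  away from r = 0.5.
- The CHE I² is reported as the multilevel total; a between-study-only I²
  would be smaller whenever τ²_W > 0.
- The bivariate model fixes the within-study sampling covariance of the
  paired estimates at zero; since both estimates share the same subjects
  this is an approximation, adopted for estimability from aggregate data.
- `read_trial_data` expects one row per comparison (wide, two-arm layout);
  long per-arm layouts need reshaping first.
- Replicating published corpus-level numbers requires the corresponding
  versioned database deposit; the shipped default mapping targets the 2023
  Metapsy-style column layout and is user-overridable for other versions.
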