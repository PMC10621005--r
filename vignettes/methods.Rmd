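---
title: "Immune subset proportions and CAD status: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune subset proportions and CAD status: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadimmune)
```

## The scientific setting

Mass-cytometry (CyTOF) immune profiling of peripheral blood yields, for
each patient, the proportions of dozens of gated immune cell subsets —
here 82 subsets nested in 11 major populations, each expressed either as a
percentage of total live cells or of its parent population. In a
CT-angiography-phenotyped cohort, patients divide into CAD+ (any coronary
stenosis, Gensini score > 0) and CAD− (Gensini score 0). The questions the
pipeline answers, in order:

1. Do the CAD groups differ on demographics, risk factors and medications?
2. Which subsets shift with CAD status, before and after adjusting for the
   age and sex imbalance between groups?
3. Do the shifts replicate in an independent validation cohort measured in
   a different batch?
4. For which patients is the immune profile informative about CAD status
   (classifiability), and does a clinical variable index that sub-cohort?
5. How well does a multivariate immune signature discriminate CAD in the
   selected sub-cohort, compared with and combined with age and sex?

## Group comparison tests

Categorical characteristics are compared between the CAD groups with the
Pearson chi-squared statistic on the 2×2 table, **without** Yates
continuity correction:

$$\chi^2 = \frac{N\,(ad - bc)^2}{(a+b)(c+d)(a+c)(b+d)}.$$

The uncorrected form is deliberate: it is the convention under which the
reference p-values this package reproduces (e.g. hypertension 0.013,
statin 0.024 on the shipped margins table) come out to the printed
decimals; the Yates-corrected statistic would give visibly different
values (hypertension 0.022). The default rule applies chi-squared to every
categorical variable because every reference categorical p-value —
including variables with small expected counts such as diabetes — matches
the uncorrected chi-squared. The conventional textbook rule (Fisher's
exact test whenever an expected cell is below 5) is retained as
`table1_test_rule = "paper_footnote"`; under it the diabetes-like table
routes to Fisher and returns p = 1.0 instead of 0.640, which
`build_table1()` reports honestly rather than hiding.

Fisher's exact test uses the probability-ordering two-sided convention
(sum of hypergeometric probabilities not exceeding the observed table's,
relative tolerance 1e-7), delegated to `stats::fisher.test` and verified
in the test suite against a full hypergeometric enumeration for N ≤ 200.
Continuous variables use the Wilcoxon rank-sum test with mid-ranks, exact
enumeration when the pooled sample is at most 12 without ties, otherwise
the tie-corrected normal approximation with continuity correction.

Because 2×2 tests depend only on the table margins, a published
characteristics table can be re-encoded as a patient-level dataset that
reproduces its p column exactly. `records_from_margins()` does this,
packing risk-factor flags round-robin among the non-SMuRFless patients of
each group so that the derived "no standard modifiable risk factor" count
also matches. One caveat is documented rather than resolved: the shipped
margins table implies 13 + 47 = 60 male patients by group, while the
source table's "All" column prints 57 (49%); the group counts are the ones
that reproduce the printed p-value (0.010), so they are taken as
authoritative.

## Per-subset logistic association

For each subset $k$ the pipeline fits
$\operatorname{logit} P(\text{CAD}) = \alpha + \beta_k x_k$ and, in the
adjusted model, adds age in years (untransformed) and a male indicator.
Predictors stay on the percent scale, so $e^{\beta_k}$ is the odds ratio
per one percentage-point increase — the effect measure used throughout.
Inference is Wald: CI $= \exp(\beta \pm 1.959964\,\mathrm{se})$, two-sided
normal p. Wald rather than profile-likelihood intervals are used because
they are the mainstream default and are symmetric on the log scale, which
is how such forest plots are conventionally drawn. No multiple-testing
correction is applied by default, matching the single-subset presentation
convention of this literature; Benjamini–Hochberg adjusted p-values are
available behind `bh = TRUE`. Zero-variance subsets are flagged
untestable, never silently dropped; suspected perfect separation
(standardised |coefficient| > 20) raises an error naming the predictor.

## Cross-cohort concordance

Replication is assessed on summary statistics rather than pooled data
because a between-experiment batch effect precludes direct comparison:
within each cohort, each subset's fold change of means
$\mathrm{FC} = \bar x_{\mathrm{CAD}+} / \bar x_{\mathrm{CAD}-}$ is
computed, and the discovery and validation fold-change vectors are
correlated (Pearson) over the discovery-significant subsets. The
correlation is computed on raw fold changes by default — that is the
quantity as plotted — with a log-scale option, since no transform is
canonical. The zero-correlation test uses
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ df; at the reference values
$r = 0.624$, $n = 18$ this gives $p = 0.0056$, printed as 0.006.
Heat-map clustering of the percent-of-total matrix uses Euclidean
distance with complete linkage (`hclust`), checked in the tests against a
brute-force $O(n^3)$ agglomeration via cophenetic distances.

## Classifiability

Patient-level classifiability asks *for whom* the immune profile is
informative. Under a stratified repeated 5-fold cross-validation with 20
repeats, each fold's model is built from the training split only: the top
18 of 82 features are screened by AUC, features are standardised with
training statistics, and an L1-penalised (lasso) logistic model is fitted
with its penalty chosen by an inner 5-fold deviance grid of 50 log-spaced
values spanning three decades below the data-driven maximum (smaller
penalties rarely win on deviance and often fail to converge on
near-separable folds). Held-out probabilities are classified at 0.5.
A patient's classifiability $c_i$ is the proportion of the 20 repeats in
which their held-out prediction was correct; $\bar c$ equals the overall
repeated-CV accuracy as an exact identity, which the tests assert.

Screening ranks features by $|AUC - 0.5|$ by default, because a feature
with AUC 0.2 is exactly as informative as one with 0.8; since the
convention could also be read as raw AUC, both are implemented
(`screen_rank_key`), and the default is a documented choice rather than a
claim about any particular prior analysis. Stratified folds are the
default because at prevalence 0.68 unstratified 5-fold splits of ~117
patients are occasionally single-class; when a non-stratified plan
produces such a fold it is re-drawn (at most 10 times, logged).

Modifier analysis regresses $c_i$ on each candidate clinical covariate by
simple per-covariate least squares (a joint model is available behind
`joint = TRUE`; the simple form is the default because per-variable
screening is the common reading of ranking risk factors by coefficient
significance). The age-based sub-cohort rule is boundary-inclusive
(age ≥ 55), and `scan_age_cutoff()` provides the threshold scan that
locates a step in classifiability; the pipeline then proceeds with the
age rule alone, treating other ranked modifiers (such as statin use,
which is itself strongly age-correlated) as descriptive.

## The SVM signature

On the age ≥ 55 sub-cohort a radial-kernel SVM is evaluated three ways:
repeated-CV ROC/AUC in discovery, train-on-all-discovery with evaluation
on validation, and a comparison of three feature sets (immune signature,
age + sex, combined) under byte-identical fold assignments so the AUCs are
comparable. Hyperparameters are the minimal-assumption defaults — cost 1,
kernel width $\gamma = 1/p$ on standardised features — both exposed in the
API; ROC scores are signed decision values (oriented on training data),
not calibrated probabilities, because ROC/AUC only needs a ranking score.
Per-fold ROCs are averaged vertically: mean TPR at a fixed FPR grid from 0
to 1 in steps of 0.01. "Averaged over folds" admits several readings;
vertical averaging is the documented choice here, and the mean AUC is
always the arithmetic mean of per-fold rank-formulation AUCs (an exact
identity in the report object). The fixed signature for
train-on-discovery/evaluate-on-validation is the set of subsets flagged
significant by the unadjusted discovery panel, not re-screened per fold.

The decision-boundary visualisation standardises the signature features
with discovery statistics, extracts the first two principal components by
SVD (signs fixed by making each component's largest-magnitude loading
positive), and projects the validation cohort with discovery loadings
only. A feed-forward network (2 inputs → 16 tanh units → linear outputs,
seeded initialisation, least-squares training) maps the PC grid back to
feature space, and the SVM classifies each mapped point. If the network
fails to reach 1.5× the residual error of the exact rank-2 linear inverse
it is replaced by that linear map with a warning — so on exactly rank-2
data the back-mapping is exact by construction. The boundary map is a
diagnostic visual, not a deployment model.

## The synthetic cohort generator

Because the underlying patient-level data are available only on request,
every downstream stage is exercised on a generator that emulates the
study's structure. Proportions follow a logit-normal model: for subset
$k$, $z_k \sim N(\mu_k + \delta_k\,\mathbb{1}[\text{CAD}] +
\gamma_k\,(\text{age}-61)/10 + b\,\mathbb{1}[\text{validation}],
\sigma_k^2)$ and $p_k = 100\,\operatorname{logit}^{-1}(z_k)$. The
logit-normal respects the [0, 100] bounds and makes planted effects
analytically tractable; nothing in the emulated study constrains the
distributional family, so this is a modelling choice. Defaults are the
study conditions: 117 + 58 patients, age ~ N(61, 12) truncated to
[30, 95], 49% male, CAD prevalence 0.68 with label log-odds slopes of
0.86 per decade of age and 1.03 for male sex (back-solved from the
reported group contrasts of 64 ± 10 vs 53 ± 13 years and 59% vs 34%
male), and a validation batch shift of 0.25 on the logit scale — large
enough that naive pooling is visibly biased while within-cohort fold-change
directions are preserved. The 18 headline subsets take their CAD−/CAD+
group means and SDs from the reported discovery-cohort results; baseline
$\mu_k, \sigma_k$ and shifts $\delta_k$ are back-solved by the delta
method, which lands the implied per-percent odds ratios in the reported
1.05–1.25 range for most subsets (small-denominator subsets such as
proliferating B cells imply larger per-percent ORs, as they do in the
reported data). The remaining 64 subsets are null fillers with
deterministic population-typical baselines; a third carry mild age trends.
Risk factors and medications are age-dependent Bernoulli draws near the
reported margins; Gensini scores are log-normal with median 7.5 in CAD+
and exactly 0 in CAD−. Major-population percent-of-total draws are
proportionally rescaled in the rare case their sum exceeds 100.

`planted_or()` converts generator truth into the per-percent odds ratio a
large-sample single-predictor logistic fit converges to, by Newton
iteration on the population score equations under quadrature over the
age × sex × label × noise distribution; `plant_target_or()` inverts it.
An optional `effect_age_knot` restricts the CAD shifts to patients at or
above a given age, planting the classifiability step that the sub-cohort
machinery is designed to find.

What the generator does **not** emulate: between-subset correlation
beyond the compositional bound (real gated subsets are strongly
correlated along the gating tree), measurement error from finite cell
counts, non-Gaussian logit-scale tails, and any dependence of the batch
effect on the subset. Passing tests therefore demonstrate that the
statistical machinery recovers what was planted under a clean generative
model at the study's scale — not that the study's biological conclusions
are correct, nor how the methods behave under correlated features.

## Problem sizes and numerical choices

The test suite and the acceptance script run simulations at the sizes the
corresponding claims are about: planted-OR recovery at n = 2000 over 100
replicates, null calibration of the differential panel at n = 117 over
200 replicates, the planted age-modifier study at the full pipeline scale
(n = 117, 82 features, 5-fold × 20 repeats) over 100 replicates, and
chance-level signature checks over 20 seeds. Smoke tests of the
end-to-end pipeline use reduced cohorts (60 + 30) and fewer CV repeats,
chosen to exercise every stage rather than to estimate rates. Logistic
fits converge at a relative log-likelihood change of 1e-10 (max 100
iterations); Fisher probability comparisons use relative tolerance 1e-7;
dendrogram tie-breaks follow `hclust` (ties have measure zero for
continuous data); all randomness flows from one integer seed through
`derive_seed()`, a 31-bit label hash, so stages are reproducible
independently of execution order.

## Known limitations

- The per-percent odds ratio is scale-dependent: subsets with small
  denominators produce large ORs for the same standardised effect.
- Classifiability scores take at most `repeats + 1` values and are noisy
  at 20 repeats; modifier regressions on them are screening tools, not
  confirmatory inference.
- The boundary map inherits the distortions of rank-2 projection and a
  small back-mapping network; it should be read qualitatively.
- With 18 features and ~88 sub-cohort patients the CV AUC of the
  signature has substantial fold-to-fold spread; the report stores all
  per-fold AUCs so users can inspect it.
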