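---
title: "Phenome-wide Mendelian randomization with a genetic risk score: models and design"
author: "mrphewas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenome-wide Mendelian randomization with a genetic risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrphewas)
```

## The problem and the design

Age at natural menopause (ANM) is associated observationally with bone,
cardiometabolic, hepatic and oncological outcomes, but those associations
are confounded. Mendelian randomization (MR) uses germline variants as
instruments: because alleles are assigned at conception, a weighted
genetic risk score (GRS) for ANM is (under the instrumental-variable
assumptions) unconfounded by postnatal exposures. A phenome-wide MR scan
(MR-pheWAS) tests that score against thousands of health-related traits at
once, then follows up the findings with formal causal-effect estimation.

`mrphewas` implements that whole chain — score construction, an automated
rule-based phenome scan, rank-based multiple-testing thresholds,
one-sample two-stage MR, and a two-sample summary-statistics estimator
suite — together with a synthetic-data generator that produces cohorts and
GWAS summary statistics with known ground truth. Individual-level biobank
data cannot be redistributed, so the generator is the package's test bed:
every statistical property claimed here is demonstrated on data it
produced.

## The genetic risk score

Each instrument SNP $j$ carries a published per-allele weight $w_j$ (years
of ANM change per effect allele), an effect-allele frequency, and a
DNA-damage-response (DDR) pathway annotation. The score counts
ANM-*decreasing* alleles: when $w_j > 0$ the counted allele is the other
allele with dosage $2 - d_{ij}$, and

$$s_i = \sum_j |w_j| \, d^{*}_{ij},$$

so one unit of score means one expected year of earlier menopause. This
orientation canonicalisation makes the score invariant to how each SNP's
alleles happen to be labelled (a property the tests assert directly).
Missing dosages are mean-imputed at twice the oriented allele frequency by
default (`missingPolicy = "complete"` propagates NA instead); the choice
follows standard allele-score practice.

Pruning (`pruneInstruments`) applies greedy selection in ascending
published p-value order — falling back to $|\beta|/\mathrm{se}$, then id
order, when p-values are absent — dropping any candidate within 10,000 kb
of a kept SNP on the same chromosome or with squared dosage correlation
$\ge 10^{-3}$ against any kept SNP. Both cut-offs are arguments: note that
with a finite reference sample the expected squared correlation between
two *independent* SNPs is about $1/n$, so the default $r^2 < 0.001$ is
only meaningful when dosage correlations are estimated from tens of
thousands of individuals; small fixtures should use a larger `r2Max`.

Instrument strength is summarised by the $R^2$ of the
exposure-on-score regression and the univariable F-statistic
$F = R^2 (n-2)/(1-R^2)$. A k-regressor form is available via
`nRegressors`; the two differ when the instrument enters as many separate
variants rather than one score, and published F values do not always state
which form was used, so the package exposes both rather than calibrating
to any printed value.

## The phenome scan

`runPhenomeScan` resolves each field's type, preprocesses, and routes:

| resolved type | preprocessing | model | reported p |
|---|---|---|---|
| continuous | inverse-normal rank transform | linear | Wald |
| binary | — | logistic | Wald |
| ordered categorical | — | proportional-odds | Wald |
| unordered categorical | — | multinomial | likelihood ratio |

with every model adjusted for age and the first ten genetic principal
components. Sex is never a covariate: scans are run within one sex by
design, which is what makes the male scan a negative control.

Auto-typing uses the rule table: two distinct observed values are binary;
numeric columns with at least 20 distinct values are continuous; numeric
columns with 3–19 distinct values are ordered categorical; non-numeric
columns with three or more levels are unordered. The 20-value cut-off is
the reimplemented rule engine's convention and is configurable
(`continuousMin`); declared types pass through after validation.

The inverse-normal rank transform maps the value with (average) rank $r$
among $m$ non-missing values to $\Phi^{-1}((r - 0.5)/m)$. It guarantees
the linear branch's p-values are invariant to any strictly monotone
transformation of the outcome — so the scan cannot be driven by skewness
or outliers in raw units.

Multinomial fields need a single per-field p-value for the threshold step;
the package uses the likelihood-ratio test against the score-free model
and reports the largest-magnitude category contrast as the estimate. The
proportional-odds and multinomial fits retry once with a rescaled score on
failure; still-failing fields are reported with `converged = FALSE` and
excluded from thresholds. Binary fields with fewer than ten cases in the
rarer class are skipped (a separation guard, logged). Nothing is dropped
silently: results plus logged skips always account for every input field.

## Multiple-testing thresholds

With $n$ tests, the Bonferroni threshold is $0.05/n$. The rank-based 5%
FDR threshold sorts p-values ascending and finds the largest rank $k$ with
$p_{(k)} < 0.05\,k/n$ (the step-up rule); the threshold is
$P_t = 0.05\,k/n$ and the significant set is $\{p \le P_t\}$. The strict
inequality in the rank rule with closed membership at $P_t$ mirrors how
such thresholds are conventionally reported; `strictMembership` flips the
membership rule for sensitivity. At the published test count of 18,961
these formulas give $2.64\times10^{-6}$ and, at rank 221,
$5.83\times10^{-4}$ — reproduced (to the printed three significant
figures) by `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`.

`qqData` pairs the $i$-th smallest observed $-\log_{10} p$ with the
uniform expectation $-\log_{10}((i-0.5)/n)$ and floors exact zeros at the
smallest positive double.

## One-sample MR

Two-stage estimation as described for individual-level data: first a
linear regression of the exposure on the score plus covariates (the
fitted values are the "genetically predicted" exposure), then a linear or
logistic regression of the outcome on that prediction plus the same
covariates. For continuous outcomes the point estimate equals the ratio of
the covariate-adjusted reduced-form and first-stage coefficients — an
algebraic identity the tests assert to eight digits. Reported effects are
per year *decrease* of ANM by default (matching how the replication
analyses present effects); `sign = "increase"` reverses the convention.

Two deliberate fidelity choices, both flagged in the output rather than
"fixed": second-stage standard errors are *not* adjusted for first-stage
uncertainty (the plain two-step regression described), and the logistic
second stage is used for binary outcomes despite the non-collapsibility of
the odds ratio. The latter means the logistic two-stage estimand is mildly
attenuated relative to the conditional log-odds that generated a synthetic
outcome; the shipped tests therefore hold the linear branch to a strict
Monte-Carlo unbiasedness check but assess the logistic branch on the
estimator's own SE scale.

## Two-sample MR

`harmonizeSumstats` aligns outcome to exposure effect alleles by id:
swapped labels flip the outcome beta and complement its frequency; strand
complements resolve through the A/T–C/G map; palindromic SNPs with
effect-allele frequency in (0.42, 0.58) in either source are excluded as
strand-unresolvable, outside that band they are oriented by frequency
agreement; anything irreconcilable is excluded with a reason code.

The estimators, all operating on harmonized $(\hat\beta_{Xj},
\hat\beta_{Yj})$ pairs:

* **IVW** — weighted regression through the origin,
  $\hat\theta = \sum w_j \beta_{Xj}\beta_{Yj} / \sum w_j \beta_{Xj}^2$
  with $w_j = 1/\mathrm{se}_{Yj}^2$. The default SE is multiplicative
  random effects: the fixed-effect SE scaled by
  $\sqrt{\max(1, Q/(k-1))}$ with $Q$ Cochran's statistic, so
  heterogeneity widens intervals but can never narrow them below the
  fixed-effect SE. One instrument delegates to the Wald ratio.
* **MR-Egger** — the same weighted regression with a free intercept,
  after orienting all $\beta_{Xj} \ge 0$. The intercept estimates the
  mean direct (pleiotropic) effect under the InSIDE assumption; the
  slope remains consistent for the causal effect when directional
  pleiotropy is present but independent of instrument strength. The same
  random-effects SE scaling applies (floored at 1), and constraining the
  intercept to zero reproduces fixed-effect IVW exactly.
* **Weighted median** — per-SNP ratios $\beta_{Yj}/\beta_{Xj}$ ordered
  ascending with inverse-variance weights from the delta-method SE
  $\mathrm{se}_{Yj}/|\beta_{Xj}|$; the estimate interpolates the ratio at
  standardized cumulative weight one half (midpoint convention), and is
  consistent when valid instruments carry at least half the weight.
* **Simple / weighted mode** — Gaussian-kernel density over the ratios
  with bandwidth $\varphi \cdot 0.9 \min(\mathrm{sd},
  \mathrm{mad})\,k^{-1/5}$ (modified Silverman; $\varphi = 1$ by default)
  evaluated on a fixed 2048-point grid spanning the ratio range plus
  three bandwidths; the estimate is the density argmax.

Median and mode SEs come from a seeded parametric bootstrap (default 1000
replicates) resampling each $\hat\beta_{Xj}, \hat\beta_{Yj}$ from its SE.
IVW and Egger use analytic SEs with normal inference. All estimators are
equivariant under joint per-SNP sign flips (allele relabelling), and under
no pleiotropy with strong instruments they agree on the planted effect —
the concordance that motivates running the whole suite as a sensitivity
analysis.

The reporting convention is per year *decrease* of the exposure,
implemented by negating $\beta_X$ once before estimation so every
estimator inherits it identically.

## What the generator emulates — and what it does not

`simulateCohort` draws Hardy–Weinberg genotypes at configured frequencies
(optionally with constant within-block latent-factor correlation, solely
to exercise pruning), a latent standard-normal confounder, and an exposure

$$X_i = \mu + \textstyle\sum_j w_j (g_{ij} - 2p_j) + c\,U_i +
\varepsilon_i,$$

with the weight magnitudes scaled so the true score explains exactly
`targetR2` of the marginal variance, and the noise variance solved so the
marginal mean and SD equal `exposureMean` and `exposureSd`. The defaults —
mean 50, SD 5 years, 7.3% variance explained — are the study conditions
the analysis assumes. Phenome fields are generated per descriptor:
linear for continuous traits, a logistic link with the intercept solved by
root-finding to hit a target prevalence for binary traits, a thresholded
latent scale for ordered traits, and a multinomial logit with
category-specific slopes for unordered traits. Per-SNP direct
(pleiotropic) effects are drawn mean-zero (balanced) or with nonzero mean
(directional) and act on the exposure-*increasing* oriented dosage, so a
directional mean creates a coherent score–outcome channel — exactly the
shared-aging scenario the male negative control is designed to catch. The
male generator shares the instrument panel and the per-SNP direct effects
(their stream is keyed by field, not by sex) but has no exposure variable
and no exposure-mediated path.

Summary statistics are emitted with SEs consistent with the stated GWAS
sample sizes and allele frequencies
($\mathrm{se} = \sigma/\sqrt{2p(1-p)n}$), after orienting instruments so
all true SNP-exposure effects are positive; direct effects are drawn on
that allele, which is what makes the Egger intercept identify their mean.

Not emulated: realistic LD maps, imputation dosage uncertainty,
relatedness, X-chromosome inheritance, selection bias, and the
multi-visit field structure of real biobank phenomes. Passing tests
demonstrate the *statistical machinery* — calibration under the null,
parameter recovery, deconfounding, negative-control behaviour — not
robustness to those data pathologies.

Randomness derives from one integer seed through labelled substreams (a
polynomial hash of the component label), so partial re-runs reproduce and
the two sexes share exactly the per-SNP quantities they should share.

## Numerical choices and problem sizes

Degenerate inputs are policy, not accidents: constant fields and all-tied
transforms are skipped with a logged reason; a zero-variance score raises
a named weak-instrument error; $\beta_X = 0$ SNPs are excluded from ratio
estimators with a message; zero p-values are floored at the smallest
positive double; an exact fit reports $F = +\infty$. Ties in the rank
transform take average ranks; ties in the FDR rule share the decision of
the last tied index.

The shipped test suite runs its heavier experiments at sizes chosen to
make the statistical assertions sharp while keeping the suite quick: a
1,000-field all-null phenome at n = 5,000 for calibration (the p < 0.05
rate must sit within three binomial SEs of 0.05 and the empirical CDF
inside a 1% Kolmogorov–Smirnov band), 50 replicates at n = 4,000 for
one-sample recovery, 200 summary-statistics replicates for IVW coverage,
and n = 8,000 cohorts for the sex comparison. The acceptance script uses
n = 20,000 with the full 267-SNP panel for the instrument-strength
quantities and n = 50,000 for the odds-ratio-scale recovery.

## Known limitations

* First-stage uncertainty is not propagated into one-sample SEs
  (documented fidelity choice); with F-statistics in the hundreds the
  effect is negligible, but the flag travels with every estimate.
* The published F-statistic convention for a score instrument is
  ambiguous; both closed forms are provided, neither is privileged.
* The FDR rule is the rank-based step-up threshold as specified — not
  permutation-based FDR or q-values.
* The mode estimators' bandwidth rule (and hence their point estimates)
  follows the modified-Silverman convention with $\varphi$ configurable;
  mode estimates are intrinsically bandwidth-dependent.
* Nonlinear exposure-outcome relationships are out of scope throughout.
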