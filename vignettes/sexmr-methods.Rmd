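---
title: "Methods: sex-specific two-sample Mendelian randomization with sexmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-specific two-sample Mendelian randomization with sexmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexmr)
```

## The model and its assumptions

Mendelian randomization treats genetic variants as instrumental
variables for an exposure. A variant is a valid instrument when it (i)
robustly predicts the exposure, (ii) shares no common cause with the
outcome, and (iii) affects the outcome only through the exposure.
`sexmr` implements the two-sample design: per-SNP associations with the
exposure come from one GWAS and per-SNP associations with the outcome
from a second, non-overlapping sample, so only summary statistics are
needed and weak-instrument bias is towards the null rather than towards
the confounded observational estimate.

For harmonized SNP $j$, the Wald ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the causal
effect on the outcome scale (log odds ratio for binary outcomes) per
unit of exposure. Its default standard error is the first-order delta
approximation $\sigma_{Yj}/|\hat\beta_{Xj}|$, which ignores
exposure-side sampling error. This matches the
$\sigma_{Yj}^{-2}$ weighting convention of the inverse-variance
weighted (IVW) estimator; a second-order SE that adds
$\hat\beta_{Yj}^2\sigma_{Xj}^2/\hat\beta_{Xj}^4$ is available via
`wald_ratio(..., second_order = TRUE)`. With the package's default
validation design (binary outcome, case fraction ~0.04), the
outcome-side variance dominates and the first-order SE is accurate;
residual under-statement is absorbed by the multiplicative
random-effects scale described next.

## Estimators

**IVW with multiplicative random effects** (`mr_ivw()`) is weighted
least squares of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through the
origin. The fixed-effect SE $(\sum_j \hat\beta_{Xj}^2\sigma_{Yj}^{-2})^{-1/2}$
is multiplied by $\varphi = \max\{1, \sqrt{\mathrm{RSS}/(J-1)}\}$ where
RSS is the weighted residual sum of squares. The floor at 1 means
between-SNP over-dispersion (heterogeneous ratios, e.g. from balanced
pleiotropy) widens the interval while chance under-dispersion never
narrows it. A single-SNP set falls back to the fixed model with a
warning; it then equals the Wald ratio exactly.

**Weighted median** (`mr_weighted_median()`): ratios are sorted, and
with normalized weights $w'_j$ the cumulative midpoints
$s_j = \sum_{k\le j} w'_k - w'_j/2$ are linearly interpolated at
$s = 0.5$. The estimator is consistent as long as valid instruments
carry more than half the weight. Its SE is a parametric bootstrap:
exposure and outcome betas are redrawn from per-SNP normal
distributions, ratios and weights recomputed, and the SD across
replicates taken (default `n_boot = 1000`; below 100 a warning flags
unstable SEs).

**Mode-based estimate** (`mr_mode()`): the argmax of the weighted
normal-kernel density of the ratios, located on a 512-point grid and
refined by golden-section search between the neighbouring grid points.
The bandwidth is the modified Silverman rule
$h = \varphi_{bw}\cdot 0.9\,\min(\mathrm{sd},\mathrm{mad})\,J^{-1/5}$
(with the normal-consistent MAD; when the MAD degenerates to zero the
SD is used, and identical ratios return the common value). Weights are
the simple inverse-variance ratio weights and $\varphi_{bw} = 1$ by
default, both configurable. The bootstrap SE deliberately includes the
kernel-smoothing variability, which makes the mode-based intervals
conservative; the test suite therefore checks its null rejection rate
is not anticonservative rather than exactly 5%.

**MR-PRESSO** (`mr_presso()`): for each SNP the IVW slope is re-fitted
without it and the observed global statistic is the weighted RSS of
each SNP's outcome beta around its leave-one-out prediction. The null
distribution comes from `n_sim` parametric draws
($\beta^*_{Xj}\sim N(\hat\beta_{Xj},\sigma_{Xj})$,
$\beta^*_{Yj}\sim N(\hat\theta_{(-j)}\hat\beta_{Xj},\sigma_{Yj})$) with
the statistic recomputed identically on each draw. Empirical p-values
use the add-one correction $(1+\#\{\ge\})/(n_{sim}+1)$ so they are
never zero. Per-SNP squared residuals are compared with their own
simulated distributions and Bonferroni-adjusted by $J$; flagged SNPs
are removed and IVW re-fitted for the corrected estimate. The default
`n_sim = 10000` is sized for interactive use; raise it to 100,000 for
publication-grade global p-values. The distortion between raw and
corrected estimates is reported as their relative difference without
an accompanying test. MR-Egger is deliberately not provided: with the
small instrument sets this package targets it is more sensitive to
outliers and less efficient than the three robust methods above.

All stochastic estimators take one integer seed per invocation, record
it in the result, and restore the caller's RNG state.

## Instrument selection

`select_instruments()` composes three filters in a fixed order:

1. **LD pruning** (`ld_filter()`): greedy clumping on a user-supplied
   r² matrix — candidates ordered by ascending exposure p-value (ties
   broken lexicographically), kept iff r² < 0.01 (configurable)
   against every already-kept SNP. The r² values are an input because
   reference-panel LD estimation is a different tool's job.
2. **Confounder screen** (`confounder_screen()`): a SNP is dropped iff
   any screened confounder association has p strictly below the
   Bonferroni threshold `alpha / n_phenotypes` (0.05/2000 = 2.5e-5 by
   default); the recorded reason names the confounder with the
   smallest p. The boundary is strict because the criterion is stated
   as "p < threshold"; a p exactly at the threshold survives.
   Unscreened SNPs are kept and logged rather than silently trusted.
3. **Curated exclusions** (`apply_curated_exclusions()`): a
   user-supplied list standing in for lookups in curated
   genotype-phenotype databases (e.g., a known obesity locus).

Every dropped SNP carries exactly one reason, and reports are
bit-reproducible. The bundled instrument tables reproduce the
published main sets (7 insulin SNPs, 9 BMI-adjusted SNPs) and the
men-only sensitivity drop; the package keeps one published tension
as-is: rs10195252 is dropped from the IVW instrument sets by the
alcohol screen yet retained in the 10-SNP insulin-resistance score,
because the score is used as previously validated. The orientation and
selection logs make that choice auditable rather than resolving it.

## Harmonization

Outcome associations are aligned to the exposure's effect alleles,
considering the outcome pair as-is, swapped, strand-complemented, and
both; sign and allele-frequency flips are applied on swaps. Pairs
fitting none of the four orientations are dropped with a logged
reason. Palindromic (A/T, C/G) pairs are strand-ambiguous: by default
they are dropped when either effect-allele frequency is missing or
lies in [0.42, 0.58], and otherwise oriented so the frequencies agree;
a strict drop policy is available. When a source prints no second
allele (as instrument tables often do), the effect-allele match is
trusted and the record logged `assumed_forward`. Published odds ratios
enter on the log scale via `se_from_ci()`, which uses the exact normal
quantile (1.959964 at 95%, never the rounded 1.96) and warns when the
point estimate sits off the CI midpoint by more than 5% of the SE —
the signature of rounded source values.

## Meta-analysis, sex contrasts, power

Fixed-effect inverse-variance pooling (`meta_fixed()`, backed by
`metafor`) is used across cohorts; with two studies a random-effects
variance is not meaningfully estimable, and the fixed-effect
reproduction of the published pooled rows confirms that choice. The
sex contrast is the one-tailed z-test
$z = (b_m - b_w)/\sqrt{se_m^2 + se_w^2}$ with $p = 1-\Phi(z)$ under
the directional hypothesis that the male effect is larger; a
two-sided option exists.

Binary-outcome power uses
$\Phi(\sqrt{N R^2 K(1-K)}\,|\log OR| - z_{1-\alpha/2})$ with case
fraction $K$; `detectable_or_binary()` is its exact inverse. The
formula was validated against all ten published minimal detectable
odds ratios before being frozen: eight agree at the printed 2-decimal
precision and the two near-boundary cases (angina overall, heart
failure in women) within 0.01 — consistent with last-digit rounding in
the source. Sex-specific analytic sample sizes are approximated as
45.6%/54.4% of the full cohort, the recruited sex split, because no
sex-specific analytic N is published.

## Genetic-risk-score association

`score_association()` builds an allele score
$s_i = \sum_j w_j d_{ij}$ with dosages oriented to the
exposure-raising alleles, standardizes it by default (so the odds
ratio is per SD of the score — the published score's unit and
weighting are not stated, which is why its odds ratios are not
reproduction targets), and fits logistic regression of the outcome on
score plus covariates, adding sex in the overall stratum. The fit is
IRLS (`stats::glm.fit`) with convergence on relative deviance change
below `tol` (default 1e-8, max 50 iterations), Wald SEs from the
inverse observed information, an explicit rank check before fitting,
and an explicit separation check after (standardized coefficient
magnitude above 15 aborts with advice that penalized regression is out
of scope).

## The synthetic-data generators

Three generators share one genetic architecture (`draw_genetics()`):
effect-allele frequencies uniform on the configured range, relative
instrument strengths either drawn uniform on (0.7, 1.3) or supplied
(`gamma_rel`, e.g. the published per-allele betas), rescaled so the
instruments jointly explain `target_r2` of a unit-variance exposure,
and non-palindromic allele pairs.

* `simulate_individual()` — dosages $\mathrm{Bin}(2, f_j)$, exposure =
  genetics + shared confounder + noise, binary outcome from a logistic
  model whose intercept is solved numerically for the target case
  fraction (on a capped 100k subsample of the linear predictor — the
  case fraction is a design constant, not an estimand), plus sex, age,
  array and principal-component covariates with modest outcome
  effects.
* `simulate_two_sample()` — two disjoint samples; exposure-side betas
  and SEs from actual single-SNP linear regressions (so
  weak-instrument noise is realistic, not theoretical), outcome-side
  log ORs from marginal single-SNP logistic regressions, computed
  exactly via 3-cell grouped fits since dosages take values 0/1/2.
* `simulate_summary_stats()` — draws the per-SNP estimates directly
  from their large-sample normal sampling model. This is the right
  tool for estimator-calibration studies (it is the model under which
  the estimators' own null distributions are derived) and orders of
  magnitude faster.

Pleiotropy scenarios: `balanced` adds mean-zero per-SNP direct
effects independent of instrument strength (so the InSIDE condition
holds); `directional` shifts their mean. Scales are relative to the
median genetic effect on the outcome.

**Default study conditions.** The defaults are the validated design:
J = 10 instruments, R² = 0.01, exposure n = 100,000, outcome
n = 300,000, causal log OR ln 2, confounder strength 0.3, binary
outcome with case fraction 0.037. The case fraction matters more than
it looks: marginal per-SNP log odds ratios are non-collapsible, so at
common-outcome case fractions (~0.1+) the per-SNP estimand is
attenuated by several percent relative to the conditional causal
effect, while at a myocardial-infarction-like rate of ~0.04 the
logistic model is close to log-linear and the attenuation is well
under the simulation's resolution. Coverage is therefore assessed at
the rare-outcome design where the Wald/IVW estimand equals the
generating effect.

**What the generators do not emulate:** LD between instruments,
population stratification, sample overlap, genotyping error, selection
into the cohort, or sex-differential instrument effects. Passing
calibration and coverage tests therefore demonstrates the estimators
behave as advertised under their own assumptions — not that those
assumptions hold in any particular cohort.

## Numerical choices

* Exact normal quantiles everywhere; printed-value comparisons
  tolerate last-digit rounding.
* Bonferroni boundary: strict inequality drops.
* LD pruning: greedy by significance, deterministic lexicographic
  tie-break.
* $\varphi$ floor at 1 (under-dispersion never shrinks SEs).
* Empirical p-values: add-one correction, never zero.
* Weighted-median interpolation: `approx()` over strictly increasing
  cumulative midpoints; boundary ratios returned outside the
  breakpoint range.
* Mode search: 512-point grid spanning the ratio range ± 2 bandwidths,
  then local refinement; zero-bandwidth degeneracy returns the common
  ratio.
* IRLS: deviance tolerance 1e-8, max 50 iterations; rank and
  separation checked explicitly.
* Seeds: every stochastic routine takes one integer seed, records it,
  and restores the caller's RNG state.

## Validation problem sizes

The test suite validates the estimators at deliberately chosen sizes:
CI coverage of IVW/weighted-median/mode over 500 two-sample replicates
of the full individual-level generator at the default design;
MR-PRESSO global-test size and 10-SE outlier detection over 200
replicates each at `n_sim = 1000` (the add-one-corrected empirical p
resolves to ~0.001, ample for a 0.05-level test); null calibration of
all three estimators over 400 sampling-model replicates; closed-form
oracle checks (IVW weighted least squares, 2×2 logistic log OR,
interpolated medians, grid-density modes) at machine-level tolerances.

## Known limitations

* Wald SEs ignore exposure-side uncertainty by default (convention,
  see above); use the second-order option for weak instruments.
* MR-Egger, multivariable MR, Steiger filtering and colocalization are
  out of scope.
* LD pruning consumes a user-supplied r² matrix; the package never
  estimates LD.
* The genetic-risk-score odds ratios are per SD of an unweighted
  score by default and are not comparable across differently scaled
  scores.
* Penalized/Firth logistic regression is not provided; separated
  datasets abort with an informative error.
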