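---
title: "Beta-regression batch correction for methylation data: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-regression batch correction for methylation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betabatch)
```

## The model

A β-value is a proportion of methylated alleles, so its natural sampling
model on (0, 1) is the beta distribution. For feature-wise observations
$y_{ij}$ (sample $j$ in batch $i$) we fit, independently per feature,

$$\mathrm{logit}(\mu_{ij}) = \alpha + X_j\beta + \gamma_i, \qquad
\operatorname{var}(y_{ij}) = \frac{\mu_{ij}(1-\mu_{ij})}{1+\phi_i},$$

i.e. $y_{ij} \sim \mathrm{Beta}(\mu_{ij}\phi_i,\,(1-\mu_{ij})\phi_i)$.
The covariate row $X_j$ carries the biological condition and any further
adjustment variables; $\gamma_i$ is an additive batch effect on the M-value
(logit) scale; and each batch has its own precision $\phi_i$, because batch
effects in methylation data disturb spread as much as location (different
platforms or conversion chemistries produce visibly tighter or noisier
β-values). A pooled-precision mode exists for very small batches.

Identifiability follows the classic location/scale batch-model convention:
the sample-size-weighted batch effects satisfy $\sum_i n_i\gamma_i = 0$, so
$\alpha$ is the weighted cross-batch average M-value. We implement this by
fitting with one batch as the dummy-coded baseline and re-centering
afterwards — algebraically identical to the constrained fit and easier to
optimize. In reference-batch mode the constraint is replaced by
$\gamma_{\mathrm{ref}} = 0$: $\alpha$ becomes the reference batch's average
and all other batches are expressed as offsets from it.

### Estimation

The likelihood is maximized by BFGS over
$(\alpha, \beta, \gamma_{\text{free}}, \log\phi_1,\dots,\log\phi_{N_B})$
with analytic gradients; $\log\phi$ keeps precisions positive without
constraints. Starting values are OLS on $\mathrm{logit}(y)$ for the mean
coefficients and a method-of-moments precision per batch — the standard
recipe for beta-regression software, robust in practice. Convergence uses a
relative log-likelihood tolerance of `1e-8` with at most 200 iterations.

A fit is flagged non-converged when the optimizer fails, hits the iteration
cap without meeting the tolerance, or runs a precision beyond $10^6$ (the
signature of a batch whose values are essentially constant, where the
precision MLE diverges). Non-convergence is a per-feature flag, never an
error: the adjustment step passes such features through unadjusted with a
warning. This is the conservative choice — a feature whose within-batch
values are all at the squeezed boundary carries no estimable precision
signal, and inventing an adjustment for it would be less defensible than
leaving it alone and saying so. On boundary-heavy simulated data this can
affect 10–20% of features; downstream error rates are unaffected because
the passthrough features are returned verbatim.

## The adjustment

Once a feature is fitted, every observation gets a batch-free target
distribution:

$$\mathrm{logit}(\mu^*_j) = \mathrm{logit}(\hat\mu_{ij}) - \hat\gamma_i,
\qquad \phi^* = \frac{\sum_i n_i \hat\phi_i}{\sum_i n_i},$$

and is mapped onto it by quantile matching:
$y^*_j = F^{-1}\!\big(F(y_{ij};\hat\mu_{ij},\hat\phi_i);\,\mu^*_j,\phi^*\big)$.
Because β-values are continuous, "nearest quantile" reduces to exact
inverse-CDF evaluation through the regularized incomplete beta function;
the map is monotone in $y$, preserves the covariate effects $X_j\beta$
(only $\gamma$ is removed), and cannot produce values outside (0, 1) — the
structural advantage over Gaussian adjustment of β-values, which provably
escapes the unit interval on boundary-heavy data (see
`make_boundary_instance()` and the baselines tests). Quantiles are clamped
to $[10^{-12}, 1-10^{-12}]$ before inversion so squeezed boundary cells can
never map to exactly 0 or 1.

In reference-batch mode $\mu^*_j$ and $\phi^*$ are the reference batch's
estimates, so reference samples are fixed points of the map. This supports
sequential integration: when a new batch arrives, it can be harmonized to
the reference without recomputing anything for earlier batches.

### Empirical-Bayes shrinkage (off by default)

`eb_shrink()` implements a nonparametric Monte-Carlo pooling of batch
parameters across features, in the style of the count-based ComBat lineage:
for each feature, a seeded random subset of donor features is drawn
(default `min(F, 500)` — full pooling over a whole methylome is
prohibitively expensive), the feature's data are scored under each donor's
$(\gamma, \phi)$, and the feature's batch parameters are replaced by the
likelihood-weighted average, then re-centered. Shrinkage is **off by
default**: the beta distribution already accommodates skewness and
outliers, and in the benchmark shrinkage systematically under-corrects —
it leaves more residual batch-explained variance and costs detection power
(this is asserted as an acceptance property, not just stated).

## The count-level route

For bisulfite sequencing counts, `fit_bb_feature()` fits the same logit
mean model as a beta-binomial regression on methylated counts, with a
per-batch intraclass correlation $\rho_i \in (0,1)$ (shapes
$\mu(1-\rho)/\rho$, $(1-\mu)(1-\rho)/\rho$). The batch-free parameters
remove $\gamma$ from the logit mean and pool $\rho$ weighted by per-batch
total coverage (the count analogue of the sample-size-weighted precision
pool). Because the support is discrete, `adjust_counts()` does an explicit
search: the adjusted count is the integer $k \in [0, n]$ whose batch-free
CDF is nearest the observed count's CDF, ties broken toward the original
count for stability. Coverage is never altered, so adjusted data remain
valid count pairs. Differential testing uses a likelihood-ratio
chi-square ($\mathrm{df} = $ condition levels $- 1$) on pooled-dispersion
fits (`bb_lrt()`). A caveat worth knowing: at 20 samples the asymptotic
chi-square is optimistic, and the count route inflates false positives;
the effect fades by $N = 100$ (tested in `test-benchmark.R`).

## The synthetic-data generator

`simulate_dataset()` emulates a bisulfite benchmark dataset. The defaults
*are* the study conditions used throughout: 1000 features × 20 samples in
a balanced two-condition × two-batch layout; 100 truly differentially
methylated features with a +10 percentage-point effect under condition 2;
a cross-batch mean shift of 0/2/5/10 points whose sign alternates per
feature by a seeded coin flip (so both directions occur); batch-1
precision 10 and batch-2 precision 10 × fold for fold ∈ {1, 2, 5, 10}.

Choices the generator makes where no single convention exists, with
rationale:

* **Base proportions** come from the bimodal mixture
  $0.5\,\mathrm{Beta}(0.6, 2.4) + 0.5\,\mathrm{Beta}(2.4, 0.6)$ — real CpG
  methylation is strongly bimodal with mass near 0 and 1; mean 0.5 overall.
* **Coverage** is negative binomial with mean 30 and size 5, floored at 1
  (zero-coverage cells are re-drawn), a realistic moderate-depth bisulfite
  profile with over-dispersed depth.
* **True proportions are clamped** to [0.001, 0.999] after all shifts, so
  injected effects shrink at the boundaries exactly as real effects do.
* Per cell, the realized proportion is beta-distributed around the true one
  with the batch's precision, and the methylated count is binomial given
  coverage; β-values are the count ratios squeezed off the boundaries.

What the generator does *not* emulate: correlation between neighbouring
loci, coverage–methylation dependence, cell-type composition effects, and
array-specific probe chemistry. Passing tests on this generator therefore
demonstrates correct behaviour under the beta/beta-binomial sampling model
with feature-independent noise, not performance on any particular platform.

`make_boundary_instance()` is the adversarial companion: half its features
sit near β = 0.5, half near 0.93 with one diffuse batch (φ = 8) and one
batch concentrated just under the boundary (φ = 300). Rescaling the tight
batch to the pooled scale forces a Gaussian adjustment above 1, while the
quantile map cannot leave (0, 1).

## Differential testing and scoring

`mvalue_lm_test()` fits per-feature linear models to M-values via limma —
ordinary t, or moderated t with limma's inverse-chi-square variance
squeezing (default, as is common practice). The benchmark thresholds raw
$P < .05$ with no multiplicity correction, because the scored quantities
are per-feature error *rates* (TPR/FPR against simulation truth) — BH
q-values are exposed for real-data use. The "one-step" baseline skips
correction and passes batch dummies (`onestep_design()`) into the model.

`run_grid()` orchestrates scenario × replicate × method: replicate seeds
are drawn once from the master seed, every method sees identical data
within a replicate (required for fair medians), medians — not means — are
taken across replicates, and the replicate-level scores are attached for
uncertainty assessment. Results are bit-identical across runs and worker
counts; the fitting step itself contains no randomness.

## Numerical choices, in one place

* Boundary β-values: `clip` to $[\varepsilon, 1-\varepsilon]$,
  $\varepsilon = 10^{-6}$ (default; idempotent, interior values untouched)
  or the Smithson–Verkuilen compression $(y(n-1)+0.5)/n$. Clipped cells are
  recorded. Public methylation releases contain exact 0/1 calls, so both
  are load-time options.
* Missing cells: dropped from the feature's fit, `NA` in the output —
  propagation over imputation.
* Quantile clamping $[10^{-12}, 1-10^{-12}]$; adjusted values likewise.
* Gaussian baseline EB: parametric priors (normal on location,
  inverse-gamma on scale), moment-matched, iterated to $10^{-4}$ —
  verified equal to the reference ComBat implementation to $10^{-10}$, and
  with EB off it reduces to closed-form per-batch standardization (the
  oracle used in tests).
* Discrete quantile ties: toward the original count.
* Beta-binomial fits use numeric gradients (the digamma algebra buys
  little at bisulfite sample sizes); beta fits use analytic gradients.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` choose sizes so each claim is
measured at meaningful resolution: the FPR-calibration criterion runs the
full design (1000 features × 20 samples, 50 replicates of the 10%-shift /
equal-precision scenario); the power-ordering comparisons run 500 features
× 20 replicates per grid cell; the shrinkage comparison 300 features × 15
replicates with 100 Monte-Carlo donors; parameter recovery 200 features at
200 samples per batch; oracle equivalence 50 random instances against a
3125-point likelihood grid. Directional findings (power orderings,
shrinkage under-correction, count-route FPR inflation) were verified to
hold with wide margins at these sizes.

## Known limitations

* Beta regression has no closed-form MLE; correction is iterative per
  feature and thus slower than Gaussian M-value correction (parallelizable
  via `n_jobs`).
* Only batch effects from *known* sources are modelled; latent-factor
  methods (SVA/RUV) are the right tool when the source is unknown, and are
  deliberately out of scope.
* Features that are constant within a batch (common at the methylation
  boundaries after clipping) have no estimable per-batch precision and are
  passed through unadjusted; pooled-precision mode is a workaround when
  this matters.
* The count-level route should not be trusted for small-sample inference
  (see above); at $N \approx 20$ prefer the β-value route.
* Two-level conditions only in `mvalue_lm_test()`; multi-level designs
  need a custom contrast on top of the fitted models.
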