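---
title: "Heavy-tailed residuals in Bayesian sire models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heavy-tailed residuals in Bayesian sire models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`robustsire` fits the multi-trait linear mixed model

$$\mathbf{y}_i = \mathbf{X}_i \mathbf{b} + \mathbf{Z}_i \mathbf{a} +
  \mathbf{W}_i \mathbf{h} + \boldsymbol\epsilon_i,$$

for animal $i$ with $m$ traits, fixed effects $\mathbf{b}$, genetic
(sire or sire–maternal-grandsire) effects
$\mathbf{a} \sim N(\mathbf{0}, \mathbf{A} \otimes \mathbf{G}_0)$, an
uncorrelated random factor (herd or herd-year-season)
$\mathbf{h} \sim N(\mathbf{0}, \mathbf{I} \otimes \mathbf{H}_0)$, and
residuals

$$\boldsymbol\epsilon_i = \mathbf{e}_i / \sqrt{\lambda_i}, \qquad
  \mathbf{e}_i \sim N(\mathbf{0}, \mathbf{R}_0), \qquad
  \lambda_i \sim \mathrm{Gamma}(\nu/2, \nu/2).$$

Marginally $\boldsymbol\epsilon_i$ is multivariate Student's-$t$ with scale
$\mathbf{R}_0$ and degrees of freedom $\nu$, so its covariance is
$\frac{\nu}{\nu-2}\mathbf{R}_0$ for $\nu > 2$. A record whose mixing scale
$\lambda_i$ sits well below 1 carries an inflated residual variance on
*both* traits simultaneously — the model's mechanism for discounting
outliers. $\lambda_i \equiv 1$ (equivalently $\nu = \infty$) recovers the
ordinary multivariate normal mixed model, so the normal fit is a special
case of the same sampler with the mixing-scale and degrees-of-freedom
updates switched off.

The scale $\mathbf{R}_0$ of a Student's-$t$ fit is **not** comparable to
the residual covariance of a normal fit. All reporting therefore passes
through `marginal_residual_covariance()`, and heritabilities are always
computed from marginal residual variances.

## Posterior computation

A single seeded Gibbs sampler with a fixed update order drives everything
(`fit_mixed()`); the same seed and configuration reproduce a chain exactly.
Per cycle:

1. **Location effects** $(\mathbf{b}, \mathbf{a}, \mathbf{h})$ are drawn
   *jointly* from their Gaussian full conditional. The mean solves
   Henderson's mixed-model equations with heterogeneous residual
   precisions $\lambda_i \mathbf{R}_0^{-1}$; the coefficient matrix is
   assembled as $(\mathbf{T}'\Lambda\mathbf{T}) \otimes \mathbf{R}_0^{-1}$
   (with $\mathbf{T} = [\mathbf{X}\,\mathbf{Z}\,\mathbf{W}]$) plus the
   random-effect prior precisions
   $\mathbf{A}^{-1} \otimes \mathbf{G}_0^{-1}$ and
   $\mathbf{I} \otimes \mathbf{H}_0^{-1}$, and factorized by dense
   Cholesky. A joint draw avoids the slow mixing of single-site sweeps;
   the coefficient order (columns of $\mathbf{T}$, traits fastest) is
   fixed and recorded in the chain.
2. **Mixing scales**: $\lambda_i \mid \cdot \sim
   \mathrm{Gamma}\!\big(\tfrac{\nu+m}{2},
   \tfrac{\nu + \mathbf{e}_i'\mathbf{R}_0^{-1}\mathbf{e}_i}{2}\big)$, the
   standard scale-mixture conditional. It is verified in the test suite
   against a numerical-integration oracle (prior $\times$ Gaussian
   likelihood, normalized on a grid).
3. **Covariance matrices** $\mathbf{G}_0, \mathbf{H}_0, \mathbf{R}_0$ have
   inverse-Wishart full conditionals. Under the package's flat-prior
   convention the conditional degrees of freedom equal the number of
   contributing vectors and the scale is the (relationship- or
   $\lambda$-weighted) cross-product; the convention lives in a single
   internal function (`riwish()` callers) so an alternative convention is
   a one-line change. An optional proper inverse-Wishart prior
   (`vc_prior` in `fit_config()`) adds its own df and scale to the full
   conditional.
4. **Degrees of freedom** $\nu$ has no standard conditional and uses
   random-walk Metropolis–Hastings on the product of
   $\mathrm{Gamma}(\nu/2,\nu/2)$ mixing densities times the prior.
   Proposals below 2 are set to 2 before evaluation, keeping the marginal
   residual covariance defined; a `reject` variant that preserves detailed
   balance exactly at the boundary is available.

### Tunable parameters that matter

| parameter | default | role |
|---|---|---|
| `burn_in`, `n_keep`, `thin` | 50,000 / 50,000 / 1 | production chain sizes typical of this model class; validation work in this package uses 5,000 / 10,000, which the recovery experiments show is adequate for the balanced design |
| `nu_prior` | `uniform` on (2, 5000) | bounded-uniform keeps the posterior proper and lets normal data push $\nu$ into the thousands; `damped` $(1+\nu)^{-2}$ is available when a proper heavy penalty toward small $\nu$ is wanted |
| `nu_start`, `proposal_sd` | 8, 0.5 | neutral start between "heavy" and "normal"; the step adapts anyway |
| `tuning_interval`, `tune_factor` | 100, 1.3 | burn-in-only multiplicative step adaptation toward 40–50% acceptance, frozen afterwards to preserve the post-burn-in Markov property |

The adaptation is deliberately aggressive (factor 1.3 every 100 burn-in
cycles). When the data are effectively normal the $\nu$ posterior lives in
the thousands and is nearly flat, so acceptance stays high and the step
must grow by orders of magnitude within the burn-in to traverse the prior
range; a gentler schedule would leave the chain stranded near its start.
For concentrated posteriors (heavy-tailed data) acceptance drops and the
same rule shrinks the step back into the 40–50% window — the recovery
experiments land at ~0.45–0.5 acceptance.

## Model comparison and diagnostics

`predictive_log_likelihood()` implements per-observation conditional
predictive ordinates: for each record the harmonic mean, across retained
draws, of its per-draw density, summed on the log scale (computed online
during sampling with a streaming log-sum-exp; a stored-matrix route exists
for validation). The per-draw density *marginalizes* $\lambda_i$
analytically — the record's density is multivariate Student's-$t$ —
rather than conditioning on the sampled $\lambda_i$: marginalization is
the standard CPO construction, is numerically stabler, and makes values
from Student's-$t$ and normal fits commensurable. A difference exceeding
2.5 is read as an important difference in fit (`compare_models()`).

Effective sample sizes use Geyer's initial-positive-sequence estimator:
integrated autocorrelation time truncated at the first non-positive sum of
adjacent autocorrelation pairs. Posterior intervals are empirical 2.5/97.5
percentiles with type-7 interpolation. Outlier screening
(`flag_outliers()`) thresholds posterior-mean mixing scales at 0.3 and 0.2
(about three residual standard deviations under the Student's-$t$
calibration).

## Genetic-parameter transforms

Sire–MGS components are converted to direct/maternal animal-model
components by the Willham inversion $\mathbf{G}_{DM} = \mathbf{P}
\mathbf{G}_0 \mathbf{P}'$ with per-trait block
$\begin{pmatrix}2 & 0\\ -1 & 2\end{pmatrix}$, i.e.
$\sigma^2_D = 4\sigma^2_s$, $\sigma_{DM} = 4\sigma_{sm} - 2\sigma^2_s$,
$\sigma^2_M = 4\sigma^2_m + \sigma^2_s - 4\sigma_{sm}$. The map is linear
and exactly invertible; the test suite checks the round trip and an
external consistency anchor (published sire–MGS posterior means for
gestation length imply a direct–maternal correlation of about −0.86, which
the transform reproduces).

Heritabilities are computed **per draw** and then averaged — the posterior
mean of the ratio, not a ratio of posterior means. The phenotypic-variance
denominator is a genuine modelling choice for sire–MGS models; the default
convention is $\sigma^2_P = \sigma^2_s + \sigma^2_m + \sigma_{sm} +
\sigma^2_{HYS} + \sigma^2_{E,\mathrm{marginal}}$ per trait, with
`no_hys` and `no_cov` alternatives, and every summary row is tagged with
the convention used because published field heritabilities are not exactly
reproducible under any single obvious convention.

## The simulator

`simulate_dataset()` reproduces the balanced validation design used
throughout: 50 unrelated sires × 50 progeny, 100 herds, a two-level gender
factor with trait means (11, 90) and (38, 32), sire covariance
$[[2, 1.5], [1.5, 4]]$, herd variances (1.5, 6), residual scale
$[[15, 4], [4, 20]]$, and true $\nu \in \{4, 12, \infty\}$. Herd and
gender are assigned uniformly at random; the draw order (sire effects,
herd effects, gender, herd, mixing scales, residuals) is fixed so a seed
identifies a dataset. Two published anchors pin the residual scale: under
normality the marginal residual variances are the scale itself (15, 4, 20)
while the $\nu = 4$ and $\nu = 12$ rows are exactly 2× and 1.2× the scale.
The herd covariance between traits is not stated in the source design and
defaults to zero (configurable).

`simulate_fieldlike()` emulates the *structure* of national
gestation-length/birth-weight recording — 16 age-sex fixed subclasses,
many small uneven herd-year-season subclasses (mean size ≈ 7), a bull
pedigree in which younger bulls have a sire and a maternal grandsire among
older bulls (connected through phantom dams), and marginal trait scales GL
290 ± 8.1 d, BW 39.6 ± 4.1 kg. It is a synthetic stand-in: passing tests
on it demonstrate correct mechanics of the sire-MGS machinery on
realistic shapes, not agreement with any real population. Real field data
differ in ways the generator does not attempt: selection and non-random
mating, culling, heteroskedasticity across herds, genuine outlier
processes rather than Student's-$t$ tails.

## Numerical choices and degenerate inputs

- Factor levels are interned in first-appearance order; incidence columns
  and chain columns are therefore stable across reruns of the same input.
- Unknown parents are unrelated founders; relationship matrices come from
  the sire–dam tabular method, with maternal grandsires entered via
  phantom dams. How relationships among bulls were computed is typically
  unstated in field analyses; the phantom-dam convention is this package's
  documented choice.
- The mixed-model coefficient matrix is refactorized every cycle (the
  $\lambda_i$ reweighting changes it); a singular factorization aborts
  with a message about confounded levels.
- Chains abort with the cycle number on any non-finite state; kept-draw
  accumulators (effect means, mixing-scale means, CPO terms) are running
  sums, so memory does not grow with chain length unless the full
  log-density matrix is requested.
- Quantiles use type-7 interpolation; Kendall comparisons use tau-b (ties
  from numerical coincidence are corrected for).

## Known limitations

- **Flat covariance priors need enough levels.** With roughly fewer than
  15 levels in a random factor, the flat-prior inverse-Wishart conditional
  lets a covariance matrix drift to a rank-deficient boundary
  (correlation ±1), which is numerically absorbing: the chain stops with
  the positive-definiteness error rather than silently continuing. The
  balanced validation design (50 sires, 100 herds) is far from this
  regime; for small designs supply a weak `vc_prior`.
- The usual prior-predictive "getting it right" sampler check is not
  well-defined under improper flat priors; sampler validity rests instead
  on the exact equivalence of the location update with a dense
  mixed-model-equations oracle, closed-form inverse-Wishart means, a
  numerical-integration oracle for the mixing-scale conditional, and
  parameter-recovery experiments at the design scale.
- One mixing scale is shared across traits. Trait-specific scales would
  decouple outlier discounting between traits, at the cost of a
  multivariate mixing distribution; positively correlated trait pairs
  (such as gestation length and birth weight) are the case where the
  shared scale is most defensible.
- Residual truncation of $\nu$ proposals at 2 mildly perturbs detailed
  balance at the boundary; posteriors concentrated near 2 should use
  `nu_truncation = "reject"`.
- No missing-trait records, no heterogeneous residual variances across
  subclasses, no genomic relationships.

## A validation recipe

A reduced-scale recovery experiment (the package's own acceptance
workflow) is one call:

```r
library(robustsire)
ex <- replicate_experiment(n_replicates = 2, burn_in = 5000,
                           n_keep = 10000, master_seed = 1)
ex
```

This simulates each true residual family, fits both residual families to
every replicate, and tabulates degrees-of-freedom inference, variance
components (residuals on the marginal scale), predictive log-likelihoods
and sire-prediction quality — the quantities a practitioner would check
before trusting the machinery on real data. With these chain sizes each
fit takes on the order of a minute or two on a single core.
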