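---
title: "Hybrid QSPR regression for flammability limits: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid QSPR regression for flammability limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flamlim)
```

## The model and its assumptions

Flammability limits (LFL/UFL, volume percent) correlate strongly but
nonlinearly with topological and information-content molecular
descriptors. Rather than commit to one functional form, `flamlim` fits a
*hybrid* family that unions several classical QSPR forms in a single
least-squares design built from descriptors $X_1 \dots X_n$:

$$Y = \alpha_0 + \sum_{i=1}^{n}\alpha_i X_i
    + \sum_{d=1}^{D}\gamma_d\,\omega^d
    + \sum_{i=1}^{k}\delta_i\,\omega X_i
    + \sum_{i=1}^{n}\beta_i \ln X_i
    + \sum_{j=1}^{n}\sum_{i=1}^{n}\lambda_{j,i}\,X_j \ln X_i
    + \varepsilon$$

The blocks are: multiple linear regression (MLR); a polynomial in a
descriptor-sum feature $\omega$; MLR-by-polynomial interactions
$\omega X_i$; a logarithmic model; and MLR-by-logarithmic cross terms. A
polynomial-by-logarithmic interaction family is deliberately absent — its
contribution is negligible relative to the five families above, and
omitting it keeps the expansion from growing another factor of $n$. The
residual $\varepsilon$ is treated as i.i.d. Gaussian; no weighting or
heteroscedasticity correction is applied, matching how such correlations
are conventionally fitted.

Assumptions worth making explicit:

* **Descriptors are taken as given.** They are computed upstream
  (Dragon-style software) and used untransformed; no standardization is
  applied, so fitted coefficients stay in raw descriptor units and remain
  comparable to published compact equations.
* **Positivity for logarithms.** $\ln X_i$ and $X_j\ln X_i$ are only
  defined for positive descriptors. Eligibility is decided *on the rows
  being fitted*: a descriptor with any non-positive training value simply
  contributes no log/cross columns, and the mask is stored with the model.
  An optional $\ln(x + \epsilon)$ shift exists (`log_shift`) but is off by
  default: silently shifting would corrupt the meaning of the
  coefficients.
* **The family is intentionally redundant.** $\omega = \sum_i X_i$ makes
  the degree-1 polynomial column an exact linear combination of the linear
  block, and $\omega^2 = \sum_i \omega X_i$ ties the quadratic column to
  the interaction block. The hybrid design is therefore *intrinsically
  rank-deficient* even before $p$ exceeds $N$. This is a feature of the
  family, not an accident, and it dictates the estimator below.

### Two readings of $\omega$

`poly_mode = "global_sum"` (default) takes one feature
$\omega = \sum_{i=1}^n X_i$ and its powers $\omega, \dots, \omega^D$.
`poly_mode = "pairwise_sum"` instead builds $\omega$-features from pairwise
descriptor sums $X_a + X_b$ — the shape visible in compact published
flammability equations, whose terms look like $(\mathrm{AAC} +
\mathrm{PW5})$ or $(\mathrm{SIC0})^2(\mathrm{AAC} + \mathrm{PW5})$. Both
are first-class; the global sum is the default because it is the literal
reading of the hybrid family, while pairwise sums are the default
*generator* truth (below) because they match the published equations'
shapes.

### Estimation

With all families on, the column count is $p = 1 + 2n + m + k + n^2$
($m$ polynomial and $k$ interaction columns, $k = n$ by default). For
$n = 105$ descriptors that is over 11,000 columns against a few hundred
training compounds: $\Psi'\Psi$ is singular and the textbook
$(\Psi'\Psi)^{-1}\Psi'Y$ does not exist. The estimator is therefore
**minimum-norm least squares** via SVD — among all minimizers of
$\|Y-\Psi\Theta\|^2$, the $\Theta$ of smallest norm — with the effective
rank reported (singular values below
`max(dim) * .Machine$double.eps * max(d)` are treated as zero). The
normal-equations path is kept behind `method = "normal"` for well-posed
problems and pedagogy; it refuses singular systems rather than
regularizing silently.

### Pruning

`prune_coefficients()` implements backward elimination: repeatedly remove
the least significant term, refit, record the training $R^2$ after each
step. Significance is the classical per-coefficient $t$-test when it is
defined — residual degrees of freedom exist, the retained design has full
column rank, and the residual sum of squares is not numerically zero
(below $10^{-12}\max(\sum Y^2, 1)$). Otherwise — noise-free fits,
interpolating fits, rank-deficient designs — the ranking falls back to the
drop-one change in training $R^2$, which coincides with the $t$-ordering
where both exist. Ties are broken by column order (the earlier column is
retained) so pruning is deterministic. Two stopping rules are exposed,
since published compact models are sometimes described by a significance
level and sometimes by a coefficient count: `alpha_level` (eliminate while
any retained p-value exceeds $\alpha$) and `target_count`. Pruning uses
training rows only; held-out data never influence which terms survive.
The intercept is protected by default (`keep_intercept = TRUE`) because
the percent-$R^2$ reporting assumes a translation-invariant fit.

### Accuracy statistics

All deviation statistics carry their conventional literal $100/N$ factor:
ARD $= \frac{100}{N}\sum (cal-exp)/exp$, AARD with absolute values, and
AAE $= \frac{100}{N}\sum|cal-exp|$ — note AAE is therefore $100\times$ the
mean absolute error in volume percent and scales with the data. Two
$\sigma^2$ variants are always computed: the *printed* form, the sample
variance of the calculated values $\sum(cal_i - \overline{cal})^2/(N-1)$,
and the *residual* form with $(cal - exp)$ deviations about their mean.
The printed form is what conventional comparison tables show, but it
measures the spread of predictions, not their error — a constant
(useless) predictor has $\sigma^2_{printed} = 0$ — so reports carry both,
defaulting to the literal variant for table comparability. $R^2$ is the
coefficient of determination $100(1 - SS_{res}/SS_{tot})$ (the squared
Pearson correlation is available behind a flag); it can legitimately be
negative on held-out data.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `fraction` | `split_dataset()` | 0.8 | training share; size is round-half-up(`fraction`·N), reproducing 846/211 from 1057 and 412/103 from 515. The split is uniform random — whether reference splits were stratified is unknowable from printed sources, so plain uniform sampling is used and seeded. |
| `poly_degree` (D) | `hybrid_spec()` | 2 | highest $\omega$ power; 0 disables the block |
| `n_interactions` (k) | `hybrid_spec()` | n | number of $\omega X_i$ columns; the family's upper index is read as one interaction per descriptor |
| `log_shift` | `hybrid_spec()` | 0 | optional $\ln(x+\epsilon)$; off so coefficients keep their meaning |
| `tol` | `fit_least_squares()` | machine-precision scaled | singular-value cutoff for the effective rank |
| `value` | `prune_coefficients()` | — | $\alpha$ level or target term count |
| `noise_sd` | `synthetic_config()` | 0.05 | property noise, in property units — a few percent of an order-unity flammability limit |

## The synthetic generator

`generate_dataset()` draws descriptor tables emulating the *statistical
shape* of real descriptor matrices — strictly positive, heterogeneous
order-unity scales — and a property from a known sparse hybrid model:

* descriptors i.i.d. Uniform(0.1, 3) by default (the magnitude range of
  indices like SIC0 or PW5; positivity keeps every log term finite and
  condition numbers tame), or lognormal for heavier tails;
* ground truth in `pairwise_sum` mode by default, active fraction 0.4 of
  terms, coefficients $\sim N(0,1)$, all drawn from one seeded stream so a
  config is fully reproducible;
* `make_fixture_suite()` freezes four canonical cases used by the tests:
  noise-free, noisy, a 30-row table whose expansion has more than 30
  columns (p > N), and a model containing a term with true coefficient
  exactly zero.

What the generator does **not** emulate: inter-descriptor correlation
(real Dragon blocks are strongly collinear in structured ways), discrete
or bounded descriptors, family structure across congeneric compounds, and
measurement error in the descriptors themselves. Passing the synthetic
benchmarks therefore demonstrates the *machinery* — design construction,
minimum-norm solving, pruning order, metric identities, determinism — not
predictive accuracy on real flammability data, which depends on
proprietary descriptor tables this package deliberately does not ship.

A subtlety the test design reflects: because the full family is
intrinsically rank-deficient, ground-truth *coefficients* are only
identifiable when the generating sub-family is full rank. Recovery tests
therefore generate from intercept + linear + interaction + log + cross
(no polynomial block); fit-quality tests ($R^2 = 100\%$ on noise-free
data) use the full redundant family, where the fit — not the coefficient
vector — is the well-defined quantity.

## Numerical choices and degenerate inputs

* Minimum-norm solutions are verified in the tests against an independent
  pseudo-inverse implementation (`pracma::pinv`) on random systems
  including p > N; agreement tolerance 1e-8.
* Noise-free refits must recover generating coefficients to 1e-6 and
  $R^2$ to 100% ± 1e-6; in practice they agree to ~1e-13.
* Model files serialize coefficients at 17 significant digits, so
  save→load→predict is bit-identical.
* Zero experimental values make relative deviations undefined: ARD/AARD
  raise an error naming the offending index rather than returning Inf.
* Duplicate compound ids, missing descriptor values and non-positive
  LFL/UFL values are rejected at container construction; lenient row
  dropping must be requested explicitly and reports its count.
* Problem sizes in the tests and acceptance script (N up to 2000 in the
  consistency check, 300×20 with a 463-column expansion at survey scale)
  were chosen to exercise the p > N regime while keeping the whole suite
  in seconds on one CPU.

## Known limitations

* No regularized estimation (ridge/lasso) and no prediction intervals:
  the minimum-norm fit interpolates when p ≥ N, and its generalization is
  checked empirically, not bounded.
* No applicability-domain analysis; extrapolating a fitted model outside
  the descriptor ranges it was trained on is the user's responsibility.
* The compact published equations are transcribed at printed precision;
  one printed symbol inconsistency in the UFL equation's final term
  (`Jhet` vs `Jhetv`) is resolved to `Jhetv` and documented in
  `?ufl_eq13` rather than silently patched.
* Spreadsheet input is not supported; tables must be CSV/TSV. The schema
  is one identifier column, one property column, numeric descriptors.
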