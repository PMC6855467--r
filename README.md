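# flamlim

Hybrid QSPR models for the flammability limits of pure compounds.

## The problem

The lower and upper flammability limits (LFL, UFL) — the lowest and highest
fuel concentrations in air, in volume percent, that can propagate a flame —
are core process-safety properties. Measuring them (20-L vessel tests, ASTM
E681/E918 and kin) is slow and expensive, so quantitative
structure–property relationship (QSPR) models that predict them from
computed molecular descriptors are widely used. `flamlim` is for safety
engineers and cheminformaticians who have a table of compounds with
precomputed descriptors (Dragon-style topological, information-content and
autocorrelation indices — descriptor computation itself is out of scope)
and want to fit, prune, apply and rigorously test flammability-limit
regressions.

## The model

A single least-squares design combines four term families built from the
descriptors X₁…Xₙ, with ω a descriptor-sum feature:

    Y = α₀ + Σᵢ αᵢXᵢ  +  Σ_d γ_d ω^d  +  Σᵢ δᵢ ωXᵢ
        + Σᵢ βᵢ ln Xᵢ  +  Σⱼ Σᵢ λ_{j,i} Xⱼ ln Xᵢ  +  ε

(multiple-linear, polynomial, linear×polynomial interaction, logarithmic,
and linear×logarithmic cross blocks; with all families on the column count
is p = 1 + 2n + m + k + n²). Two readings of ω are supported: the global
descriptor sum ω = ΣXᵢ, and pairwise sums (Xₐ + X_b) — the shape of
published compact equations with terms like (AAC + PW5) and
(SIC0)²(AAC + PW5).

Because the expansion routinely produces more columns than training
compounds, the estimator is **minimum-norm least squares** via SVD: among
all Θ minimizing ‖Y − ΨΘ‖², the one of smallest norm. The textbook
normal-equations form Θ̂ = (Ψ′Ψ)⁻¹Ψ′Y is available behind
`method = "normal"` for well-posed problems. Backward elimination with
per-coefficient t-tests (falling back to drop-one ΔR² ranking when the fit
is degenerate) prunes the expansion to a compact model. Accuracy is
reported with the field's conventional statistics, each with its literal
leading 100/N factor: ARD, AARD, AAE, σ², plus R² in percent.

The package also ships two published compact predictor equations as
ready-to-use estimators: an 11-term LFL correlation in SIC0, AAC, PW5,
GATS1v (`lfl_eq12()`) and a 10-term UFL correlation in MLOGP, Jhetv, PW5,
SIC0, MATS4m (`ufl_eq13()`), with every printed coefficient stored in an
auditable term table.

## Worked example

Everything is testable without external data via the synthetic generator,
which draws positive descriptor tables and a property from a known sparse
hybrid model:

```r
library(flamlim)

gen <- generate_dataset(synthetic_config(N = 300, n = 8, noise_sd = 0.05,
                                         seed = 42))
fit <- run_training_protocol(gen$dataset, hybrid_spec(poly_degree = 2),
                             seed = 42)
fit
#> <hybrid_fit>
#> <hybrid_model> 91 terms (effective rank 89), fitted on 240 rows by svd
#>   families: cross:64 interaction:8 intercept:1 linear:8 log:8 poly:2
#>   train n= 240  R^2 =  99.9369%  AARD =   1.3750%
#>   test  n=  60  R^2 =  99.8105%  AARD =   2.6566%
#>   whole n= 300  R^2 =  99.9098%  AARD =   1.6313%
```

The 91-column expansion of 8 descriptors fits the 240 training compounds
with R² = 99.94% and holds up on the 60 held-out compounds (99.81%); the
AARD rows say predictions sit within ~1.4–2.7% of the true values on
average. Pruning to a 25-term model records the elimination trace
(training R² after each drop, non-increasing by construction):

```r
pruned <- prune_coefficients(fit$model, gen$dataset, mode = "target_count",
                             value = 25, rows = fit$split$train_idx)
head(pruned$training_meta$prune_trace, 3)
#>   step  dropped r2_after
#> 1    1 omega*D8 99.93686
#> 2    2    omega 99.93686
#> 3    3       D4 99.93686
```

(the first drops are exact linear dependencies of the expansion — removal
does not change the fit at all). And the published equations evaluate
directly from descriptor values:

```r
ufl_eq13(0, 0, 0, 0, 0)
#> [1] 14.011
lfl_eq12(SIC0 = 0.62, AAC = 0.45, PW5 = 0.11, GATS1v = 1.2)
#> [1] 25.67102
```

A command-line front end wraps the same pipeline
(`fit`, `predict`, `evaluate`, `published-predict`, `simulate`):

```sh
$(Rscript -e 'cat(system.file("cli", "flamlim", package = "flamlim"))') \
  fit --input table.csv --property LFL --seed 7 \
  --out-model model.json --out-metrics metrics.json
```

Dataset schema: a header CSV/TSV with one identifier column, one property
column (volume percent), and any number of numeric descriptor columns;
`read_dataset()` validates strictly (unique ids, no missing values,
positive LFL/UFL).

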