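# meantarget

Oblique **Mean-Target rotation (OMT)** for exploratory factor analysis,
alongside the conventional complete oblique Target rotation (OT) it
improves on, plus the Monte-Carlo machinery to evaluate both.

## The problem

Target rotation fixes the rotational indeterminacy of EFA by rotating the
extracted loadings toward a prespecified 0/1 independent-clusters pattern.
Conventional complete target rotation fits the oblique transformation to
every *single* loading, so in small samples the sampling noise in the
cross-loadings leaks into the rotated pattern and biases the estimated
factor inter-correlations — severely so when factors are many, salient
loadings moderate, and n small. Mean-Target rotation instead fits the
transformation to the *salient-weighted mean loadings of each block*,

```
Λ₁  = Λᵤ M                                    (orthogonal Procrustes toward Λ_T)
Λ₁ₘ = [(Λ₁∘Λ_T)'Λ_T]⁻¹ (Λ₁∘Λ_T)'Λ₁            (block-wise weighted mean loadings)
T   = (Λ₁ₘ'Λ₁ₘ)⁻¹Λ₁ₘ' I_q ,  Tₙ = T diag(T'T)^(-1/2)
Λ₂  = Λ₁Tₙ ,  Λ_O = Λ₂ diag((Tₙ'Tₙ)⁻¹)^(1/2)
Φ_O = (Λ_O'Λ_O)⁻¹Λ_O'(ΛᵤΛᵤ')Λ_O(Λ_O'Λ_O)⁻¹
```

so positive and negative sampling errors cancel within each block before
they can steer the rotation. OT is the same oblique core fitted to the
single loadings (`T = (Λᵤ'Λᵤ)⁻¹Λᵤ'Λ_T`). An optional ridge safeguard
handles ill-conditioned block-mean matrices (condition number κ above a
threshold), retaining the candidate with the best mean Tucker congruence
with the target.

The package is for methodologists and applied researchers working with
simple-structure EFA in small samples: it provides the rotations on any
labelled loading matrix (CSV in/out), the population models, sample
generator, least-squares extraction (ULS/PAF), congruence-based factor
alignment, and the recovery metrics (inter-correlation bias, RMS loading
error, factor score indeterminacy, subsample stability), all returning
tibbles with `tidy()` / `glance()` / `autoplot()` methods.

## Worked example

The package ships the 18 × 3 population example whose blocks carry
balanced ±0.20 cross-loadings around salient loadings of 0.50:

```r
library(meantarget)

fit_ot <- rotate_target(population_example_loadings(), "ot")
glance(fit_ot)
#> # A tibble: 1 × 8
#>   method     p     q kappa ridge mean_congruence mean_abs_phi phi_adjustment
#>   <chr>  <int> <int> <dbl> <dbl>           <dbl>        <dbl>          <dbl>
#> 1 OT        18     3  1.48     0           0.885        0.221       8.88e-16

round(fit_ot$pattern[1:4, ], 2)
#>      F1    F2    F3
#> x1 0.52  0.25 -0.11
#> x2 0.52 -0.11  0.25
#> x3 0.52  0.25 -0.11
#> x4 0.52 -0.11  0.25
round(fit_ot$phi, 2)
#>       F1    F2    F3
#> F1  1.00 -0.22 -0.22
#> F2 -0.22  1.00 -0.22
#> F3 -0.22 -0.22  1.00
```

OT shrinks the negative cross-loadings to −0.11 and pays with spurious
factor inter-correlations of −0.22. Every block's *mean* cross-loading is
already zero, so `rotate_target(..., "omt")` returns the pattern unchanged
with Φ = I — the two methods embody different answers to which solution is
"simple".

At the sample level the difference is recovery. One hard cell of the
simulation design (6 correlated factors, ϕ = 0.50, salient level 0.50,
n = 100, 50 replications):

```r
st <- run_study(condition_spec(6, 5, 0.5, "zero", 0.5, 100),
                reps = 50, base_seed = 7)
dplyr::select(st$summary, method, phi_mean_mean, phi_bias_mean, rms_loadings_mean)
#> # A tibble: 2 × 4
#>   method phi_mean_mean phi_bias_mean rms_loadings_mean
#>   <chr>          <dbl>         <dbl>             <dbl>
#> 1 OMT           0.452        -0.0478             0.246
#> 2 OT            0.0944       -0.406              0.283
```

OT's estimated inter-correlations collapse from the true 0.50 toward 0.09;
OMT keeps them at 0.45. `autoplot(st)` plots such summaries across sample
sizes, and `autoplot(fit_ot)` draws the rotated pattern as a heatmap.

A thin command-line wrapper over the same functions lives at
`inst/scripts/meantarget-cli.R` (subcommands `rotate`, `population`,
`simulate`, `stability`, `fixtures`).

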