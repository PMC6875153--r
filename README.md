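# stngrad

Gradients or compartments? `stngrad` implements a quantitative pipeline for
deciding how protein-marker immunoreactivity is spatially organized in 3D
reconstructions of the human subthalamic nucleus (STN): as a homogeneous
field, a linear gradient, three discrete subdivisions with abrupt borders
(the classic tripartite model), or a smooth sigmoidal gradient. It is aimed
at quantitative neuroanatomists working with serial-section
immunohistochemistry, and at anyone who wants to re-run or stress-test this
style of model comparison on synthetic data.

## The model family

The masked nucleus is rasterized into equal-volume sectors (3×3×3 for
across-specimen consistency testing, 10×10×10 for model fitting) along
three anatomical axes: the rostrocaudal cutting-plane axis plus two
in-plane PCA axes. Sector intensities are modelled as overdispersed counts,
`y ~ NB(mu, alpha)` with `Var = mu + mu²/alpha`, under four mean
structures on the normalized coordinates `x1, x2, x3 ∈ [0, 1]`:

| model | log-mean | parameters |
|---|---|---|
| A (homogeneous) | `λ0` | 2 |
| B (linear gradient) | `λ0 + λ1x1 + λ2x2 + λ3x3` | 5 |
| C (three subdivisions) | `λ0 + λ1·d1 + λ2·d2`, dummies switching at border fractions `τ1, τ2` of a fitted projection axis `p = β1x1 + β2'x2 + β3'x3` | 8 |
| D (sigmoidal gradient) | as C with logistic transitions of smoothness `κ` | 9 |

Each model is fitted by maximum likelihood with differential evolution
inside the published parameter bounds, then refined by bounded L-BFGS-B.
Models are compared by BIC and by BIC weights
`w_i = exp(-Δi/2) / Σ exp(-Δk/2)`; the model with the lowest BIC is the
preferred description of that specimen/marker combination.

The package also provides the surrounding stages: per-marker threshold
windows, mask-normalized Gaussian smoothing (FWHM 0.3 mm, kernel truncated
outside the mask and renormalized), outlier exclusion
(`log(y+1) > median + 5·IQR`), the across-specimen per-sector t-test
consistency analysis with Benjamini–Hochberg FDR control, and a seeded
synthetic-study generator (7 specimens × 12 markers) so every stage runs
without tissue data.

## Worked example

Simulate one specimen/marker with a sigmoidal-gradient truth, then let the
pipeline decide which organization the data support:

```r
library(stngrad)
truth <- model_params("D", lambda0 = log(30), lambda1 = 1, lambda2 = -1,
                      beta1 = 0.4, beta2 = 0.5, tau1 = 0.35, tau2 = 0.65,
                      kappa = 10, alpha = 10)
grid <- simulate_intensities(truth, grid_shape = c(10, 10, 10), seed = 7,
                             specimen_id = "S01", marker = "PARV")
grid <- exclude_outliers(grid)
sel <- stn_select(grid, control = stn_control(de_maxiter = 400,
                                              popsize_factor = 8,
                                              de_tol = 1e-3, seed = 42))
sel
#> Model comparison: specimen S01, marker PARV
#>  model k      nll      bic wbic
#>      A 2 3493.639 7001.093    0
#>      B 5 3489.062 7012.662    0
#>      C 8 3421.625 6898.512    0
#>      D 9 3407.115 6876.399    1
#> Preferred model (lowest BIC): D (sigmoidal gradient)
```

The generating sigmoidal model wins: it beats the threshold model C by
about 22 BIC points (so its BIC weight is ~1), while the homogeneous and
linear models are far behind. The fitted coefficients recover the
generating geometry — borders near the true `τ = (0.35, 0.65)`, projection
weights near `β = (0.4, 0.5)`, dispersion near `α = 10`:

```r
round(coef(sel$fits[[sel$preferred]]), 3)
#> lambda0 lambda1 lambda2   beta1   beta2    tau1    tau2   kappa   alpha
#>   3.488   2.318  -2.227   0.373   0.536   0.407   0.610   6.709   9.820
```

(The larger `|λ1|, |λ2|` with a smaller `κ` trade off against the truth's
steeper transitions — the fitted mean surfaces are nearly identical.)

Fitted objects support the usual verbs — `coef`, `predict`, `residuals`,
`simulate`, `plot`, `logLik` — and whole studies run through
`select_study()` / `run_pipeline()`, which write the canonical sector
tables, preference table, tallies and a reproducibility manifest.

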