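# deerens

Quantifying two-domain conformational equilibria from magnetic
resonance: DEER distance distributions, PRE distance restraints, and
two-state ensemble evaluation against ensemble-averaged restraints.

## Who this is for

Structural biologists and spectroscopists studying multidomain
proteins (the motivating system is the prolyl isomerase Pin1, whose WW
and PPIase domains exchange between a *compact* contact state and an
*extended* tethered state). The package answers three questions:

1. **What are the state populations and distances?** Invert a DEER
   dipolar time trace into a two-state distance distribution.
2. **What do relaxation data add?** Convert PRE rates into
   population-averaged distance restraints.
3. **Are two states required?** Evaluate and optimize one- vs
   two-state rigid-body ensembles against the combined NOE + PRE +
   DEER restraints via a sum-of-squared-violations target function.

## The model

A DEER trace is modeled as

V(t) = [ Λ₀ + Σₖ λₖ ∫ P(r) K(t − T₀⁽ᵏ⁾, r) dr ] · exp(−κ|t|ᵈ),

with the powder-averaged dipolar kernel
K(t,r) = ∫₀¹ cos[(1−3x²) ω_dd(r) t] dx, ω_dd = 2π·52.04 MHz·(r/nm)⁻³,
evaluated in closed form via Fresnel integrals. P(r) is either a
two-component Gaussian mixture — compact state (r₁, σ₁, population p₁)
and extended state (r₂, σ₂) — fitted jointly with the modulation depth
and background by bounded multi-start Levenberg–Marquardt, or a
non-parametric density from non-negative Tikhonov regularization with
GCV-selected penalty. Residual-resampling bootstrap (200 samples)
yields 95% confidence intervals.

PRE rates convert to distances through the Solomon–Bloembergen
relation r = [K/R₂ˢᵖ · (4τ_c + 3τ_c/(1+ω_H²τ_c²))]^(1/6) (distances
above 25 Å are excluded as beyond the reliable PRE range). Restraints
are scored against population-weighted ensemble averages — r⁻⁶
averaging for NOE/PRE, linear averaging for DEER effective distances —
with weights 1 (NOE), 1 (DEER), 0.01 (PRE) and a flat-bottom ±5 Å
tolerance on DEER effective distances.

## Worked example

Simulate a noisy apo-like trace (68% compact at 22 Å, 32% extended at
45 Å), fit it, and turn the result into a structure-calculation
restraint:

```r
library(deerens)

truth <- bigaussian_model(r1 = 22, sigma1 = 1.5, p1 = 0.68,
                          r2 = 45, sigma2 = 8)
trace <- simulate_trace(truth, pathway_model_4p(0.4),
                        background_model(0.1, 1),
                        time = seq(0, 2.5, length.out = 251),
                        noise_sigma = 0.005, seed = 42)
fit <- fit_bigaussian(trace, n_starts = 4, seed = 1)
fit <- bootstrap_ci(fit, n_samples = 200, seed = 1)
fit
#> bi-Gaussian model: compact r1 = 22.08 A (sigma 1.51, p1 = 0.681); extended r2 = 44.94 A (sigma 8.73, p2 = 0.319)
#>   amplitudes: lambda = 0.399; background kappa = 0.112 /us, d = 0.900; residual rms = 4.77e-03
#>   95% CI (bootstrap):
#>           r1 sigma1    p1     r2 sigma2 lambda kappa   d
#> lower 21.968  1.395 0.626 44.332  7.684  0.393 0.065 0.9
#> upper 22.160  1.642 0.702 45.711 10.758  0.431 0.118 1.2

r_eff <- effective_deer_distance(as_distribution(fit$model))
round(r_eff, 2)
#> [1] 29.36
make_limits(r_eff)   # flat-bottom restraint bounds, +/- 5 A
#> lower upper
#> 24.36 34.36
```

The fit recovers the planted populations within the bootstrap
interval (p₁ = 0.681, interval [0.63, 0.70], truth 0.68); the
population-averaged CB–CB distance of 29.4 Å, bracketed at ±5 Å,
becomes a DEER restraint for `optimize_two_state()`.

`run_pipeline(pipeline_config(seed = 1))` chains the full analysis on
synthetic ground truth (simulate → fit → populations → restraints →
one- and two-state optimization → state classification) and writes a
machine-readable report; `inst/cli/deerens.R` exposes the same stages
as shell subcommands.

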