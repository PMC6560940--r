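# warpgm — time-warped gradient matching for ODE parameter inference

`warpgm` estimates the kinetic parameters of coupled nonlinear ordinary
differential equations from noisy time-series observations, for systems
biologists and modellers who need parameter estimates without running a
numerical solver inside every step of an optimization loop.

## The method

For a fully observed system `ẋ = f(x, θ)` with noisy observations
`y_si = x_s(t_i) + ε_si`, **gradient matching** smooths each state with
kernel ridge regression, `g_s(t) = Σ_i b_si k(t, t_i)` with
`b_s = (K_s + λ_s I)⁻¹ y_s`, and estimates

```
θ̂ = argmin_θ  Σ_s Σ_i [ ġ_s(t_i) − f_s(g(t_i), θ) ]²
```

using analytic kernel derivatives (the baseline estimator, `rkg_fit()`,
called RKG). When the signal's intrinsic length scale varies — spiky
limit cycles, bursts, plateaus — one global kernel length scale fails,
and the failure is amplified at the derivative level.

The two-layer estimator `rkgw_fit()` (RKGW) first learns, per state, a
strictly increasing time warp `t̃ = w_s(t) = Σ_j exp(b_j) S(t − t_j, l)`
(a sum of weighted sigmoids) chosen so that the warped signal is close to
a regular oscillation: a sinusoid is the shape invariant under second
differentiation, so the warp minimizes
`Σ_i (q̈(t̃_i) + [λ_w]² q(t̃_i))²` plus an endpoint anchor, where
`q = g ∘ w⁻¹`. The warp is then smoothed by an MLP-kernel ridge
regression, the data are re-interpolated in the warped domain, and
gradients return to the original domain through the chain rule
`ġ(t_i) = q'(t̃_i) · w'(t_i)` before the same matching step. The methods
vignette (`vignettes/time-warped-gradient-matching.Rmd`) documents the
model, every tunable and the design decisions.

The package also ships the four benchmark systems (Lotka–Volterra,
FitzHugh–Nagumo, a five-species signal transduction biopathway, a
soft-tissue artery model), an adaptive RK2(3) solver, a synthetic-data
generator with a decibel SNR protocol, paired-Wilcoxon evaluation
machinery, and a YAML-driven CLI (`simulate` / `fit` / `evaluate` /
`run-all`; see `?warpgm_main`).

## Worked example

Simulate the Lotka–Volterra benchmark (`θ* = (1, 1, 4, 1)`,
`x0 = (0.5, 1)`, one limit-cycle period, ~28 points on the adaptive
solver's step pattern, 40 dB SNR) and fit both estimators:

```r
library(warpgm)
tr <- default_truth("lotka_volterra")
ds <- generate_dataset("lotka_volterra", tr$theta, tr$x0, tr$span,
                       snr_db = 40, seed = 7, n_obs = tr$n_obs)
rkg_fit(ds, "lotka_volterra", fit_config(seed = 1))
#> <ode_fit> RKG on lotka_volterra
#>  alpha   beta  gamma  delta
#> 0.7596 0.7894 4.3710 1.0050
rkgw_fit(ds, "lotka_volterra", fit_config(seed = 1))
#> <ode_fit> RKGW on lotka_volterra
#>  alpha   beta  gamma  delta
#> 1.0020 0.9953 4.0280 0.9990
```

On this noise draw the baseline misses the prey parameters by ~24%
(its single length scale over-smooths the population spikes), while the
warped estimator recovers all four parameters within 0.7%. Means over
the 10-replicate protocol (seed 1): `alpha = 0.9765`, `beta = 0.9765`,
`gamma = 4.0085`, `delta = 0.9970` — all within 2.5% of the generating
values.

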