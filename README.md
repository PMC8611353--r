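# ebtgrowth

Bayesian calibration of a non-local logistic proliferation model for
multicellular spheroid growth.

Spheroids cultured with replenished medium grow linearly in diameter for
weeks once proliferation is confined to an outer rim of viable cells.
`ebtgrowth` models this with a non-local logistic law in which daughter
cells appear within a kernel radius of their mothers,

    ∂t n(x,t) = α (k ∗ n)(x,t) (1 − n(x,t)),      k = ball indicator, radius σ_k,

so the colony expands without a diffusion term.  For radial data the model
reduces to a 1D equation for p(R,t) = 4πR² n(R,t), which the package solves
with an escalator boxcar train (EBT) particle scheme — fixed particle
locations, mass ODEs integrated by a compiled Dormand–Prince method with a
banded interaction matrix.  Colony radii are read off the particle measure
as 95% mass quantiles, observed radii carry multiplicative lognormal noise
with log-sd σ_o, and the four parameters

| parameter | meaning | unit |
|---|---|---|
| α | proliferation rate | 1/day |
| σ_k | kernel (interaction) radius | mm |
| σ_o | log-scale measurement error | — |
| σ_i | initial colony radius | mm |

are inferred by random-walk Metropolis–Hastings on the log scale with
lognormal priors.  Presets bundle the constants and priors of the three
classical spheroid cell lines (L-5178Y, V-79, B-16).  The package also
ships the validation machinery: an exact bounded-Lipschitz (flat) norm on
discrete measures, a 3D FFT reference solver, convergence and
posterior-stability harnesses, and a synthetic growth-curve generator.

## Worked example

Simulate a V-79-like dataset at the preset prior medians and fit it:

```r
library(ebtgrowth)

ps <- preset("V-79")
ps$priors$medians
#>   alpha sigma_k sigma_o sigma_i
#>   1.040   0.060   0.100   0.403

ds <- simulate_preset_dataset("V-79", sigma_o = 0.05, seed = 42)
ds
#> Growth dataset (V-79): 20 measurements, t in [0, 38] d, radius in [0.435668, 1.98604] mm
round(ds$radii[1:6], 3)
#> [1] 0.436 0.449 0.537 0.615 0.681 0.737
```

The first observation sits near the initial colony radius σ_i = 0.403 mm
(times the 5% noise), and the radius then grows quasi-linearly at a front
speed set jointly by α and σ_k.  The noiseless forward map at the same
parameters:

```r
round(forward_radii(model_params(1.04, 0.06, 0.05, 0.403),
                    c(0, 10, 20, 38), forward_config(N = 400)), 3)
#> [1] 0.407 0.743 1.132 1.869
```

A desk-scale fit tunes the proposal step towards 23% acceptance and runs a
20 000-iteration chain at N = 400 particles (a few minutes on one CPU):

```r
chain <- run_chain(ds, ps$priors,
                   forward_config(N = 400,
                                  control = solver_control(rtol = 1e-6,
                                                           atol = 1e-10)),
                   n_iter = 20000, burn_in = 2000, seed = 1)
chain                  # posterior quantiles per parameter
map_estimate(chain)    # highest-posterior draw, natural units
predictive_band(chain) # 95% pointwise band for the diameter curve
```

The posterior concentrates tightly for σ_i and σ_o; α and σ_k show the
expected ridge (the data pin the front speed, a joint function of both), so
their marginal intervals are wide while the fit of the growth curve itself
is tight.

A shell entry point wrapping `cmd_simulate()` / `cmd_fit()` /
`cmd_validate()` with YAML run configurations is installed at
`inst/cli/ebtgrowth`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ebtgrowth", package="ebtgrowth"))')" \
    simulate --preset V-79 --seed 1 --out run1
```

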