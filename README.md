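# rrlogistic

Individual-based simulation and theory for the **range-resident logistic
model**: a single-species birth–death population on a periodic square
habitat in which organisms move within home ranges and compete through a
spatial kernel. It is aimed at movement and population ecologists who want
to quantify how home-range size, space use and dispersal shape carrying
capacity — and at modellers who need a fast, exactly seeded spatial logistic
IBM with sessile and well-mixed limits.

## The model

Each organism has a home-range centre μ and position x(t). Movement follows
an Ornstein–Uhlenbeck process

> dx = −(x − μ)/τ dt + √(2σᵣ²/τ) dW,

with crossing time τ and stationary per-component variance σᵣ² (long-run
space use is Gaussian around μ). Brownian movement (uniform space use, the
non-spatial limit) and sessile organisms (the classical spatial logistic
model) are the τ, σᵣ² limits and are available as modes. Demography is
density-independent birth at rate b with Gaussian natal dispersal of centres
(scale σ_d), and density-dependent death at rate

> dᵢ = d₀ + γ Σ_{j≠i} K_c(xᵢ − xⱼ),

where K_c is an isotropic Gaussian competition kernel (scale σ_q, truncated
at 2.45 σ_q ≈ 95% of its mass). Events are simulated exactly with
Gillespie's algorithm; all positions are propagated between events with the
exact OU transition law.

The spatial structure feeds back on abundance through the **crowding
index** c = ∫ K_c(u) g₂(u) du (g₂ the pair correlation function): the mean
density obeys dn/dt = (b − d₀)n − γ c n², so the carrying capacity is
n\* = n\*_CSR / c\* with n\*_CSR = (b − d₀)/γ. The package estimates c from
organism positions or from home-range centres and sizes (via the composed
kernel with per-component variance σ_q² + 2σᵣ²), and predicts carrying
capacity from it.

## Worked example

Sessile organisms with short-range competition (σ_q = 0.01) and long-range
dispersal (σ_d = 0.1) at the standard rates (b = 1.5, d₀ = 0.1, γ = 0.002,
so n\*_CSR = 700 on the unit torus):

```r
library(rrlogistic)
dom <- torus_domain(1)
dem <- demography_params(b = 1.5, d0 = 0.1, gamma = 0.002,
                         kernel = kernel_spec(0.01),
                         dispersal = dispersal_spec(0.1))
sim <- simulate_rrl(700, 2e5, dem, movement_params("SESSILE"), dom,
                    seed = 42, record_stride = 1000)
sim
#> Range-resident logistic IBM run
#>   events: 200000  final N: 1312  t_final: 51.164
#>   births: 100306  deaths: 99694

normalized_carrying_capacity(nrow(sim$snapshot), dom, 1.5, 0.1, 0.002,
                             kernel_retained_mass(dem$kernel))
#> [1] 1.781
crowding_from_positions(sim$snapshot, dem$kernel, dom)
#> Crowding index (positions): c = 0.542924  [N = 1312]
equilibrium_prediction(1.5, 0.1, 0.002, 0.542924)
#>   n_csr    c_star   n_star predicted_K
#> 1   700 0.5429243 1289.314    1.841878
```

The population equilibrates ~78% above the homogeneous reference (1312
organisms vs 700/0.95 ≈ 737): long-range dispersal spreads offspring away
from their parents, the pattern becomes segregated at competition scales
(c ≈ 0.54 < 1), and the measured capacity (1.78) agrees with the
crowding-based prediction 1/c\* (1.84) up to demographic noise. A sweep over
movement modes and kernel scales (`run_sweep()`) reproduces the
predicted-vs-measured regression with R² ≈ 0.98 for both crowding
estimators.

A command-line front end (`inst/cli/rrlogistic.R`) exposes `simulate`,
`crowding`, `predict`, `sweep` and `fixtures` subcommands over YAML configs
and CSV snapshots; see the script header for usage. The methods vignette
(`vignettes/range-resident-logistic.Rmd`) documents the model, estimator
conventions and numerical design.

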