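---
title: "The range-resident logistic model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The range-resident logistic model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrlogistic)
```

## The model

`rrlogistic` simulates a single-species population in a homogeneous square
habitat of side $L$ with periodic boundaries (a torus). Each organism $i$
carries a home-range centre $\mu_i$ and a current position $x_i(t)$, and the
population evolves through three coupled processes:

* **Movement.** Between demographic events every organism moves as an
  Ornstein--Uhlenbeck (OU) process,
  $\dot x = -(x - \mu)/\tau + \sqrt{2\sigma_r^2/\tau}\,\eta(t)$,
  with home-range crossing time $\tau$ and stationary per-component variance
  $\sigma_r^2$; its long-run space use is an isotropic Gaussian around
  $\mu$. Two limits are exposed as modes of their own: Brownian motion
  (`BM`: $\tau,\sigma_r^2 \to \infty$ at fixed diffusion
  $D = \sigma_r^2/\tau$, uniform space use of the torus) and sessile
  organisms (`SESSILE`: $D = 0$, the classical spatial logistic model of
  plant ecology).
* **Birth and dispersal.** Births occur at a constant per-capita rate $b$.
  An offspring's home-range centre is displaced from the parent's by a draw
  from the dispersal kernel (isotropic Gaussian with scale $\sigma_d$, so
  dispersal distances are Rayleigh with mode $\sigma_d$; a Gamma-distance
  variant is available for robustness checks). Its initial position is drawn
  from its stationary space-use distribution — newborns are assumed to relax
  to range residency immediately.
* **Death by competition.** Organism $i$ dies at rate
  $d_i = d_0 + \gamma \sum_{j \ne i} K_c(x_i - x_j)$, where $K_c$ is an
  isotropic Gaussian competition kernel with scale $\sigma_q$, normalised to
  one over the plane, evaluated at minimum-image displacements and truncated
  at $2.45\,\sigma_q$ (which keeps $1 - e^{-2.45^2/2} \approx 95\%$ of its
  mass).

Demography is simulated exactly with Gillespie's algorithm: total rates
$B = bN$ and $D_{tot} = \sum_i d_i$ are computed from current positions, a
waiting time is drawn from $\mathrm{Exp}(B + D_{tot})$, all positions are
advanced by that interval, and a birth or death is executed with the frozen
rates. The default experiment starts from $N_0 = 700$ organisms with
uniform centres — the carrying capacity of the non-spatial model at the
standard rates — and runs for a fixed event budget.

## Crowding and the first-order theory

Spatial structure enters the mean-density dynamics through a single number.
Writing $g_2(u, t)$ for the pair correlation function of positions, the
**crowding index**

$$c(t) = \int K_c(u)\, g_2(u, t)\, du$$

is a kernel-weighted second-order statistic: $c = 1$ for homogeneous
(Poisson) populations, $c > 1$ when organisms are overcrowded at competition
scales, $c < 1$ when they are segregated. The density then follows the
crowded logistic equation $\dot n = (b - d_0) n - \gamma c(t) n^2$, whose
non-trivial equilibrium defines the carrying capacity
$n^\ast = n^\ast_{CSR} / c^\ast$ with $n^\ast_{CSR} = (b - d_0)/\gamma$. The
identity $n^\ast c^\ast = n^\ast_{CSR}$ is exact in the code path
(`equilibrium_prediction()`), and $1/c^\ast$ measured from an end-state
snapshot predicts the normalised carrying capacity.

Two estimators are provided. `crowding_from_positions()` sums the
(mass-renormalised) competition kernel over all ordered pairs of positions;
`crowding_from_home_ranges()` replaces positions by home-range centres and
the kernel by the composed weighting function `khr_value()`: because two
independent stationary OU organisms each add $\sigma_r^2$ per component to
their displacement, the composed kernel is the isotropic Gaussian with
per-component variance $\sigma_q^2 + 2\sigma_r^2$. The two estimators agree
when movement is fast relative to demography; we read that condition as
$\tau (b + d_0) \ll 1$ (the crossing time short against the mean individual
event time), which the stated rate comparison leaves dimensionally open.

Estimator conventions, chosen so that the homogeneous reference is exact at
finite $N$:

* pair sums are normalised by $N(N-1)$ (ordered pairs), not $N^2$, so a CSR
  pattern has expectation exactly 1;
* inside the estimators the truncated kernel is renormalised by its retained
  mass; inside the simulator's death rate it is **not** — truncation bias in
  the dynamics is instead absorbed by normalising measured capacities by
  $n^\ast_{CSR}/0.95$ (`normalized_carrying_capacity()`). Keeping both
  conventions separate means the estimator's reference value and the
  simulation protocol's normalisation are each exact on their own terms;
* the composed home-range kernel is evaluated to 6 composite standard
  deviations (mass deficit $e^{-18}$, far below estimator noise) rather than
  at the simulation cut-off, because it is defined by the stationary
  displacement distribution, not by the simulator's truncation.

`pair_correlation()` uses the torus estimator (no edge correction):
annulus-binned ordered-pair counts of minimum-image distances, normalised by
$N(N-1)/A$ times the annulus area.

## Parameters and defaults

| Parameter | Meaning | Units | Default |
|---|---|---|---|
| $L$ | domain side | length | 1 |
| $b$ | birth rate | 1/time | 1.5 |
| $d_0$ | baseline death rate | 1/time | 0.1 |
| $\gamma$ | competition strength | rate·area | 0.002 |
| $\sigma_q$ | competition scale | length | 0.01 |
| truncation | kernel cut-off multiplier | — | 2.45 |
| $\sigma_d$ | dispersal scale | length | 0.1 |
| $\tau$ | home-range crossing time | time | — |
| $\sigma_r^2$ | stationary positional variance | area | — |
| $N_0$ | initial abundance | count | 700 |

The demographic defaults give $n^\ast_{CSR} = 700$ on the unit torus, so
normalised capacities are directly interpretable as deviations from the
non-spatial expectation. Home-range "size" reported by sweeps is the 95%
Gaussian home-range area $-2\pi\sigma_r^2 \ln 0.05$ (emitted alongside raw
$\sigma_r^2$, since an area is the quantity field ecologists compare);
sweeps over home-range size at fixed diffusion vary $\tau$ and derive
$\sigma_r^2 = D\tau$.

## Numerical design

* **Exact OU transitions.** Positions advance with the closed-form
  conditional Gaussian $x' = \mu + (x-\mu)e^{-\Delta t/\tau} + \varepsilon$,
  $\varepsilon \sim N(0, \sigma_r^2(1 - e^{-2\Delta t/\tau}))$, rather than
  Euler steps: Gillespie waiting times span orders of magnitude and the
  exact sampler is unconditionally stable (the test suite checks it against
  a fine-step Euler--Maruyama integration of the Langevin equation).
* **Event ordering.** Rates and the waiting time are computed from pre-move
  positions; positions are then advanced and the event executed with the
  frozen rates. The alternative order (execute, then move) agrees to first
  order in $\Delta t$; freezing keeps the sampled waiting time and the
  selection probabilities mutually consistent and is exact in both the
  sessile and fast-movement limits.
* **Unwrapped positions.** OU positions are never wrapped during
  propagation — wrapping a mean-reverting path would corrupt the distance to
  its own centre. Centres are wrapped at birth; all interactions use
  minimum-image displacements of wrapped coordinates, with half-box ties
  ($\pm L/2$) resolved to $-L/2$ for determinism.
* **Neighbour search.** Death rates use a grid hash with cell size equal to
  the truncation radius (3×3 neighbourhood scan). In sessile mode rates are
  maintained incrementally — only the affected neighbourhood changes after a
  birth or death — with a full recompute every 4096 events to cap
  floating-point drift; in moving modes every event moves everyone, so rates
  are recomputed in full each event. A vectorised all-pairs implementation
  in R (`death_rates(..., method = "reference")`) is retained as an
  independent oracle and is required by the tests to agree to $10^{-12}$.
* **Wide kernels.** When the truncation radius reaches $L/2$ the kernel is
  summed over periodic images; a kernel with $\sigma_q \gtrsim L$ thereby
  flattens to $\approx$ mass$/A$ everywhere, which is how the mean-field
  (law-of-mass-action) limit is exercised end to end.
* **Quasistationarity.** Runs use a fixed event budget with summary
  statistics taken from the end state (and tail averages where a single
  final value would be noisy), replacing by-eye convergence checks with a
  fixed protocol.
* **Degenerate inputs.** Extinction is absorbing and recorded; crowding is
  an error below two points; a flat predictor or response makes the
  regression R² an error rather than NaN.

## Synthetic patterns and what the tests show

`generate_fixture()` produces CSR, Thomas-cluster, lattice and two-point
patterns with known statistics; these drive the estimator tests (CSR
unbiasedness, the Thomas pair-correlation and crowding closed forms with the
truncation correction, exclusion signatures, coincident-pair arithmetic).
The IBM itself is the generator for everything else. These patterns emulate
the *spatial* structure of real populations but none of the biology that
produces heterogeneity in practice — habitat selection, territory exclusion,
individual variation in rates or home-range size, observation error in
tracking data — so passing tests certify the estimators and the simulator
against their mathematical definitions, not the model against field data.

## Scale of the shipped experiments

The replication experiments are run at desk scale, as the package's own
protocol: 5 replicates of $2\times10^5$ events for the sessile
long-range-dispersal uplift, and an 11-cell grid (sessile cells at
$\sigma_q \in \{0.01, 0.1\} \times \sigma_d \in \{0.003, 0.01, 0.03, 0.1\}$
plus OU cells spanning home-range areas over two decades) with 2 replicates
of $10^5$ events for the crowding-predicts-capacity regression. Abundance
trajectories at these budgets are visibly quasistationary well before the
budget is exhausted (extinctions excepted), and the regression reproduces
the headline behaviour: $R^2 \approx 0.98$ for both estimators with slope
$\approx 1$ against the $1$–$1$ line, degrading when the smallest
competition scales are included (local interactions produce extreme
effective rates that a mean-rate theory does not capture). Full-scale
sweeps (20 replicates, $10^6$ events, denser grids) are a matter of
configuration, not code.

## Known limitations

* Movement modes are OU, BM and sessile; autocorrelated-velocity (OUF)
  movement, behavioural switching, memory and interaction-dependent movement
  are out of scope.
* Birth is density independent; only death responds to crowding.
* The theory is first order: the crowding index is measured, not predicted
  from parameters — no pair-dynamics closure is attempted.
* Estimation of movement parameters from empirical tracking data is not
  provided; `crowding_from_home_ranges()` accepts a known $\sigma_r^2$ (in
  simulations, the model parameter).
* The Gamma-distance dispersal variant's shape is a free choice (default 3)
  with its scale matched to the Gaussian kernel's mean dispersal distance;
  only kernel-shape robustness, not any empirical dispersal law, is claimed.
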