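---
title: "Continuum models of epithelial growth and collision: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuum models of epithelial growth and collision: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epigrowth)
```

## The models

`epigrowth` simulates and calibrates two minimal continuum descriptions of an
expanding epithelial monolayer. Cell density $\rho(\mathbf{x},t)$ (cells
mm$^{-2}$) obeys the continuity equation
$$\partial_t \rho + \nabla\cdot \mathbf{j} = r\,\rho\,f(\rho), \qquad
f(\rho) = 1 - \rho/K,$$
with logistic growth encoding contact inhibition of proliferation. The two
families differ in the flux:

* **Fisher-KPP** (`family = "linear"`): cells move randomly, so
  $\mathbf{j} = -D\nabla\rho$ with constant diffusivity $D$
  ($\mu$m$^2\,$h$^{-1}$). Fronts are "pulled", decay exponentially in space,
  and travel asymptotically at $c = 2\sqrt{Dr}$.
* **Porous–Fisher** (`family = "porous"`): cells drift down gradients of a
  population pressure via Darcy's law, $\mathbf{j} = -\rho\nabla P(\rho)$ with
  the power law $P(\rho) = D\rho^{m-1}$. For the default volume-exclusion
  exponent $m = 2$ this is $\partial_t\rho = D\nabla\cdot(\rho\nabla\rho) +
  r\rho(1-\rho/K)$, a degenerate (porous-medium-type) equation: solutions have
  compact support and sharp fronts, with travelling-wave speed
  $\sqrt{DKr/2}$ for $m = 2$. $m \to 1$ recovers the linear case.

For $n$ tissues of the same cell type seeded at distinct locations, the
package solves the cross-diffusion extension in which every species responds
to the *total* pressure $P = D(\sum_j \rho_j)^{m-1}$ and the *total* density
limits growth. Adding the $n$ equations recovers the single-species equation
for $\sum_j\rho_j$; for segregated initial data the common pressure keeps the
supports essentially disjoint, which is the mechanism behind the sharp,
persistent tissue–tissue boundaries. The linear-diffusion analogue couples the
species only through growth, so colliding tissues interpenetrate.

All user-facing parameters use experimental units ($\mu$m$^2\,$h$^{-1}$ or
$\mu$m$^2$(cells h)$^{-1}$, h$^{-1}$, cells mm$^{-2}$); internally everything
is converted once to mm/h/cells mm$^{-2}$ to avoid mixed-unit arithmetic.

### Derived biological quantities

`growth_summary()` and `packing_radius()` expose the standard sanity checks on
a calibrated fit: the hexagonal close-packing relation $K = 1/(2\sqrt3 a^2)$
inverted for the cell radius $a$; the crowding-reduced proliferation rate
$r(1-\bar\rho/K)$ at a bulk density $\bar\rho$; and the implied division time.
The division time is reported both exactly (the reciprocal of the effective
rate) and in a "headline" form that first rounds the rate to one significant
figure — the convention that turns an effective rate of $0.119\,$h$^{-1}$ into
a quoted 10 h division time. Which convention a quoted figure uses is rarely
stated; we adopt the reciprocal-of-rounded-rate reading because it reproduces
the arithmetic of the worked estimates, and always report the exact value
alongside it.

## The finite-volume solver

The solver (`fv_step()`, `fv_solve()`) is a conservative, positivity-
preserving explicit finite-volume scheme on uniform cell-centred grids, in two
modes: full 2D Cartesian (`ny = 1` gives planar 1D) and radially symmetric 1D
for circular expansions, where fluxes are weighted by face radius so that the
polar mass $\sum_c 2\pi r_c \rho_c h$ is conserved exactly.

For the porous family the face flux between cells $L,R$ is
$F = -M\,(P_R - P_L)/h$ with the mobility $M$ equal to the density of the
*upwind* cell (the side the pressure pushes mass out of). Upwinding by the
sign of the pressure difference makes the scheme positivity preserving and,
because the mobility of an empty cell is exactly zero, vacuum regions stay
exactly empty — compact supports and sharp fronts are preserved without any
regularisation. The linear family uses the centred Fickian flux
$-D(\rho_R-\rho_L)/h$. The logistic reaction is applied explicitly within the
same step. All boundaries are no-flux.

Numerical choices:

* **Stability.** $\Delta t \le \mathrm{CFL}\cdot h^2/(2\,d\,D_{\max})$ with
  $\mathrm{CFL} = 0.4$, $d$ the dimension and $D_{\max}$ the largest current
  diffusivity, combined with $\Delta t \le 0.1/r$ so the explicit logistic
  update stays accurate. `fv_solve()` re-evaluates the bound every step;
  `fv_step()` rejects an inadmissible step and reports the admissible bound.
* **Multi-species fluxes** share one pressure field per step, so the discrete
  two-species system sums *identically* (to rounding) to the single-species
  scheme applied to the summed initial condition — a structural identity the
  test suite asserts at $10^{-10}$.
* **Verification.** The suite checks mass conservation ($<10^{-10}$ relative
  over 1000 steps), an independently coded dense update oracle ($10^{-13}$),
  L$^1$ convergence to the heat kernel (linear) and to the Barenblatt
  source-type solution of $\partial_t\rho = D(\rho\rho_x)_x$ (porous), the two
  travelling-wave speeds within 5%, a comparison principle, and agreement of
  the radial and 2D modes on a circular expansion.

Front locations (`front_position()`) use the outermost linear-interpolated
crossing of a 10 cells mm$^{-2}$ threshold, a conventional visualisation
cutoff for these data; speeds are least-squares slopes of front position
against time. The Fisher-KPP front relaxes towards $2\sqrt{Dr}$ only
algebraically ($O(1/t)$ with a large constant), so speed checks measure late
windows on grids that resolve the exponential tail.

## Geometry and the synthetic observation protocol

`tissue_spec()`/`build_state()` rasterise circles and rectangles with uniform
seeding density onto the grid, anti-aliasing shape edges by $4\times4$ subcell
supersampling (sub-1% mass accuracy at the default spacings; exact annulus
coverage on radial grids). Shapes of different species must not overlap —
tissues start segregated — while same-species shapes are additive.
`hex_circle_array()` builds the multi-tissue layout: $n$ circles on a
triangular lattice with alternating labels.

`observe()` emulates how the experiments quantify density: the model field is
averaged over square voxels (default 115 $\mu$m, the experimental voxel size)
on a lattice anchored at the domain corner, and perturbed with additive
i.i.d. Gaussian noise of standard deviation $\sigma$ per voxel and time.
Voxel values are *area averages*, not point samples, matching nucleus-count
densities which are area measures. Negative noisy values are kept: the error
model is additive and unbounded, and the likelihood assumes exactly that.
Noise is generated from per-(time, voxel) counters so observations are
reproducible independently of iteration order.

`expansion_protocol()` reproduces the circular-expansion assay end to end: a
3.4 mm-diameter disc seeded at 2600 cells mm$^{-2}$ (the seeding density used
for the collision assays; the expansion seeding density is not quoted, so this
is an assumption of the generator), a 6 h burn-in standing in for the
discarded post-stencil-removal transient (the end-of-burn-in state plays the
role of the measured initial profile), observations at $t = 16, 26, 36, 46$ h,
and optional 11-replicate averaging. The simulation runs in the radial mode,
which is exact for this geometry. The default radial domain is 3.5 mm: at the
calibrated Fisher-KPP parameters the expansion front passes 3 mm before 46 h,
and a closer no-flux wall would distort the last observation time.

What the generator does *not* emulate: image formation and nucleus detection,
spatially or temporally correlated errors from model misspecification, the
non-monotonic intermediate-time density profiles seen in real expansions, and
densities above carrying capacity at late times. Passing the recovery tests
therefore demonstrates internal consistency of the pipeline under its own
error model, not fidelity of either model to real tissue.

## Inference

With $\theta = (D, r, K, \sigma)$, the log-likelihood of the voxelised data is
$$\ell(\theta) = -\tfrac12\sum_{i,j}\Big[\log(2\pi\sigma^2) +
\Big(\frac{\rho(x_i,t_j) - \rho_D(x_i,t_j)}{\sigma}\Big)^2\Big],$$
with $\rho$ the model solution voxel-averaged at position $x_i$ and time
$t_j$. Each evaluation is one PDE solve from the configured initial state.

* **Priors** are uniform on $\log_{10}\theta$ inside a box
  (`default_priors()`): $D \in [10^{2.5}, 10^{4.5}]$ $\mu$m$^2\,$h$^{-1}$
  (linear) or $[10^{-2.5}, 10^{1.5}]$ $\mu$m$^2$(cells h)$^{-1}$ (porous),
  $r \in [10^{-2.5}, 10]$ h$^{-1}$, $K \in [10^3, 10^4]$ cells mm$^{-2}$,
  $\sigma \in [10, 10^{3.5}]$ cells mm$^{-2}$ — wide enough to hold the
  calibrated reference estimates ($K \approx 5100$–$5300$, porous
  $D \approx 1.2$) with a decade or more of margin on the log scale.
* **Maximum likelihood** (`ml_fit()`): bound-constrained `L-BFGS-B` on the
  $\log_{10}$ scale, multistarted from points sampled uniformly on the log
  scale within the box; the full sorted multistart table is returned.
* **MCMC** (`mcmc_sample()`): Metropolis–Hastings on $\log_{10}\theta$ with
  Gaussian proposals whose covariance adapts to the sample covariance of the
  trailing half of the chain (scaled by $2.38^2/d$, updated every 50
  iterations after iteration 500, with a small diagonal jitter), plus a
  decaying global scale adaptation targeting 23.4% acceptance. Out-of-box
  proposals have prior density zero. The reference run length is 12 000
  iterations per chain with the last 5000 retained, three chains; scaled-down
  runs retain half the chain.
* **Diagnostics and summaries.** `gelman_rubin()` computes per-parameter
  (split) $\hat R$ from between/within-chain variances, normalised so
  identical chains give exactly 1 (this differs from the $(n-1)/n$-weighted
  textbook form by $O(1/n)$). `posterior_summary()` pools retained draws and
  reports the univariate mode (Gaussian-kernel density argmax, Silverman
  bandwidth — no mode recipe is quoted for the reference analysis, so this is
  the package's choice), mean, s.d. and central credible intervals;
  `posterior_bivariate()` supplies plot-matrix histograms in which the
  same-front-speed $D$–$r$–$K$ correlations are visible.

Circular-expansion likelihoods run on the radial grid (identical physics,
orders of magnitude cheaper); the 2D mode is reserved for collisions. Chains
can start anywhere in the box; starting them at the multistart ML estimate
(the `init` argument, used by `run_infer()`) is the standard practice the
package adopts, since the ML step precedes sampling anyway.

## Quantifying collisions

`interface_position()` locates the tissue–tissue boundary as the linear-
interpolated sign change of $\rho_1-\rho_2$ between the two supports, averaged
over grid lines along the collision axis. This is exact for segregated porous
solutions and degrades gracefully for mixed linear solutions; it is a
modelling stand-in for the image-based boundary used experimentally.
`track_interface()` detects the collision time (first output time at which
the supports meet; output cadence, not sub-step bisection, bounds its
resolution) and records displacement relative to the collision position,
with the initial-mass centroid as reference. `overlap_index()` measures
mixing as $\int\rho_1\rho_2 / (\int\rho_1\int\rho_2/A)$ — zero for disjoint
supports, one for identical uniform fields.

### The displacement scaling law

For two 1D tissues with an initial mass mismatch and no proliferation, the
boundary displacement under a power-law pressure grows asymptotically as
$t^{1/(m+1)}$. The balance: the merged blob approaches the self-similar
spreading solution with density scale $t^{-1/(m+1)}$ and width $t^{1/(m+1)}$,
so the Darcy interface velocity $-\partial_x P \sim
\rho^{m-1}/\mathrm{width} \sim t^{-m/(m+1)}$, whose integral is
$t^{1/(m+1)}$. This exponent decreases with $m$ (stiffer pressure, slower
boundary motion) and exceeds the diffusive $1/2$ for $m < 1$, i.e. faster
boundary motion for $m < 1$. (A form of this law with exponent $1/(m-1)$ is
sometimes quoted; that exponent is negative for $m<1$, at odds with both the
faster-for-$m<1$ behaviour and our simulations, so the package uses
$1/(m+1)$ throughout.) At finite
times the displacement passes first through a $\sqrt t$ regime — the
similarity solution of the initial density-jump problem — before the outer
rarefactions reach the interface, so `displacement_scaling_exponent()` fits
the last decade of a horizon long enough to leave that transient (defaults:
blocks of 0.5 mm at 2600 vs 1300 cells mm$^{-2}$, 200 h horizon, displacement
measured from the exact initial contact plane to avoid offset bias in the
log–log fit). Fitted exponents at the test resolution land within 0.15 of
$1/(m+1)$ for $m = 2$ and $m = 3$ while still drifting slowly towards the
asymptote from above.

## Problem sizes used by the test and acceptance runs

Derived-quantity checks are closed-form. Solver verification uses 1D grids of
200–600 cells ($h = 10$–40 $\mu$m). Collision phenomenology runs the
rectangle assays at $h = 50\,\mu$m on roughly $70\times60$ grids to 57 h.
The inference round trip generates the expansion protocol on a radial grid
with $h = 20\,\mu$m (175 cells, ~3600 voxel-times per observation time at
115 $\mu$m voxels), fits by 4-start ML, and samples 3 chains of 3000
iterations with noise $\sigma = 50$ cells mm$^{-2}$ — small relative to bulk
densities, as appropriate for a recovery check; these sizes keep the full
suite at a few minutes on one CPU while leaving every criterion's tolerance
unchanged.

## Known limitations

* Explicit time stepping only; the degenerate-diffusion time-step bound
  scales as $h^2$, so very fine 2D grids become expensive.
* The porous mobility upwinding is first-order accurate at the sharp front;
  front speeds carry an $O(h)$ bias (positive for the porous family).
* No cell–cell adhesion, viscoelasticity, cell-cycle structure or cell-size
  heterogeneity; the pressure law is the pure power law.
* The three-species tessellation demo and heterotypic (different-parameter)
  pairs are supported by the types but not studied quantitatively.
* Real collision datasets are external; all calibration targets in the tests
  are synthetic, generated by the package's own protocol.
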