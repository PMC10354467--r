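# epigrowth

Simulation and Bayesian calibration of continuum models of expanding and
colliding epithelial monolayers.

Epithelial tissues grown from a stencil expand by cell migration and
proliferation; when several tissues grow towards each other they collide and
form boundaries. `epigrowth` implements the two standard minimal models of
this process for cell density $\rho(\mathbf{x},t)$ (cells mm⁻²),

$$\partial_t \rho = \nabla\cdot\big(D(\rho)\nabla\rho\big) + r\,\rho\Big(1-\frac{\rho}{K}\Big),$$

with either constant diffusivity $D(\rho)=D$ (**Fisher-KPP**: random cell
motion, pulled fronts of speed $2\sqrt{Dr}$) or the degenerate,
population-pressure-driven diffusivity $D(\rho)=D\rho^{m-1}$ arising from
Darcy's law $\mathbf v = -\nabla P$, $P = D\rho^{m-1}$ (**Porous–Fisher**,
default $m=2$: compactly supported solutions with sharp fronts of speed
$\sqrt{DKr/2}$). Multi-tissue experiments are modelled by the cross-diffusion
extension in which every tissue responds to the total pressure
$P = D(\sum_j\rho_j)^{m-1}$ — the mechanism that keeps colliding tissues
segregated behind a sharp, trackable boundary.

The package is aimed at quantitative cell biologists and modellers who want
to (i) simulate expansions and collisions for arbitrary seeded geometries,
(ii) calibrate either model to voxelised density measurements by maximum
likelihood and adaptive Metropolis–Hastings MCMC with log-uniform priors,
(iii) assess practical identifiability through posterior width, unimodality
and Gelman–Rubin diagnostics, and (iv) quantify collision boundaries
(position, displacement direction and magnitude, mixing, and the
displacement scaling law $t^{1/(m+1)}$).

## What is in the box

| Area | Functions |
|---|---|
| Models & derived biology | `model_params()`, `crowding_function()`, `diffusivity()`, `packing_radius()`, `growth_summary()` |
| Finite-volume solver | `fv_grid()`, `tissue_state()`, `fv_step()`, `fv_solve()`, `front_position()`, `radial_profile()`, `wave_speed_estimate()` |
| Initial geometries | `tissue_spec()`, `build_state()`, `hex_circle_array()` |
| Synthetic observations | `observe()`, `expansion_protocol()`, `average_observations()` |
| Inference | `log_likelihood()`, `ml_fit()`, `mcmc_sample()`, `gelman_rubin()`, `posterior_summary()`, `default_priors()` |
| Collision analysis | `interface_position()`, `track_interface()`, `overlap_index()`, `displacement_scaling_exponent()` |
| Config-driven runs & I/O | `run_simulate()`, `run_infer()`, `read_run_config()`, `write_snapshot()`, `write_observations()`, `write_chains()` |

The solver core is compiled (Rcpp): a full radial expansion solve takes
milliseconds, which is what makes PDE-in-the-loop MCMC practical.

## Worked example

Simulate a synthetic circular-expansion assay at the calibrated
Porous–Fisher parameters, then recover the parameters from the noisy
voxelised observations:

```r
library(epigrowth)

p <- model_params("porous", D = 1.18, r = 0.214, K = 5319)
growth_summary(p, 3000)
#> <derived_quantities>
#>   cell radius          7.37 um
#>   effective rate       0.0933 h^-1
#>   division time        10.72 h (11 h at 1 s.f. rate)
#>   average diffusivity  3540.0 um^2 h^-1

# 3.4 mm disc, 6 h burn-in, voxelised (115 um) noisy observations
obs <- expansion_protocol(p, sigma = 50, seed = 42, h = 0.02)
obs
#> <observation_set> 14400 values | 3600 voxels (115 um) x 4 times (16, 26, 36, 46 h)
#>   synthetic, sigma_true = 50, seed = 42

cfg <- likelihood_config(obs, attr(obs, "initial_state"), family = "porous")
fit <- ml_fit(obs, cfg, default_priors("porous"), n_starts = 4, seed = 1)
fit
#> <ml_fit> maximum-likelihood estimate
#>           D           r           K       sigma
#>    1.181020    0.213843 5319.820000   50.220500
#>   logLik = -76829.521 over 4 starts (4 converged)
```

The derived quantities are the usual biological sanity checks: a ~7 µm cell
radius from hexagonal close packing at carrying capacity, a ~0.09 h⁻¹
effective proliferation rate at a 3000 cells mm⁻² bulk density, and an
average diffusion coefficient `D * 3000 = 3540` µm² h⁻¹. The multistart fit
recovers the generating `(D, r, K, sigma)` to a fraction of a percent.
Posterior sampling continues with
`mcmc_sample(obs, cfg, default_priors("porous"), init = fit$theta)`, then
`gelman_rubin()` and `posterior_summary()`.

Collisions use the same solver in 2D; see `?track_interface` for boundary
tracking and `?displacement_scaling_exponent` for the scaling law. YAML-driven
batch runs (`run_simulate()`, `run_infer()`) write snapshots, chains,
diagnostics and a manifest per output directory.

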