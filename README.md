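# permflow

Quantifying water permeation through lipid bilayers from molecular
dynamics trajectories — counting complete water crossings of the membrane
per observation window, then inferring the underlying **bursty** flow rate
with a Bayesian latent-rate model.

The package is aimed at people analysing MD simulations of pore-forming
peptides or channels (the motivating system is a saposin-like antimicrobial
peptide embedded in a POPC bilayer, simulated as monomer and dimer) who
want more than a single average permeability number: a posterior rate
*function* over simulation time, with honest uncertainty, plus a
diagnostic for how strongly the flow departs from simple Poisson
behaviour.

## The model

Per-window crossing counts $Y_1,\dots,Y_n$ (default window: 10 ps, one per
saved frame) are modelled with an autoregressive latent log-rate with
Student-t drift and negative-binomial observations

$$\lambda_i \sim t_\nu(\rho\,\lambda_{i-1},\,\sigma), \qquad
  Y_i \sim \mathrm{NB}\big(\mu = e^{\lambda_i},\, \phi\big),
  \quad \mathrm{Var}(Y) = \mu + \mu^2/\phi,$$

with weakly informative priors $1/\phi \sim \mathrm{HalfCauchy}(0,5)$,
$\sigma \sim \mathrm{HalfCauchy}(0,5)$, $\nu \sim \Gamma(2, 0.1)$,
$\rho \sim N(0,1)$, $\lambda_1 \sim \mathrm{Cauchy}(0,5)$. The heavy-tailed
drift captures bursts; the negative binomial captures within-window
overdispersion. Posterior sampling uses a No-U-Turn Hamiltonian Monte
Carlo sampler (written in C++ with analytic gradients, non-centered latent
path, dual-averaging step-size and diagonal mass-matrix adaptation) over
four independent chains, with split-R-hat convergence gating.

Alongside the fit, `compare_to_poisson()` contrasts the marginal count
distribution with a Poisson of equivalent expectation: a dispersion index
(variance/mean) and a tail-mass ratio at the Poisson 99th-percentile
threshold turn "heavier-tailed than Poisson" into a number.

A synthetic-data module generates count series from the model with known
parameters and kinematic membrane trajectories with known crossing
schedules, so the full pipeline is testable without MD runs.

## Worked example

```r
library(permflow)

## 1. a synthetic "dimer-like" trajectory: 120 waters, 800 frames (8 ns),
##    180 scheduled crossings through a slab at z = +-18 A
sched <- random_schedule(n_molecules = 120, n_frames = 800,
                         n_events = 180, seed = 1)
slab  <- membrane_slab(-18, 18)
traj  <- simulate_membrane_trajectory(sched, slab, seed = 2, box_z = 80)

## 2. count crossings per 10 ps window
y <- count_crossings(traj, slab, window_ps = 10)
y
#> <crossing_counts> 799 windows of 10 ps
#>   total 180 crossings; mean 0.225 / window (22.53 molecules/ns)
#>   down 92 / up 88

## 3. fit the latent-rate model (reduced draws for a quick look)
fit <- sample_posterior(y, n_chains = 4, n_draws = 500, n_warmup = 500,
                        seed = 3)
summarize_rates(fit)$mean_flow
#> [1] 22.63059

## 4. burstiness diagnostic
compare_to_poisson(y)
#> <marginal_comparison> 799 windows, mean 0.2253 counts/window
#>   dispersion index (var/mean): 0.943
#>   tail (k* = 3): observed 0.00125 vs Poisson 0.00161, ratio 0.78
```

The counted series here is nearly Poisson by construction (scheduled
events are scattered independently); counts simulated from the bursty
generative model show dispersion indices well above 1 and tail ratios of
5–20. The fitted mean flow (~22 molecules/ns) recovers the scheduled rate:
180 crossings / 7.99 ns = 22.5 molecules/ns.

For real trajectories, `read_standard_trajectory()` extracts water-oxygen
and lipid-phosphate z-coordinates from a multi-model PDB (or PDB + DCD)
via bio3d selections, and `infer_slab()` places the slab at the
time-averaged leaflet phosphate planes.

A command-line interface wraps the same functions:

```sh
permflow simulate --kind counts --n-windows 10000 --seed 1 --out counts.csv
permflow count --top system.pdb --coords run.dcd --window-ps 10 --out counts.csv
permflow fit --counts counts.csv --chains 4 --draws 2000 --warmup 1000 --seed 1 --out posterior/
permflow diagnose --counts counts.csv --out report.json
permflow run --config pipeline.json
```

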