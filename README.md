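# spclone

Simulation and inference for the **single-progenitor (SP) model** of
squamous epithelial tissue maintenance, aimed at transgenic
lineage-tracing studies in mouse skin and oesophagus.

In these tissues a single equipotent population of basal progenitors
divides at rate λ (per week), each division yielding two progenitors, two
differentiating cells, or one of each with probabilities *r*, *r* and
1 − 2*r*; differentiating basal cells stratify out of the basal layer at
rate Γ, which homeostasis ties to the progenitor fraction ρ via
Γ = ρλ/(1 − ρ). Lineage tracing labels single cells and scores the basal
clone size *n* = *n*<sub>A</sub> + *n*<sub>B</sub> of persisting clones at
a handful of sacrifice timepoints; the inference task is to recover
(*r*, ρ) at fixed, independently measured λ, with honest uncertainty.

The package provides:

* **Three routes to the clone-size distribution P<sub>n</sub>(t)** —
  the exact branching-process generating function (complex-plane ODE
  integration + FFT inversion), a truncated master-equation integrator
  (uniformization, with measured truncation leakage; the verification
  oracle), and stochastic simulators, both Gillespie (exponential cell
  cycle) and event-queue non-Markovian (gamma-distributed cell-cycle
  times, mean fixed at 1/λ).
* **Grid-search maximum likelihood** (`mle_grid_analytic`,
  `mle_grid_simulation`), per-timepoint likelihood decomposition
  (`per_timepoint_surfaces`), and normalized-surface equal-tailed
  intervals.
* **SMC-ABC** (`smc_abc`) with a summed per-timepoint Kolmogorov–Smirnov
  distance, adaptive tolerance and Gaussian perturbation kernel — the
  route that handles realistic cell-cycle times and reports realistic
  uncertainty.
* **A synthetic cohort generator** (`generate_cohort`) emulating sacrifice
  designs with per-mouse parameter variation, plus timepoint-subset
  rebalancing (`subset_timepoints`) for in-silico experimental design.
* **I/O and a CLI**: long-format clone tables (CSV/TSV), CSV + JSON result
  serialization with provenance, and `inst/cli/spclone.R` with
  subcommands `synth`, `simulate`, `mle-analytic`, `mle-sim`,
  `timepoints`, `abc`.

## Worked example

```r
library(spclone)

p <- sp_params(lambda = 2.9, r = 0.06, rho = 0.5)
p
#> Single-progenitor model parameters
#>   lambda (division rate)      : 2.9 /week
#>   r (symmetric division prob) : 0.06
#>   rho (progenitor fraction)   : 0.5
#>   Gamma (stratification rate) : 2.9 /week [derived]

# exact clone-size distribution at 10 days
pmf <- clone_size_pmf_analytic(p, days_to_weeks(10), n_max = 64)
round(pmf$p[1:5], 4)
#> [1] 0.1257 0.3042 0.2792 0.1561 0.0731
# P_0 is the extinct fraction; surviving clones average ~1/rho cells later on

# a large synthetic cohort at that parameter set, then recover (r, rho)
design <- cohort_design(mice_per_timepoint = 1, clones_per_mouse = Inf,
                        simulated_clones_per_mouse = 14286,
                        lambda_mean = 2.9, lambda_sd = 0,
                        r_mean = 0.06, r_sd = 0, rho_mean = 0.5, rho_sd = 0)
cohort <- generate_cohort(design, seed = 101)
fit <- mle_grid_analytic(cohort$observations, lambda = 2.9,
                         grid = grid_spec(25, 25))
fit
#> SP log-likelihood surface (analytic engine), 25 x 25 grid
#>   argmax: r = 0.06, rho = 0.5 (loglik -97259.52)
#>   95% interval r  : (0.06, 0.06)
#>   95% interval rho: (0.5, 0.5)
```

The argmax lands on the generating values; the zero-width intervals on
this very large, perfectly specified cohort illustrate how sharp (and,
under model mis-specification, over-sharp) grid-MLE uncertainty is. For
realistic data, run the ABC route:

```r
noisy <- generate_cohort(cohort_design(cell_cycle = cc_gamma(8)), seed = 202)
post <- smc_abc(noisy$observations, lambda = 2.9, cell_cycle = cc_gamma(8),
                config = abc_config(n_populations = 5, population_size = 200,
                                    clones_per_particle = 500), seed = 303)
post
#> SMC-ABC posterior: 5 generation(s), 200 particles in final
#>   r  : median 0.08976, 95% CI (0.04134, 0.1417)
#>   rho: median 0.734, 95% CI (0.5064, 0.9831)
```

The credible intervals comfortably cover the generating means
(r = 0.09 ± 0.01, ρ = 0.7 ± 0.05 across mice) — unlike the grid-MLE
intervals on the same data, which are narrower than the bias introduced
by the exponential cell-cycle assumption. See the vignette
(`vignettes/single-progenitor-inference.Rmd`) for the full methods
account.

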