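# jointmark

Bayesian joint live-recapture/dead-recovery ("joint encounter", JE) models
and Seber dead-recovery (DR) models for marked animal populations, with a
capture-history simulator and a bias/RMSE/CV evaluation workflow.

## The problem

Banding studies of harvested birds (and many other marked populations)
produce two encounter streams from the same individuals: live recaptures at
the study site and reports of dead animals recovered anywhere in the range.
A multistate JE model combines both and jointly estimates, per year:

* **S** — true survival,
* **F** — fidelity (probability a survivor does not permanently emigrate
  from the study area),
* **p** — recapture probability,
* **r** — reported mortality, the probability that an animal which died in
  an interval is found and reported (Seber's λ; related to the Brownie
  recovery rate *f* by *r = f/(1 − S)*).

The latent process has four states — alive inside, alive outside,
recently dead, dead — with one-interval transition matrix

| from \ to | inside | outside | recently dead | dead |
|---|---|---|---|---|
| inside  | SF | S(1−F) | (1−S)r | (1−S)(1−r) |
| outside | 0 | S | (1−S)r | (1−S)(1−r) |
| recently dead | 0 | 0 | 0 | 1 |
| dead | 0 | 0 | 0 | 1 |

and an observation model in which only animals alive inside can be seen
alive (probability p) and only recently dead animals are recovered. All
four parameter families carry logit-normal random time effects
(logit θ<sub>t</sub> = logit μ + ε<sub>t</sub>, ε<sub>t</sub> ~ N(0, σ²))
with uniform priors on each μ and σ.

The package's likelihood is *marginal*: the latent states are integrated
out by a forward algorithm (in C++), rather than sampled, so it is exact,
fast, and unit-testable against brute-force path enumeration. Posterior
sampling is an adaptive Metropolis-within-Gibbs scheme with interweaving
moves for the hierarchy, gated on rank-normalized split R-hat < 1.05.
The DR model is the multinomial m-array likelihood with Seber cell
probabilities. A simulator generates encounter histories with exactly the
model's structure for study designs of the usual "N marked per year for T
years" form.

## Worked example

Simulate the canonical study design (100 newly marked individuals per year
for 10 years, year-specific parameters around S = 0.90, F = 0.90, r = 0.19,
p = 0.50) and fit the JE model:

```r
library(jointmark)

build_transition_matrix(S = 0.90, F = 0.90, r = 0.10)
#>               alive_inside alive_outside recently_dead dead
#> alive_inside          0.81          0.09          0.01 0.09
#> alive_outside         0.00          0.90          0.01 0.09
#> recently_dead         0.00          0.00          0.00 1.00
#> dead                  0.00          0.00          0.00 1.00

d <- sim_design(n_new_per_year = 100, n_years = 10,
                param_means = list(S = 0.90, F = 0.90, r = 0.19, p = 0.50),
                seed = 42, use_reference_vectors = TRUE)
sim <- simulate_histories(d)
sim$histories
#> Encounter histories: 1000 individuals (1000 distinct), 10 occasions
#>   recovered dead: 79; ever recaptured: 491

fit <- fit_je(sim$histories, prior_spec(), mcmc_preset("fast", seed = 1))
fit
#> Bayesian JE model fit: 3 chains x 1000 kept draws
#>   max R-hat = 1.0464  (converged)
#>  parameter  mean     sd   q2.5 q97.5 rhat
#>       mu_S 0.843 0.0408 0.7543 0.917 1.02
#>    sigma_S 0.567 0.3048 0.1147 1.338 1.00
#>       mu_F 0.910 0.0531 0.7756 0.979 1.01
#>    sigma_F 1.506 0.3278 0.8183 1.982 1.00
#>       mu_r 0.179 0.0409 0.1232 0.288 1.02
#>    sigma_r 0.296 0.2679 0.0103 1.051 1.01
#>       mu_p 0.512 0.0651 0.3784 0.638 1.00
#>    sigma_p 0.735 0.2385 0.4057 1.357 1.00
```

The grand means recover the generating levels (fidelity 0.91 vs. 0.90,
reported mortality 0.179 vs. 0.19, recapture 0.51 vs. 0.50; survival 0.84
against a realized year-mean of 0.88). Per-year fidelity bias against the
generating values:

```r
truth <- design_params(d)
s <- fit$summary
Fhat <- s$mean[s$parameter == "F" & !is.na(s$year)]
round(compute_bias(Fhat, truth$F), 3)
#> [1]  0.105  0.041  0.110  0.071 -0.099 -0.024  0.069  0.077  0.023
```

Individual year effects are partially pooled, so years with extreme
generating values (0.65, 0.99) are shrunk toward the mean — visible above
as the larger per-year deviations.

## Analysis workflow

The `analysis/` drivers chain the package into the full study; each writes
CSV outputs and a JSON manifest under `results/`:

1. `01_simulate.R` — the eight canonical data sets (r ∈ {0.10, 0.19} ×
   p ∈ {0.01, 0.20, 0.50, 0.90}).
2. `02_fit_je.R`, `03_fit_dr.R` — single JE / DR fits with draws and
   summaries.
3. `04_simulation_study.R` — the 8-cell bias/RMSE study with convergence
   gating and boxplots.
4. `05_case_study.R` — JE vs DR precision comparison at banding-program
   scale on synthetic stand-in data (~18,400 individuals, 18 years).
5. `06_report.R` — aggregates the study and case-study tables.

All take `--seed` (and most `--preset fast|default|...`).

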