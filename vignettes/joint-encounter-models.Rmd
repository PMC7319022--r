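---
title: "Joint live-recapture/dead-recovery models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint live-recapture/dead-recovery models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its models, algorithms and design
choices. It states no empirical result: numbers come out of the test suite
and the analysis drivers, not out of this document.

## The estimation problem

Marked-animal studies often collect two encounter streams from the same
individuals: live recaptures at the marking site, and reports of dead
animals recovered anywhere in the species' range (for harvested birds,
mostly hunter band reports). A joint encounter (JE) model uses both streams
at once and can then separate quantities that neither stream identifies
alone: true survival $S$ (not apparent survival), fidelity $F$ to the
study area, recapture probability $p$, and reported mortality $r$ — the
probability that an animal which died in an interval is found and reported.
$r$ is the Seber reporting parameter; it relates to the Brownie recovery
probability $f$ by $r = f/(1-S)$ (`r_from_f()`).

A dead-recovery (DR) model uses only the recovery stream. It estimates $S$
and $r$ but not $F$ or $p$, and serves here as the recapture-free baseline
against which the value of sparse recapture data is measured.

## Latent process and observation model

The JE model is a hidden Markov model over four latent states: *alive
inside* the study area, *alive outside* (permanent emigration — there is no
return), *recently dead* (died in the last interval and was reported), and
*dead*. Per interval $t \to t+1$ the transition matrix built by
`build_transition_matrix(S, F, r)` is

| from \ to | inside | outside | recently dead | dead |
|---|---|---|---|---|
| inside  | $SF$ | $S(1-F)$ | $(1-S)r$ | $(1-S)(1-r)$ |
| outside | $0$ | $S$ | $(1-S)r$ | $(1-S)(1-r)$ |
| recently dead | $0$ | $0$ | $0$ | $1$ |
| dead | $0$ | $0$ | $0$ | $1$ |

Placing $r$ in the transition step (rather than the observation step) makes
*recently dead* mean "died and was reported": that state is observed as a
dead recovery with certainty, lasts exactly one occasion, and then is
absorbed into *dead*. A death in $[t, t+1)$ that is reported therefore
appears as a recovery at occasion $t+1$. The observation matrix
`build_observation_matrix(p)` maps states to the three observable symbols
(seen alive / recovered dead / not seen): only animals alive inside can be
recaptured (probability $p$), animals outside or long dead are never seen.
Under marginalization (below) the placement of $r$ in the transition rather
than the observation matrix is a representational choice with no effect on
the likelihood.

Marking is the entry point: a newly marked animal is alive inside with
certainty, and its first encounter is recorded without error. There is no
recruitment modeling, age/sex structure, tag loss, or trap response.

## Exact marginal likelihood

Rather than sampling the latent states in the MCMC (the usual
data-augmentation route, which mixes poorly when recaptures are sparse),
the package integrates the latent trajectory out with a forward algorithm
over the four states (`history_loglik()`, `dataset_loglik()`, implemented
in C++). The likelihood of a history conditions on the first release and
multiplies one interval-transition and one observation weight per
subsequent occasion; the forward variables are renormalized each step, so
probabilities never underflow even for long, silent histories. A history is
closed at its recovery occasion: everything after a dead recovery is
deterministic.

Two consequences matter in practice:

* **Testability.** The forward value is checked against brute-force
  enumeration over all $4^T$ latent paths, and the likelihood is verified
  to sum to one over the space of legal observable histories. These
  property tests hold to $10^{-10}$.
* **Pooling.** Individuals with identical (marking occasion, symbol
  sequence) records contribute identical factors, so histories are pooled
  with multiplicity weights (`pool_histories()`). Banding data sets with
  tens of thousands of individuals but sparse detection collapse to a few
  hundred distinct records, and likelihood cost scales with the distinct
  count only. Pooling is exact, not an approximation.

The DR model works on the m-array sufficient statistic (`build_marray()`):
release cohort $j$ is multinomial over first-recovery intervals with
$\pi_{j,k} = \left(\prod_{t=j}^{k-1} S_t\right)(1-S_k)\,r_k$ plus a
never-recovered remainder. The multinomial coefficient is omitted, which
makes `marray_loglik()` exactly equal to the individual-level product —
convenient for the sufficiency test that links it to `dataset_loglik()`
with recapture switched off. Each animal belongs to exactly one release
cohort (its marking year); live recaptures are not re-releases.

## Hierarchical structure, priors, sampling

All parameter families carry random time effects on the logit scale:
$\operatorname{logit}(\theta_t) = \operatorname{logit}(\mu_\theta) +
\varepsilon_t$, $\varepsilon_t \sim N(0, \sigma_\theta^2)$. Priors are
uniform on each $\mu_\theta$ on the probability scale (the study
configurations use $U(0,1)$; the case study uses informed bounds), mapped
to the sampling scale by change of variables. The prior on each
$\sigma_\theta$ is $U(0, 2)$ on the logit-scale SD — a deliberately wide
choice: annual SDs of 0.02–0.07 on the probability scale at means near 0.9
correspond to logit-scale SDs of roughly 0.2–0.8, so the bound is far from
binding while still proper.

Sampling is adaptive random-walk Metropolis-within-Gibbs over the scalar
components of the transformed parameter vector
($u = \operatorname{logit}$-scaled mean, $v$ for $\sigma$, and the
$\varepsilon_t$), with batch adaptation toward 44% acceptance during
burn-in only, so the retained kernel is fixed. Centered hierarchies of this
kind mix slowly along two directions — the grand mean against its effects,
and the effect SD against the effects — so each sweep adds two interweaving
moves per family: a translation that shifts $\operatorname{logit}(\mu)$ and
subtracts the same amount from every $\varepsilon_t$ (the year-specific
values, and hence the likelihood, are unchanged; only the priors and the
change-of-variables Jacobian enter the acceptance ratio), and a rescaling
that moves $\sigma$ and scales the $\varepsilon_t$ proportionally (the
effect prior cancels against the Jacobian exactly). Both are standard
ancillarity–sufficiency interweaving moves; correctness is verified by
prior-recovery tests, and the whole sweep runs in compiled code — the
likelihood sits in the innermost loop of the sampler, which is where
capture–recapture packages routinely compile. Chains are initialized from
prior draws (with the random-effect scale capped at 0.5 to avoid absurd
starting trajectories) and re-drawn up to 25 times if the posterior is
non-finite at the start — with interior parameters this is a formality.
Every run is fully determined by one integer seed: chain seeds derive from
it, and per-cell seeds in the study runner derive from the study seed, so
reruns are bit-identical.

Convergence is gated on the rank-normalized split Gelman–Rubin statistic
(`rhat()`): a fit is flagged `converged` only when every monitored
quantity (each family's $\mu$, $\sigma$ and year-specific values) has
R-hat < 1.05. The study runner re-runs a non-converged cell with doubled
iterations and burn-in, up to twice, and otherwise reports the cell as
failed — never silently.

## The simulator and what it does (not) emulate

`simulate_histories()` draws latent trajectories from the transition matrix
and observations from the observation matrix, cohort by cohort, under one
root seed. The canonical study design is 100 newly marked individuals per
year for 10 years, with fixed year-specific parameter vectors
(`reference_annual_params()`) around means $S = 0.90$, $F = 0.90$,
$r \in \{0.10, 0.19\}$ and $p \in \{0.01, 0.20, 0.50, 0.90\}$; using the
same fixed vectors in every cell isolates the effect of the information
level from parameter noise. Fresh vectors can be drawn instead with
`gen_annual_params()`, which samples on the logit scale. Printed annual
SDs are interpreted on the probability scale and mapped by the delta
method, $\sigma_{\text{logit}} = \text{sd}/(\mu(1-\mu))$; a Monte-Carlo
test confirms the back-transformed draws recover the intended mean and
spread.

Generation is vectorized within cohorts under a single `set.seed()` per
simulate call; reproducibility is per run (same design, same histories),
which the test suite asserts, rather than per individual.

The simulator reproduces the statistical structure the models assume. Real
banding data differ in ways the simulator deliberately omits: age and sex
structure, individual heterogeneity in survival or detection, tag loss,
non-random temporary emigration, and reporting rates that drift with hunting
regulations. Passing tests therefore demonstrate correctness of the
machinery and behavior of the estimators *under the model*, not robustness
to these violations.

## Evaluation conventions

Bias for a year-specific parameter is the posterior mean of $\theta_t$
minus the generating value — the behavior of the shrunken random-effect
estimates, which is the quantity practitioners use. RMSE combines the
posterior SD with that bias as $\sqrt{\text{SD}^2 + \text{bias}^2}$;
by construction RMSE $\ge |\text{bias}|$. Per-year values are reported
individually (box-plot style), never averaged away.

Shrinkage is the dominant term in that bias surface and deserves emphasis:
where the data cannot identify an individual year's value (fidelity with
recapture near 0.01 is the extreme case), its posterior mean collapses
toward the estimated grand mean, so per-year biases approach the spread of
the generating values around their mean — up to $\pm 0.17$ for the
canonical fidelity vector — no matter how long the chains run. The
*typical* (median-across-years) bias stays small whenever the grand mean
itself is estimated well; the *maximum* per-year bias does not. The study
runner reports per-year values so either statistic can be formed, and the
maximum should be read as a worst-case shrinkage diagnostic, not as an
estimator defect.

Precision comparisons between JE and DR fits use the posterior coefficient
of variation $\text{CV} = \text{SD}/\text{mean}$, in two labeled flavors:
per year-specific estimate (the series practitioners plot) and for the
grand mean $\mu$ (the headline "mean annual estimate"). Because the
case-study "mean annual" value is likewise ambiguous between the
grand-mean posterior and the mean of annual posterior means, both are
computed and labeled.

## Problem sizes and schedules

The MCMC presets trade precision for turnaround. The `default` preset
(3 chains × 40,000, burn-in 20,000, thin 10) is the production schedule;
`long-*` presets (up to 600,000 iterations) are shipped for the
hardest low-information cells, where the posterior is diffuse and slow to
traverse; `fast` (3 × 4,000, burn-in 2,000, thin 2) is the schedule used
by the test suite, the acceptance script and the default analysis drivers.
The test suite exercises the full eight-cell study at the canonical design
size (1,000 individuals per cell) with the fast preset, a ten-fold
enlarged single-cell design for parameter recovery, and a full-scale
synthetic case study (≈18,000 individuals over 18 years, pooled to a few
hundred distinct histories). These sizes are the package's own choices for
routine verification; production analyses should use the `default` or
`long-*` presets.

Numerical details worth knowing: forward variables are renormalized every
occasion; $\sigma$ is floored at $10^{-12}$ inside the prior density to
keep the log-density finite at the boundary the uniform prior technically
excludes; proposal scales start at 0.4 on the transformed scale;
tie-breaks in R-hat use average ranks. Boundary parameter values (0 or 1)
are legal inputs to the simulator and the matrix builders, and the
likelihood remains exact there, but fits assume interior truth.

## Known limitations

* At the lowest information level (recapture ~0.01 with reported mortality
  ~0.10), fidelity and recapture are weakly identified; fits there may need
  the `long-*` schedules, and the convergence gate exists precisely to
  keep such cells from contaminating summaries. Reported-mortality levels
  below ~0.10 are outside the package's validated envelope.
* The sampler is a random-walk scheme: robust and dependency-free, but not
  competitive with gradient-based samplers at high dimension. For the
  model sizes here (≤ 80 parameters) it is adequate.
* The case-study drivers ship with synthetic stand-in data generated at the
  scale of the motivating banding program; conclusions about the real
  program require the real records, which are not redistributable.
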