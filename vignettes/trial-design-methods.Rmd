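---
title: "Bayesian two-stage designs with posterior predictive monitoring: models and methods"
author: "ppostrial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian two-stage designs with posterior predictive monitoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppostrial)
```

# The setting

`ppostrial` implements the statistical machinery of a small multi-arm
phase II oncology trial with a binary composite response endpoint. The
trial has two structural pieces:

* a **registered single-agent arm** (arm A) run as a Bayesian two-stage
  design with an interim look, and
* a **randomized comparison** (arms B vs C) allocated 1:1 in permuted
  blocks, analyzed through the posterior of the log-odds ratio.

A patient is a *responder* when at least one of two co-primary binary
endpoints is met: a radiological response (complete or partial response
by RECIST-style target-lesion rules) or a biological response (a
biomarker changing by at least 30% of its pre-treatment value).

# The single-arm model

Responders follow `R ~ Binomial(N, p)` with a conjugate `Beta(a, b)`
prior on the response rate `p`, so every posterior is again a Beta
distribution, `Beta(a + x, b + N - x)`. The package default is the
near-improper non-informative prior `Beta(1e-3, 1e-3)`.

**Final rule.** The trial recommends further research when

> P(p > 0.1 | data) >= 0.90.

Both numbers are parameters of `success_rule()`; 0.1 and 0.90 are the
defaults. The posterior statement is evaluated through the upper tail of
the regularized incomplete beta function (`pbeta(..., lower.tail =
FALSE)`). We read "a 90% posterior probability" as *meeting* the level
(non-strict `>=`): the source wording does not disambiguate, the
non-strict reading makes the discretized responder boundary well defined
at the boundary case, and the choice is configurable by adjusting
`confidence` infinitesimally. Because the posterior tail probability is
increasing in the responder count, the rule discretizes to an integer
boundary (`min_responders_final()`): at `N = 18` under the defaults, 4
or more responders succeed (`P(p > 0.1 | Beta(4.001, 14.001)) = 0.917`,
while 3 responders give 0.762). When no responder count can satisfy the
rule the function returns `NA_integer_` explicitly rather than a
sentinel count, so the design search sees infeasibility.

**Interim rule.** At the interim analysis the *posterior predictive
probability of success* (PPoS) integrates the final rule over the
beta-binomial posterior predictive distribution of the remaining
patients. The trial stops for futility when PPoS < 0.10, stops for
efficacy when PPoS > 0.90, and continues otherwise; both cut-offs are
parameters, and comparisons are strict per the "less than a 10% chance /
greater than a 90% chance" wording, so a PPoS exactly at a cut
continues. PPoS is monotone in the interim responder count, so the
interim decisions always form a monotone boundary
(futility/continue/efficacy); `bayesian_interim_rules()` verifies this
rather than assuming it.

**Numerics.** The beta-binomial pmf is computed in log space through the
Polya product form (cumulative sums of log rising factorials) instead of
`lbeta()` ratios. This matters for the near-improper prior: with shapes
of `1e-3` the `lgamma`-difference route loses ~1e-12 of normalization at
`m = 200`, while the product form keeps the pmf summing to 1 within
1e-13. Posterior tails use `pbeta` upper tails directly, avoiding the
`1 - cdf` cancellation.

# The two-stage design search

A two-stage design `(n1, r1, n, r_total)` enrolls `n1` patients, stops
for futility when at most `r1` respond (`r1 = -1` disables stopping),
and otherwise enrolls to `n`, declaring success when total responders
reach `r_total`. Note the convention: `r_total` is the smallest
*successful* count, one larger than the "reject if at most r" boundary
used in some published tables.

`exact_operating_chars()` evaluates, by exact binomial tail sums,

* the success probability
  `sum over x1 > r1 of Binom(x1; n1, p) * P(X2 >= r_total - x1)`,
* the probability of early termination `PET = P(X1 <= r1)`, and
* the expected sample size `n1 + (1 - PET) (n - n1)`.

`search_designs()` enumerates **every** design with `n <= n_max`
(default 60), keeps those with exact type-I error at `p0` at most
`alpha_max` and exact power at `p1` at least `power_min`, and selects
the *optimal* design (minimum expected sample size under `p0`, the
Simon optimality criterion) and the *minimax* design (minimum `n`).
The constraint set leaves ties possible; the package breaks them by
smaller `n`, then smaller `n1`, then larger `r_total` (the smallest
attained type-I error), and documents rather than hides this choice.
Under the defaults (`p0 = 0.1`, `p1 = 0.3`, `alpha <= 0.1`,
`power >= 0.8`) the search returns `(n1 = 7, r1 = 0, n = 18,
r_total = 4)` with exact type-I error 0.0893 and power 0.8000 — and the
frequentist futility boundary (`r1 = 0`) and success boundary
(`r_total = 4`) coincide with the boundaries induced by the Bayesian
PPoS interim rules and the Bayesian final rule at the same sizes, which
is exactly the sense in which one trial is simultaneously a frequentist
optimal two-stage design and a Bayesian monitored design. The
frequentist search allows no stage-1 efficacy stopping (the classic
two-stage formulation); efficacy stopping exists only in the
Bayesian-monitored evaluation, where `evaluate_monitored_design()`
computes the exact operating characteristics of the decision table
(efficacy stops counting as successes).

```{r design, eval = FALSE}
res <- search_designs(design_constraints(0.1, 0.3, 0.1, 0.8, n_max = 60))
res$optimal
bayesian_interim_rules(7, 18)
```

# The randomized comparison

For arms B (control) and C, responders are binomial with rates linked by
the log-odds ratio `delta = logit(p_C) - logit(p_B)`. The priors are
`Beta(1e-3, 1e-3)` on `p_B` and a Gaussian on `delta`. The Gaussian is
written `N(0, 1000)`; the package reads the 1000 as a **variance**
(sd about 31.6), the conventional N(mean, variance) notation, and
exposes `scale_type = "sd"` / `"precision"` for the other readings —
all three are effectively non-informative here, but a reproducible
default must pick one. Further research is recommended when
`P(OR > 1 | data) > 0.80`, strictly.

**Quadrature.** The posterior is integrated deterministically, never by
Monte Carlo, so decisions are bit-reproducible. The control rate is
integrated on the logit scale with the explicit Jacobian; naive grids
fail here because the near-improper prior concentrates mass within
`exp(-700)` of the boundaries. The inner integral therefore substitutes
the `Beta(a + x_B, b + n_B - x_B)` quantile transform — quadrature nodes
land exactly where that factor of the integrand puts its mass, however
extreme — using composite Gauss-Legendre panels refined dyadically
toward both endpoints of the unit interval (30 levels x 16 nodes by
default). The outer log-odds-ratio integral uses a trapezoid grid
(2001 points) whose extent adapts to the posterior: a coarse scan finds
the region within 45 log units of the mode, and the grid always brackets
`delta = 0` as a shared node so the tail probability splits exactly.

Each call reports a `normalization_diagnostic`: the largest relative
change in the normalizing constant and tail probability when the outer
grid is halved (Richardson-corrected for the trapezoid's O(h^2) rate)
or the inner panels are reduced from 16 to 12 nodes. If it exceeds
`quad_control()$tol` (default 1e-5) the call *errors* instead of
returning a silently inaccurate probability.

**A subtlety worth knowing.** The model is *not* exactly symmetric
under swapping the arms, because the Beta prior (with its Jacobian)
attaches to the control arm only. Symmetric data therefore give
`P(OR > 1)` close to, but not exactly, 0.5: the deviation is of order
(prior shape) x (posterior logit spread), about 1e-4 for data like
3/10 vs 3/10 and as large as 6e-3 for the degenerate 0/1 vs 0/1 case.
The test suite checks this against an independent importance-sampling
oracle rather than asserting exact symmetry. Relatedly, naive
Monte-Carlo cross-checks that draw `rbeta(1e-3, .)` variates are
silently wrong for all-zero data: double precision cannot represent the
half of that Beta's mass lying below 1e-300, truncating exactly the
region that carries the symmetric prior mass of `delta`. The suite's
oracle samples `logit(Beta)` exactly via the log-gamma representation
`Gamma(a) = Gamma(a + 1) * U^(1/a)`.

# The simulator

`simulate_trial()` generates the trial's structure at patient level:
arm A patients are registered (never randomized); the randomized cohort
is allocated by `permuted_block_randomization()` with block sizes drawn
uniformly from {2, 4} (the mixing distribution over block sizes is the
package's choice; only the sizes themselves are given by the design).
Each patient's two endpoint components are drawn jointly from a 2x2
table (`joint_binary_cells()`) with prescribed margins and a
Plackett-type cell odds ratio `endpoint_or` — chosen because only the
two marginal endpoint definitions and the at-least-one combination rule
are specified, leaving the dependence free; independence
(`endpoint_or = 1`) is the default. Per-arm component margins are
rescaled (preserving their ratio and the cell OR) so each arm's
composite rate `1 - p00` equals its configured true rate.

Defaults encode the emulated study conditions: 18 registered arm-A
patients, 22 randomized (the overall planned cohort of 40 minus arm A),
control rate 0.1 (the design's null) and arm A/C rate 0.3 (its target),
reference component margins 0.15/0.20 — a plausible split for a trial
whose responder definition deliberately lets the biological endpoint
rescue radiologically stable patients — and independent components.

Decorations (lesion-diameter sums, RECIST category, signed biomarker
percent change) are generated *consistently with* the drawn binary
outcomes and re-derived through `classify_recist()` /
`biological_response()`, so every record satisfies the composite rule
by construction and the suite verifies it record by record. The
direction of the 30% biomarker change ("either" vs "increase") and the
conjunctive-vs-disjunctive combination of the gene-expression and CD14
criteria are genuinely ambiguous in the endpoint definition; both are
flags (`biomarker_direction`, and `composite_biomarker_response(rule=)`),
neither reading asserted as the intended one.

What the simulator does *not* emulate: accrual timing, dropout,
toxicity, survival endpoints, nadir-tracked multi-scan RECIST, or assay
noise. Passing simulation tests certify the internal consistency of the
design calculations, not the behavior of the method on real trial data.

`estimate_operating_characteristics()` closes the loop: simulated
single-arm trials reproduce the exact success probabilities of the
monitored design within Monte-Carlo error (the suite uses 10^4-2x10^4
replicates, for which three standard errors is under a percentage
point), and simulated randomized trials exercise the full quadrature and
recommendation rule per replicate (default 200 replicates, with a
lighter quadrature resolution whose tolerance of 1e-3 is ample for a
0.80 threshold decision).

# Degenerate inputs and edge policies

* `x = 0` or `x = n` data: handled throughout in log space; posterior
  tails and predictive pmfs stay finite and normalized.
* `min_responders_final()` infeasibility: explicit `NA_integer_`.
* PPoS at full enrollment equals the 0/1 indicator of final success.
* `r_total <= r1` or `r_total > n`: rejected at construction.
* Decision tables are validated for monotonicity before operating
  characteristics are computed; non-monotone tables error.
* Degenerate endpoint margins (0 or 1) short-circuit to the forced 2x2
  table; a positive composite rate with both margins zero errors.

# Known limitations

* The exhaustive search is exact but O(n_max^4) in candidate designs
  (about 8 seconds at `n_max = 60`); no branch-and-bound pruning.
* The quadrature targets absolute accuracy ~1e-6 on posterior
  probabilities at default resolution; it is not adaptive beyond its
  extent selection, and pathological priors (sd far beyond ~100 on the
  log-OR) would need a larger `outer_points`.
* The credible interval is equal-tailed and interpolated linearly from
  the gridded CDF; quantile accuracy is ~grid spacing, ample for
  reporting but not for boundary-exact coverage studies.
* RECIST is reduced to single-assessment target-lesion rules.
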