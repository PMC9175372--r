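# ppostrial

Bayesian design and monitoring machinery for small phase II trials with
a binary (composite) response endpoint, written for trial statisticians
who need the design's operating characteristics to be exact, certified
and reproducible. The package covers:

* **Conjugate beta-binomial inference** for a single-arm response rate:
  `Beta(a, b)` prior plus `R ~ Binomial(N, p)` data, posterior tail
  probabilities, and beta-binomial posterior predictive distributions.
* **Final and interim decision rules**: success when
  `P(p > p0 | data) >= 0.90` (defaults `p0 = 0.1`, level 0.90), and
  interim monitoring by the posterior predictive probability of success
  (PPoS) — stop for futility when PPoS < 0.10, for efficacy when
  PPoS > 0.90.
* **Exhaustive two-stage design search** (Simon-type): enumerate every
  `(n1, r1, n, r_total)` up to `n_max`, evaluate exact binomial
  operating characteristics, and select the optimal design (minimum
  expected sample size under the null rate) and the minimax design
  (minimum total size) among those with type-I error `<= alpha` at `p0`
  and power `>= 1 - beta` at `p1`.
* **A randomized two-arm comparison**: binomial arms linked by a
  log-odds ratio `delta = logit(p_C) - logit(p_B)` with a
  `Beta(1e-3, 1e-3)` prior on the control rate and an `N(0, 1000)`
  (variance reading) prior on `delta`; `P(OR > 1 | data)` is computed by
  deterministic two-dimensional quadrature, and further research is
  recommended when it exceeds 0.80.
* **A patient-level trial simulator**: permuted-block 1:1 randomization
  (blocks of 2 and 4), two correlated binary co-primary endpoints
  (RECIST-style radiological response; a 30% biomarker change) combined
  by an at-least-one responder rule, and simulation-based operating
  characteristics that cross-validate the exact calculators.

See `vignettes/trial-design-methods.Rmd` for the models, numerical
choices and limitations.

## Worked example

```r
library(ppostrial)

# Two-stage design search under the trial's constraints
res <- search_designs(design_constraints(p0 = 0.1, p1 = 0.3,
                                         alpha_max = 0.1, power_min = 0.8,
                                         n_max = 60))
res
#> Optimal (min E[N] at p0): Two-stage design: n1 = 7, futility if <= 0 responders; n = 18, success if >= 4 total
#>   alpha = 0.0893, power = 0.8000, E[N|p0] = 12.74
#> Minimax (min n):          Two-stage design: n1 = 7, futility if <= 0 responders; n = 18, success if >= 4 total
#> 37955 admissible designs enumerated.

# Bayesian interim monitoring for that design
bayesian_interim_rules(7, 18)
#>   x1         ppos      decision
#> 1  0 5.944591e-05 stop-futility
#> 2  1 2.428656e-01      continue
#> 3  2 7.280735e-01      continue
#> 4  3 9.706047e-01 stop-efficacy
#> ...

# Final analysis with 4 responders out of 18
prob_rate_exceeds(update_posterior(beta_params(1e-3, 1e-3),
                                   binomial_data(4, 18)), 0.1)
#> [1] 0.917428    # >= 0.90, so the trial succeeds

# Randomized comparison, 2/10 vs 5/10
posterior_prob_or_gt1(two_arm_data(2, 10, 5, 10))
#> P(odds ratio > 1 | data) = 0.934236
#> log-odds ratio: mean 1.59, 95% CrI [-0.4471, 3.901]
#> quadrature diagnostic: 4.1e-06
```

The search's selected design enrolls 7 patients, stops if none respond,
otherwise enrolls to 18 and succeeds with 4+ responders; its exact
type-I error is 0.0893 and its exact power 0.8000. The interim PPoS
table shows the same stage-1 boundary (stop at 0 responders) emerging
from the Bayesian rules, so the frequentist and Bayesian descriptions
are one trial.

A command-line wrapper over the same functions ships in
`inst/cli/trialtool.R` with subcommands `design`, `interim`, `final`,
`compare`, `simulate` and `oc`:

```sh
Rscript inst/cli/trialtool.R interim --x1 1 --n1 7 --n-total 18
```

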