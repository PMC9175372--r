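# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: operating characteristics come from
# joint-outcome enumeration, predictive probabilities from literal
# enumeration of the future outcomes, and the two-arm posterior from
# self-normalized importance sampling.

# Exact OC of a two-stage futility design by enumerating every (x1, x2)
# joint outcome.
bf_two_stage_oc <- function(n1, r1, n, r_total, p) {
  n2 <- n - n1
  success <- 0; pet <- 0; en <- 0
  for (x1 in 0:n1) {
    p1 <- dbinom(x1, n1, p)
    if (x1 <= r1) {
      pet <- pet + p1
      en <- en + p1 * n1
    } else {
      en <- en + p1 * n
      for (x2 in 0:n2)
        if (x1 + x2 >= r_total) success <- success + p1 * dbinom(x2, n2, p)
    }
  }
  list(success_prob = success, pet = pet, expected_n = en)
}

# Same, but stage-1 behavior follows an arbitrary decision vector
# (one of "stop-futility"/"continue"/"stop-efficacy" per x1).
bf_monitored_oc <- function(decisions, n1, n, r_total, p) {
  n2 <- n - n1
  success <- 0; p_cont <- 0
  for (x1 in 0:n1) {
    p1 <- dbinom(x1, n1, p)
    d <- decisions[x1 + 1]
    if (d == "stop-efficacy") success <- success + p1
    if (d == "continue") {
      p_cont <- p_cont + p1
      for (x2 in 0:n2)
        if (x1 + x2 >= r_total) success <- success + p1 * dbinom(x2, n2, p)
    }
  }
  list(success_prob = success, pet = 1 - p_cont,
       expected_n = n1 + p_cont * n2)
}

# Beta-binomial pmf by numerical integration of the binomial likelihood
# against the Beta density (independent of the lbeta closed form).
bb_pmf_integrate <- function(a, b, m) {
  vapply(0:m, function(k)
    integrate(function(p) dbinom(k, m, p) * dbeta(p, a, b),
              0, 1, rel.tol = 1e-12)$value, numeric(1))
}

# PPoS by literal enumeration: for each possible number of future
# responders, test the final posterior statement directly.
bf_ppos <- function(a0, b0, x, n, n_total, rate_threshold = 0.1,
                    confidence = 0.9) {
  m <- n_total - n
  pmf <- bb_pmf_integrate(a0 + x, b0 + n - x, m)
  ok <- vapply(0:m, function(k) {
    tot <- x + k
    pbeta(rate_threshold, a0 + tot, b0 + n_total - tot,
          lower.tail = FALSE) >= confidence
  }, logical(1))
  sum(pmf[ok])
}

# logit(Beta(a, b)) draws via the log-gamma representation
# Gamma(a) =d Gamma(a + 1) * U^(1/a): keeps the deep tails that rbeta()
# underflows for near-improper shapes.
rlogit_beta <- function(n, a, b) {
  lg1 <- log(rgamma(n, a + 1)) + log(runif(n)) / a
  lg2 <- log(rgamma(n, b + 1)) + log(runif(n)) / b
  lg1 - lg2
}

# Self-normalized importance-sampling oracle for the two-arm posterior
# P(delta > 0 | data). Proposal: p_b ~ Beta(a + xb, b + nb - xb) (cancels
# the target's p_b terms exactly) and p_c ~ Beta(a + xc, b + nc - xc),
# leaving the effectively bounded weight
# w = pc^(-a) (1 - pc)^(-b) dnorm(delta; mu, sd).
is_oracle_prob_or_gt1 <- function(xb, nb, xc, nc, a = 1e-3, b = 1e-3,
                                  mu = 0, sd = sqrt(1000), n = 1e6,
                                  seed = 1) {
  set.seed(seed)
  tb <- rlogit_beta(n, a + xb, b + nb - xb)
  tc <- rlogit_beta(n, a + xc, b + nc - xc)
  delta <- tc - tb
  lw <- -a * plogis(tc, log.p = TRUE) - b * plogis(-tc, log.p = TRUE) +
    dnorm(delta, mu, sd, log = TRUE)
  w <- exp(lw - max(lw))
  z <- as.numeric(delta > 0)
  p <- sum(w * z) / sum(w)
  se <- sqrt(sum((w * (z - p))^2)) / sum(w)
  c(p = p, se = se, ess = sum(w)^2 / sum(w^2))
}
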