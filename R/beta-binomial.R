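## Conjugate beta-binomial machinery for a single-arm binary endpoint:
## posterior updates, posterior tail probabilities, beta-binomial posterior
## predictive distributions, and the trial's final-success and interim
## predictive-probability-of-success (PPoS) rules.

#' Shape parameters of a Beta distribution
#'
#' Container for the prior or posterior on a response probability. The
#' near-improper `beta_params(1e-3, 1e-3)` default used throughout the
#' package is a conventional non-informative choice that lets the data
#' dominate even at small sample sizes.
#'
#' @param a,b Positive shape parameters.
#' @return An object of class `beta_params` with fields `a` and `b`.
#' @examples
#' beta_params(1e-3, 1e-3)
#' @export
beta_params <- function(a, b) {
  assert_scalar_num(a, "a"); assert_scalar_num(b, "b")
  if (a <= 0 || b <= 0) stopf("Beta shapes must be positive, got (%g, %g)", a, b)
  structure(list(a = a, b = b), class = "beta_params")
}

#' @export
print.beta_params <- function(x, ...) {
  cat(sprintf("Beta(%g, %g) [mean %.4g]\n", x$a, x$b, x$a / (x$a + x$b)))
  invisible(x)
}

#' Observed binomial outcome
#'
#' @param x Number of responders observed, `0 <= x <= n`.
#' @param n Number of evaluable patients.
#' @return An object of class `binomial_data` with fields `x` and `n`.
#' @export
binomial_data <- function(x, n) {
  n <- assert_count(n, "n"); x <- assert_count(x, "x")
  if (x > n) stopf("responders x = %d exceeds evaluable n = %d", x, n)
  structure(list(x = x, n = n), class = "binomial_data")
}

#' Final success rule for a single-arm trial
#'
#' The trial declares success when the posterior probability that the
#' response rate exceeds `rate_threshold` is at least `confidence`.
#' Defaults encode the rule "90% posterior probability that the response
#' rate is greater than 0.1". Meeting the confidence level exactly counts
#' as success (non-strict comparison); see the package vignette.
#'
#' @param rate_threshold Response-rate threshold in (0, 1).
#' @param confidence Required posterior probability in (0, 1).
#' @return An object of class `success_rule`.
#' @export
success_rule <- function(rate_threshold = 0.1, confidence = 0.90) {
  assert_prob(rate_threshold, "rate_threshold")
  assert_prob(confidence, "confidence")
  structure(list(rate_threshold = rate_threshold, confidence = confidence),
            class = "success_rule")
}

#' Conjugate posterior update
#'
#' Beta prior plus binomial data gives the Beta posterior
#' `Beta(a + x, b + n - x)`. Inputs are not modified.
#'
#' @param prior A [beta_params()] prior.
#' @param data A [binomial_data()] observation.
#' @return The posterior as a [beta_params()] object.
#' @examples
#' update_posterior(beta_params(1e-3, 1e-3), binomial_data(4, 18))
#' @export
update_posterior <- function(prior, data) {
  stopifnot(inherits(prior, "beta_params"), inherits(data, "binomial_data"))
  beta_params(prior$a + data$x, prior$b + data$n - data$x)
}

#' Posterior probability that the response rate exceeds a threshold
#'
#' Computes `P(p > threshold)` for `p ~ Beta(a, b)`, i.e. one minus the
#' regularized incomplete beta function at `threshold`. Evaluated through
#' the upper-tail `pbeta()` routine so that near-boundary posteriors from
#' near-improper priors do not lose precision to cancellation.
#'
#' @param post A [beta_params()] posterior.
#' @param threshold Rate threshold in (0, 1).
#' @return A probability in `[0, 1]`.
#' @export
prob_rate_exceeds <- function(post, threshold) {
  stopifnot(inherits(post, "beta_params"))
  assert_prob(threshold, "threshold")
  stats::pbeta(threshold, post$a, post$b, lower.tail = FALSE)
}

#' Beta-binomial posterior predictive distribution
#'
#' Probability mass function of the number of responders among `m` future
#' patients when the response rate follows `Beta(a, b)`. Computed in log
#' space through the Polya product form (cumulative log rising
#' factorials) rather than `lbeta()` ratios: near-improper shapes keep
#' full precision and the pmf sums to 1 to better than 1e-13 even at
#' `m = 200`.
#'
#' @param post A [beta_params()] posterior.
#' @param m Number of future patients, `m >= 0`.
#' @return Numeric vector of length `m + 1`, the probabilities of
#'   0, 1, ..., m future responders (sums to 1).
#' @export
posterior_predictive_pmf <- function(post, m) {
  stopifnot(inherits(post, "beta_params"))
  m <- assert_count(m, "m")
  if (m == 0L) return(1)
  k <- 0:m
  a <- post$a; b <- post$b
  la <- c(0, cumsum(log(a + 0:(m - 1))))   # la[k+1] = log a^(k) rising
  lb <- c(0, cumsum(log(b + 0:(m - 1))))
  lab <- sum(log(a + b + 0:(m - 1)))
  exp(lchoose(m, k) + la[k + 1] + lb[m - k + 1] - lab)
}

#' Minimum responders needed for final success
#'
#' Smallest total responder count `r` out of `n_total` such that the
#' posterior `Beta(a + r, b + n_total - r)` satisfies the final success
#' rule. Because the posterior tail probability is increasing in the
#' responder count, totals at or above the returned boundary succeed and
#' totals below it fail.
#'
#' @param n_total Total number of evaluable patients, `n_total >= 1`.
#' @param prior A [beta_params()] prior.
#' @param rule A [success_rule()].
#' @return The integer boundary, or `NA_integer_` when no responder count
#'   up to `n_total` can satisfy the rule (no feasible boundary).
#' @examples
#' min_responders_final(18) # 4 under the default prior and rule
#' @export
min_responders_final <- function(n_total, prior = beta_params(1e-3, 1e-3),
                                 rule = success_rule()) {
  n_total <- assert_count(n_total, "n_total", min = 1L)
  stopifnot(inherits(prior, "beta_params"), inherits(rule, "success_rule"))
  r <- 0:n_total
  tail <- stats::pbeta(rule$rate_threshold, prior$a + r, prior$b + n_total - r,
                       lower.tail = FALSE)
  ok <- which(tail >= rule$confidence)
  if (!length(ok)) NA_integer_ else r[ok[1L]]
}

#' Posterior predictive probability of success (PPoS)
#'
#' Probability, under the current posterior, that the trial meets its
#' final success rule once `n_total` patients have been enrolled. The
#' remaining `n_total - interim$n` outcomes follow the beta-binomial
#' posterior predictive distribution, and final success is equivalent to
#' the total responder count reaching [min_responders_final()].
#'
#' @param prior A [beta_params()] prior.
#' @param interim A [binomial_data()] with the interim responder count.
#' @param n_total Planned total sample size, `>= interim$n`.
#' @param rule A [success_rule()].
#' @return A probability in `[0, 1]`. At `interim$n == n_total` this is
#'   the 0/1 indicator of final success.
#' @examples
#' predictive_prob_success(beta_params(1e-3, 1e-3), binomial_data(1, 7), 18)
#' @export
predictive_prob_success <- function(prior, interim, n_total,
                                    rule = success_rule()) {
  stopifnot(inherits(prior, "beta_params"), inherits(interim, "binomial_data"))
  n_total <- assert_count(n_total, "n_total", min = 1L)
  if (n_total < interim$n)
    stopf("n_total = %d is smaller than the interim sample size %d",
          n_total, interim$n)
  r_min <- min_responders_final(n_total, prior, rule)
  if (is.na(r_min)) return(0)
  need <- r_min - interim$x
  m <- n_total - interim$n
  if (need <= 0L) return(1)
  if (need > m) return(0)
  post <- update_posterior(prior, interim)
  pmf <- posterior_predictive_pmf(post, m)
  sum(pmf[(0:m) >= need])
}
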