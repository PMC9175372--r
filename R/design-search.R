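## Two-stage single-arm designs: exact binomial operating characteristics,
## exhaustive search for optimal (minimum expected sample size under the
## null) and minimax designs, and the Bayesian interim decision table
## built from the posterior predictive probability of success.

#' Constraints for the two-stage design search
#'
#' @param p0 Unacceptable ("null") response rate.
#' @param p1 Target ("alternative") response rate, `p1 > p0`.
#' @param alpha_max Maximum allowed probability of declaring success at `p0`.
#' @param power_min Minimum required probability of declaring success at `p1`.
#' @param n_max Largest total sample size searched.
#' @return An object of class `design_constraints`.
#' @export
design_constraints <- function(p0 = 0.1, p1 = 0.3, alpha_max = 0.1,
                               power_min = 0.8, n_max = 60L) {
  assert_prob(p0, "p0"); assert_prob(p1, "p1")
  if (p0 >= p1) stopf("p0 (%g) must be smaller than p1 (%g)", p0, p1)
  assert_prob(alpha_max, "alpha_max"); assert_prob(power_min, "power_min")
  n_max <- assert_count(n_max, "n_max", min = 2L)
  structure(list(p0 = p0, p1 = p1, alpha_max = alpha_max,
                 power_min = power_min, n_max = n_max),
            class = "design_constraints")
}

#' A two-stage design
#'
#' Enroll `n1` patients; stop for futility if at most `r1` respond
#' (`r1 = -1` disables the futility stop); otherwise enroll to `n` and
#' declare success if the total responder count reaches `r_total`.
#' Note the convention: `r_total` is the minimum total count that
#' *declares success*, one more than the largest "reject" count used by
#' formulations that state designs as "reject if at most r respond".
#'
#' @param n1 Stage-1 (interim) sample size.
#' @param r1 Stage-1 futility boundary (stop when stage-1 responders
#'   are `<= r1`); `-1` for no futility stopping.
#' @param n Total sample size, `n > n1`.
#' @param r_total Minimum total responders declaring success.
#' @return An object of class `two_stage_design`.
#' @export
two_stage_design <- function(n1, r1, n, r_total) {
  n1 <- assert_count(n1, "n1", min = 1L)
  n <- assert_count(n, "n", min = 2L)
  r1 <- assert_count(r1, "r1", min = -1L)
  r_total <- assert_count(r_total, "r_total")
  if (n1 >= n) stopf("need n1 < n, got n1 = %d, n = %d", n1, n)
  if (r1 > n1) stopf("futility boundary r1 = %d exceeds n1 = %d", r1, n1)
  if (r_total <= r1) stopf("need r1 < r_total, got r1 = %d, r_total = %d",
                           r1, r_total)
  if (r_total > n) stopf("r_total = %d exceeds n = %d: success unattainable",
                         r_total, n)
  structure(list(n1 = n1, r1 = r1, n = n, r_total = r_total),
            class = "two_stage_design")
}

#' @export
print.two_stage_design <- function(x, ...) {
  cat(sprintf(
    "Two-stage design: n1 = %d, futility if <= %d responders; n = %d, success if >= %d total\n",
    x$n1, x$r1, x$n, x$r_total))
  invisible(x)
}

#' Exact operating characteristics of a two-stage design
#'
#' Computes, by exact binomial tail sums, the probability of declaring
#' success, the probability of early termination (PET) and the expected
#' sample size at a given true response rate.
#'
#' @param design A [two_stage_design()].
#' @param p True response rate in (0, 1).
#' @return An object of class `operating_chars` with fields
#'   `success_prob`, `pet` and `expected_n`.
#' @examples
#' exact_operating_chars(two_stage_design(7, 0, 18, 4), 0.1)
#' @export
exact_operating_chars <- function(design, p) {
  stopifnot(inherits(design, "two_stage_design"))
  assert_prob(p, "p")
  n1 <- design$n1; n2 <- design$n - n1
  x1 <- seq.int(max(design$r1 + 1L, 0L), n1)
  need <- design$r_total - x1
  tail2 <- ifelse(need <= 0, 1,
                  stats::pbinom(need - 1, n2, p, lower.tail = FALSE))
  success <- sum(stats::dbinom(x1, n1, p) * tail2)
  pet <- if (design$r1 < 0) 0 else stats::pbinom(design$r1, n1, p)
  structure(list(success_prob = success, pet = pet,
                 expected_n = n1 + (1 - pet) * n2),
            class = "operating_chars")
}

#' @export
print.operating_chars <- function(x, ...) {
  cat(sprintf("P(success) = %.6g, PET = %.6g, E[N] = %.4g\n",
              x$success_prob, x$pet, x$expected_n))
  invisible(x)
}

#' Exhaustive search for admissible two-stage designs
#'
#' Enumerates every design `(n1, r1, n, r_total)` with `n <= n_max`,
#' keeps those whose exact type-I error at `p0` is at most `alpha_max`
#' and whose exact power at `p1` is at least `power_min`, and selects
#'
#' * the **optimal** design: smallest expected sample size at `p0`
#'   (ties broken by smaller `n`, then smaller `n1`, then larger
#'   `r_total`, i.e. the smallest attained type-I error), and
#' * the **minimax** design: smallest `n` (ties by smaller expected
#'   sample size at `p0`, then the same sequence).
#'
#' @param constraints A [design_constraints()].
#' @return An object of class `design_search`: a list with elements
#'   `feasible` (logical), `optimal` and `minimax`
#'   ([two_stage_design()]s, `NULL` if infeasible), and `admissible`, a
#'   data frame of all admissible designs ranked by expected sample size
#'   at `p0` with their exact `alpha`, `power`, `pet0` and `en0`.
#' @examples
#' \donttest{
#' search_designs(design_constraints(0.1, 0.3, 0.1, 0.8, n_max = 60))
#' }
#' @export
search_designs <- function(constraints = design_constraints()) {
  stopifnot(inherits(constraints, "design_constraints"))
  p0 <- constraints$p0; p1 <- constraints$p1
  rows <- vector("list", 2048L); nrows <- 0L
  for (n in 2:constraints$n_max) {
    for (n1 in 1:(n - 1L)) {
      n2 <- n - n1
      d0 <- stats::dbinom(0:n1, n1, p0)
      d1 <- stats::dbinom(0:n1, n1, p1)
      ## stage-2 upper tails indexed by needed responders 0..n
      t0 <- c(1, stats::pbinom(0:(n - 1L), n2, p0, lower.tail = FALSE))
      t1 <- c(1, stats::pbinom(0:(n - 1L), n2, p1, lower.tail = FALSE))
      ## need[x1+1, rt+1] = responders still required given x1 stage-1 hits
      need <- pmax(outer(0:n1, 0:n, function(x1, rt) rt - x1), 0L)
      A0 <- d0 * matrix(t0[need + 1L], n1 + 1L, n + 1L)
      A1 <- d1 * matrix(t1[need + 1L], n1 + 1L, n + 1L)
      ## success prob for futility boundary r1 = sum over x1 > r1:
      ## reverse cumulative sums down the stage-1 axis
      rc <- function(A) apply(A, 2L, function(col) rev(cumsum(rev(col))))
      S0 <- rc(A0); S1 <- rc(A1)   # row r1+2 <-> boundary r1 in -1..n1-1
      pet0 <- c(0, stats::pbinom(0:(n1 - 1L), n1, p0))
      for (r1 in -1:(n1 - 1L)) {
        a_row <- S0[r1 + 2L, ]; p_row <- S1[r1 + 2L, ]
        rt <- seq.int(max(r1 + 1L, 0L), n)
        keep <- a_row[rt + 1L] <= constraints$alpha_max &
                p_row[rt + 1L] >= constraints$power_min
        if (!any(keep)) next
        rt <- rt[keep]
        nrows <- nrows + 1L
        if (nrows > length(rows)) rows <- c(rows, vector("list", length(rows)))
        rows[[nrows]] <- data.frame(
          n1 = n1, r1 = r1, n = n, r_total = rt,
          alpha = a_row[rt + 1L], power = p_row[rt + 1L],
          pet0 = pet0[r1 + 2L],
          en0 = n1 + (1 - pet0[r1 + 2L]) * n2)
      }
    }
  }
  if (nrows == 0L) {
    out <- list(feasible = FALSE, optimal = NULL, minimax = NULL,
                admissible = data.frame(), constraints = constraints)
    return(structure(out, class = "design_search"))
  }
  adm <- do.call(rbind, rows[seq_len(nrows)])
  adm <- adm[order(adm$en0, adm$n, adm$n1, -adm$r_total, adm$r1), ]
  rownames(adm) <- NULL
  pick <- function(df) two_stage_design(df$n1[1L], df$r1[1L], df$n[1L],
                                        df$r_total[1L])
  mm <- adm[order(adm$n, adm$en0, adm$n1, -adm$r_total, adm$r1), ]
  structure(list(feasible = TRUE, optimal = pick(adm), minimax = pick(mm),
                 admissible = adm, constraints = constraints),
            class = "design_search")
}

#' @export
print.design_search <- function(x, ...) {
  if (!x$feasible) {
    cat(sprintf(
      "No admissible two-stage design with n <= %d meets alpha <= %g and power >= %g.\n",
      x$constraints$n_max, x$constraints$alpha_max, x$constraints$power_min))
    return(invisible(x))
  }
  cat("Optimal (min E[N] at p0): "); print(x$optimal)
  cat(sprintf("  alpha = %.4f, power = %.4f, E[N|p0] = %.2f\n",
              x$admissible$alpha[1L], x$admissible$power[1L],
              x$admissible$en0[1L]))
  cat("Minimax (min n):          "); print(x$minimax)
  cat(sprintf("%d admissible designs enumerated.\n", nrow(x$admissible)))
  invisible(x)
}

#' Bayesian interim decision table from the PPoS rule
#'
#' For every possible stage-1 responder count, computes the posterior
#' predictive probability of success (PPoS) at the planned total sample
#' size and classifies the interim decision: stop for futility when the
#' PPoS is strictly below `futility_cut`, stop for efficacy when it is
#' strictly above `efficacy_cut`, and continue otherwise (a PPoS exactly
#' at a cut continues). Defaults encode "stop for futility below a 10%
#' chance of success, stop for efficacy above a 90% chance of success".
#'
#' @param n1 Interim sample size.
#' @param n_total Planned total sample size, `> n1`.
#' @param prior A [beta_params()] prior on the response rate.
#' @param rule A [success_rule()] for the final analysis.
#' @param futility_cut,efficacy_cut PPoS cut-offs, `futility_cut <
#'   efficacy_cut`.
#' @return An object of class `interim_decision_table`: a data frame
#'   with columns `x1`, `ppos` and `decision` (one of `stop-futility`,
#'   `continue`, `stop-efficacy`), carrying `n1`, `n_total`, `r_total`
#'   and the cut-offs as attributes.
#' @examples
#' bayesian_interim_rules(7, 18)
#' @export
bayesian_interim_rules <- function(n1, n_total,
                                   prior = beta_params(1e-3, 1e-3),
                                   rule = success_rule(),
                                   futility_cut = 0.10, efficacy_cut = 0.90) {
  n1 <- assert_count(n1, "n1", min = 1L)
  n_total <- assert_count(n_total, "n_total", min = 2L)
  if (n1 >= n_total) stopf("need n1 < n_total, got %d >= %d", n1, n_total)
  assert_prob(futility_cut, "futility_cut", open = FALSE)
  assert_prob(efficacy_cut, "efficacy_cut", open = FALSE)
  if (futility_cut >= efficacy_cut)
    stopf("futility_cut (%g) must be below efficacy_cut (%g)",
          futility_cut, efficacy_cut)
  ppos <- vapply(0:n1, function(x1)
    predictive_prob_success(prior, binomial_data(x1, n1), n_total, rule),
    numeric(1))
  decision <- ifelse(ppos < futility_cut, "stop-futility",
                     ifelse(ppos > efficacy_cut, "stop-efficacy", "continue"))
  tab <- data.frame(x1 = 0:n1, ppos = ppos, decision = decision)
  ord <- match(decision, c("stop-futility", "continue", "stop-efficacy"))
  if (is.unsorted(ord))
    stopf("interim decisions are not monotone in the responder count")
  structure(tab, class = c("interim_decision_table", "data.frame"),
            n1 = n1, n_total = n_total,
            r_total = min_responders_final(n_total, prior, rule),
            prior = prior, rule = rule,
            futility_cut = futility_cut, efficacy_cut = efficacy_cut)
}

#' Stage-1 futility boundary induced by an interim decision table
#'
#' Monotonicity of the PPoS in the responder count means the futility
#' region is always of the form "stop when stage-1 responders are at most
#' r1", recovering a [two_stage_design()]-style boundary.
#'
#' @param rules An [bayesian_interim_rules()] table.
#' @return The integer boundary `r1` (`-1` when no count stops for
#'   futility).
#' @export
induced_futility_boundary <- function(rules) {
  stopifnot(inherits(rules, "interim_decision_table"))
  fut <- rules$x1[rules$decision == "stop-futility"]
  if (!length(fut)) -1L else max(fut)
}

#' Exact operating characteristics of a PPoS-monitored design
#'
#' Evaluates, by exact binomial enumeration, the design in which the
#' interim decision for each stage-1 responder count follows the given
#' decision table: efficacy stops count as success, futility stops as
#' failure, and trials that continue succeed when the total responder
#' count reaches `r_total`.
#'
#' @param rules An [bayesian_interim_rules()] table.
#' @param p True response rate in (0, 1).
#' @param n_total,r_total Total sample size and success boundary;
#'   default to the values carried by `rules`.
#' @return An `operating_chars` object; `pet` counts both futility and
#'   efficacy stops.
#' @export
evaluate_monitored_design <- function(rules, p,
                                      n_total = attr(rules, "n_total"),
                                      r_total = attr(rules, "r_total")) {
  stopifnot(inherits(rules, "interim_decision_table"))
  assert_prob(p, "p")
  if (is.na(r_total))
    stopf("no feasible final success boundary for this rule")
  n1 <- attr(rules, "n1")
  ord <- match(rules$decision, c("stop-futility", "continue", "stop-efficacy"))
  if (anyNA(ord) || is.unsorted(ord))
    stopf("decision table is not monotone in x1")
  n2 <- n_total - n1
  d1 <- stats::dbinom(rules$x1, n1, p)
  cont <- rules$decision == "continue"
  eff <- rules$decision == "stop-efficacy"
  need <- pmax(r_total - rules$x1, 0L)
  tail2 <- ifelse(need == 0L, 1,
                  stats::pbinom(need - 1L, n2, p, lower.tail = FALSE))
  success <- sum(d1[eff]) + sum(d1[cont] * tail2[cont])
  p_cont <- sum(d1[cont])
  structure(list(success_prob = success, pet = 1 - p_cont,
                 expected_n = n1 + p_cont * n2),
            class = "operating_chars")
}
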