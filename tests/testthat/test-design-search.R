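test_that("exact operating characteristics match joint-outcome enumeration", {
  # degenerate design that always declares success
  oc <- exact_operating_chars(two_stage_design(7, -1, 18, 0), 0.25)
  expect_equal(oc$success_prob, 1)
  expect_equal(oc$pet, 0)
  expect_equal(oc$expected_n, 18)

  # infeasible success boundary is rejected by the type invariants
  expect_error(two_stage_design(7, 0, 18, 19), "unattainable")
  expect_error(two_stage_design(7, 8, 18, 9), "exceeds")

  # the emulated trial's design
  d <- two_stage_design(7, 0, 18, 4)
  a <- exact_operating_chars(d, 0.1)$success_prob
  pw <- exact_operating_chars(d, 0.3)$success_prob
  expect_gt(a, 0.08); expect_lt(a, 0.10)
  expect_gte(pw, 0.79)

  # full oracle sweep: every legal design with n <= 12
  for (n in 2:12) for (n1 in 1:(n - 1)) for (r1 in -1:min(n1 - 1, 3)) {
    for (rt in max(r1 + 1, 0):n) {
      des <- two_stage_design(n1, r1, n, rt)
      for (p in c(0.17, 0.45)) {
        got <- exact_operating_chars(des, p)
        want <- bf_two_stage_oc(n1, r1, n, rt, p)
        expect_equal(got$success_prob, want$success_prob, tolerance = 1e-12)
        expect_equal(got$pet, want$pet, tolerance = 1e-12)
        expect_equal(got$expected_n, want$expected_n, tolerance = 1e-12)
      }
    }
  }
})

test_that("success probability increases in the true response rate", {
  d <- two_stage_design(7, 0, 18, 4)
  ps <- seq(0.02, 0.95, by = 0.03)
  sp <- vapply(ps, function(p) exact_operating_chars(d, p)$success_prob,
               numeric(1))
  expect_true(all(diff(sp) > 0))
})

test_that("the design search returns certified optimal and minimax designs", {
  # essentially unconstrained: the smallest legal design wins
  free <- search_designs(design_constraints(0.1, 0.3, 1 - 1e-9, 1e-9,
                                            n_max = 6))
  expect_true(free$feasible)
  expect_identical(free$optimal$n, 2L)
  expect_identical(free$optimal$n1, 1L)

  res <- search_designs(design_constraints(0.1, 0.3, 0.1, 0.8, n_max = 30))
  expect_true(res$feasible)
  expect_identical(res$optimal$n, 18L)
  expect_identical(res$optimal$n1, 7L)
  expect_identical(res$optimal$r_total, 4L)

  # certificates: the optimum is admissible and undominated on E[N | p0]
  oc0 <- exact_operating_chars(res$optimal, 0.1)
  oc1 <- exact_operating_chars(res$optimal, 0.3)
  expect_lte(oc0$success_prob, 0.1)
  expect_gte(oc1$success_prob, 0.8)
  expect_equal(min(res$admissible$en0), oc0$expected_n, tolerance = 1e-12)
  expect_true(all(res$admissible$alpha <= 0.1 + 1e-15))
  expect_true(all(res$admissible$power >= 0.8 - 1e-15))

  # minimax design attains the smallest admissible n
  expect_identical(res$minimax$n, as.integer(min(res$admissible$n)))

  # infeasible constraints are reported, not silently absorbed
  infeasible <- search_designs(design_constraints(0.1, 0.12, 0.01, 0.99,
                                                  n_max = 20))
  expect_false(infeasible$feasible)
  expect_null(infeasible$optimal)
})

test_that("interim PPoS rules form a monotone decision boundary", {
  rules <- bayesian_interim_rules(7, 18)
  expect_identical(rules$decision[rules$x1 == 0], "stop-futility")
  expect_identical(rules$decision[rules$x1 == 7], "stop-efficacy")
  expect_equal(rules$ppos[rules$x1 == 7], 1)
  ord <- match(rules$decision,
               c("stop-futility", "continue", "stop-efficacy"))
  expect_false(is.unsorted(ord))
  expect_identical(induced_futility_boundary(rules), 0L)

  # degenerate cuts: everything continues under strict comparisons
  lax <- bayesian_interim_rules(7, 18, futility_cut = 0, efficacy_cut = 1)
  expect_true(all(lax$decision == "continue"))

  expect_error(bayesian_interim_rules(7, 18, futility_cut = 0.9,
                                      efficacy_cut = 0.1), "below")
  expect_error(bayesian_interim_rules(18, 18), "n1 < n_total")
})

test_that("monitored-design OC is exact and reduces to the two-stage formula", {
  rules <- bayesian_interim_rules(7, 18)
  for (p in c(0.1, 0.3)) {
    got <- evaluate_monitored_design(rules, p)
    want <- bf_monitored_oc(rules$decision, 7, 18, 4, p)
    expect_equal(got$success_prob, want$success_prob, tolerance = 1e-12)
    expect_equal(got$pet, want$pet, tolerance = 1e-12)
    expect_equal(got$expected_n, want$expected_n, tolerance = 1e-12)
  }

  # an all-continue table reproduces the futility-free two-stage design
  lax <- bayesian_interim_rules(7, 18, futility_cut = 0, efficacy_cut = 1)
  for (p in c(0.07, 0.33)) {
    expect_equal(evaluate_monitored_design(lax, p)$success_prob,
                 exact_operating_chars(two_stage_design(7, -1, 18, 4),
                                       p)$success_prob,
                 tolerance = 1e-12)
  }

  # an all-futility table never declares success
  allfut <- structure(
    data.frame(x1 = 0:7, ppos = 0, decision = "stop-futility"),
    class = c("interim_decision_table", "data.frame"),
    n1 = 7L, n_total = 18L, r_total = 4L)
  expect_equal(evaluate_monitored_design(allfut, 0.3)$success_prob, 0)

  # non-monotone tables are rejected
  bad <- structure(
    data.frame(x1 = 0:7, ppos = 0.5,
               decision = c("continue", "stop-futility",
                            rep("continue", 6))),
    class = c("interim_decision_table", "data.frame"),
    n1 = 7L, n_total = 18L, r_total = 4L)
  expect_error(evaluate_monitored_design(bad, 0.3), "monotone")

  # determinism: identical inputs give bit-identical tables
  expect_identical(bayesian_interim_rules(7, 18), bayesian_interim_rules(7, 18))
})
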