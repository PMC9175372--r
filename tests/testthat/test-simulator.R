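test_that("joint endpoint cells recover margins and odds ratio", {
  # independence
  ind <- joint_binary_cells(0.3, 0.4, 1)
  expect_equal(ind$p11, 0.12, tolerance = 1e-12)

  # grid of margins and association strengths
  for (p1 in c(0.05, 0.3, 0.5, 0.9)) for (p2 in c(0.1, 0.4, 0.75)) {
    for (or in c(0.2, 1, 3, 10)) {
      cells <- joint_binary_cells(p1, p2, or)
      probs <- c(cells$p11, cells$p10, cells$p01, cells$p00)
      expect_true(all(probs >= -1e-15))
      expect_equal(sum(probs), 1, tolerance = 1e-12)
      expect_equal(cells$p11 + cells$p10, p1, tolerance = 1e-10)
      expect_equal(cells$p11 + cells$p01, p2, tolerance = 1e-10)
      if (or != 1)
        expect_equal(cells$p11 * cells$p00 / (cells$p10 * cells$p01), or,
                     tolerance = 1e-8)
    }
  }

  # comonotone limit
  lim <- joint_binary_cells(0.5, 0.5, 1e10)
  expect_equal(lim$p11, 0.5, tolerance = 1e-4)

  # degenerate margins short-circuit
  expect_equal(joint_binary_cells(1, 0.4, 7)$p11, 0.4)
  expect_error(joint_binary_cells(0.3, 0.4, -1), "positive")
})

test_that("permuted-block randomization is balanced and reproducible", {
  expect_setequal(permuted_block_randomization(2, 2, seed = 5), c("B", "C"))
  expect_error(permuted_block_randomization(10, c(2, 3)), "even")

  # prefix imbalance never exceeds half the largest block
  for (seed in 1:25) {
    a <- permuted_block_randomization(40, c(2, 4), seed = seed)
    imb <- cumsum(a == "B") - cumsum(a == "C")
    expect_lte(max(abs(imb)), 2)
    # completed blocks are exactly balanced
    drawn <- attr(a, "block_sizes_drawn")
    ends <- cumsum(drawn); ends <- ends[ends <= 40]
    expect_true(all(imb[ends] == 0))
  }

  expect_identical(permuted_block_randomization(20, seed = 42),
                   permuted_block_randomization(20, seed = 42))
  expect_false(identical(as.character(permuted_block_randomization(20, seed = 42)),
                         as.character(permuted_block_randomization(20, seed = 43))))
})

test_that("lesion-sum categorization applies the response thresholds", {
  expect_identical(classify_recist(100, 70), "PR")    # -30% boundary
  expect_identical(classify_recist(100, 120), "PD")   # +20% and +20 mm
  expect_identical(classify_recist(100, 115), "SD")
  expect_identical(classify_recist(100, 0), "CR")
  expect_identical(classify_recist(100, 50, new_lesions = TRUE), "PD")
  # +20% but under the 5 mm absolute minimum stays SD
  expect_identical(classify_recist(20, 24), "SD")
  expect_error(classify_recist(-3, 10), "positive")
  expect_error(classify_recist(100, -1), "non-negative")
})

test_that("biomarker response reads the 30% change per the direction flag", {
  expect_true(biological_response(100, 130))
  expect_false(biological_response(100, 125))
  expect_true(biological_response(100, 70))
  expect_false(biological_response(100, 70, direction = "increase"))
  expect_true(biological_response(100, 130, direction = "increase"))
  expect_error(biological_response(0, 10), "positive")

  # conjunctive vs disjunctive combination of the two assay criteria
  expect_true(composite_biomarker_response(100, 135, 100, 105,
                                           rule = "either"))
  expect_false(composite_biomarker_response(100, 135, 100, 105,
                                            rule = "both"))
  expect_true(composite_biomarker_response(100, 135, 100, 65, rule = "both"))
})

test_that("simulated trials honor the composite responder rule and seeds", {
  cfg <- simulation_config(seed = 11)
  pat <- simulate_trial(cfg)
  expect_identical(nrow(pat), 40L)
  expect_identical(sum(pat$arm == "A"), 18L)
  expect_lte(abs(sum(pat$arm == "B") - sum(pat$arm == "C")), 2L)
  expect_identical(pat$composite_responder,
                   pat$radiological_response | pat$biological_response)
  expect_identical(pat$radiological_response,
                   pat$radiological_category %in% c("CR", "PR"))
  expect_identical(pat$biological_response,
                   abs(pat$biological_change_pct) >= 30)
  # the decorated measurements re-derive the recorded category
  expect_identical(classify_recist(pat$baseline_sum_mm, pat$week6_sum_mm,
                                   pat$new_lesions),
                   pat$radiological_category)

  # byte-identical under the same seed, different otherwise
  expect_identical(simulate_trial(cfg), simulate_trial(cfg))
  expect_false(identical(simulate_trial(simulation_config(seed = 12)), pat))

  # degenerate rates
  none <- simulate_trial(simulation_config(true_rate_a = 0, true_rate_b = 0,
                                           true_rate_c = 0, seed = 2))
  expect_identical(sum(none$composite_responder), 0L)
  all_resp <- simulate_trial(simulation_config(true_rate_a = 1,
                                               true_rate_b = 1,
                                               true_rate_c = 1, seed = 2))
  expect_true(all(all_resp$composite_responder))

  # arm C rate induced from a true log-odds ratio
  cfg_or <- simulation_config(true_rate_c = NULL, true_log_or = 0)
  expect_equal(cfg_or$true_rate_c, cfg_or$true_rate_b)
})

test_that("empirical responder fraction matches the closed-form cells", {
  cells <- joint_binary_cells(0.15, 0.20, 2)
  rate <- 1 - cells$p00
  n <- 1e5
  pat <- simulate_trial(simulation_config(
    n_arm_a = n, n_randomized = 2, true_rate_a = rate,
    p_radiological = 0.15, p_biological = 0.20, endpoint_or = 2, seed = 31))
  a <- pat[pat$arm == "A", ]
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(mean(a$composite_responder) - rate), 3 * se)
  # component margins are reproduced too
  se1 <- sqrt(0.15 * 0.85 / n); se2 <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(mean(a$radiological_response) - 0.15), 3 * se1)
  expect_lt(abs(mean(a$biological_response) - 0.20), 3 * se2)
})

test_that("simulated operating characteristics match the exact calculations", {
  rules <- bayesian_interim_rules(7, 18)
  for (p in c(0.1, 0.3)) {
    cfg <- simulation_config(true_rate_a = p, n_reps = 20000, seed = 17)
    oc <- estimate_operating_characteristics(cfg, rules,
                                             include_randomized = FALSE)
    exact <- evaluate_monitored_design(rules, p)$success_prob
    expect_lt(abs(oc$arm_a$success_rate - exact), 3 * oc$arm_a$se)
  }
})

test_that("no systematic excess of recommendations under a null odds ratio", {
  cfg <- simulation_config(true_rate_b = 0.3, true_rate_c = 0.3,
                           n_reps = 1, n_reps_randomized = 120, seed = 23)
  reps <- cfg$n_reps_randomized
  # count reps whose posterior favors C (prob > 0.8) vs favors B (< 0.2);
  # under the null these are exchangeable up to the prior's small asymmetry
  probs <- withr::with_seed(cfg$seed, vapply(seq_len(reps), function(i) {
    alloc <- permuted_block_randomization(cfg$n_randomized, cfg$block_sizes)
    nb <- sum(alloc == "B"); nc <- sum(alloc == "C")
    posterior_prob_or_gt1(
      two_arm_data(rbinom(1, nb, 0.3), nb, rbinom(1, nc, 0.3), nc),
      control = quad_control(inner_levels = 20, inner_nodes = 8,
                             outer_points = 601, tol = 1e-3))$prob_or_gt_1
  }, numeric(1)))
  up <- sum(probs > 0.8); down <- sum(probs < 0.2)
  expect_gt(binom.test(up, up + down, 0.5)$p.value, 1e-3)
})
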