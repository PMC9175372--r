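## Synthetic trial generator: permuted-block randomization, correlated
## binary co-primary endpoints (radiological CR/PR and a >= 30% biomarker
## change) combined by an at-least-one responder rule, plus
## simulation-based operating characteristics that cross-validate the
## exact calculations.

#' Configuration for the trial simulator
#'
#' Defaults encode the emulated study: a registered single-agent arm A
#' with the two-stage design's total of 18 patients, and 22 patients
#' randomized 1:1 between a control arm B and an experimental arm C in
#' permuted blocks of sizes 2 and 4. True composite response rates
#' default to the design's null rate (0.1) on the control arm and its
#' target rate (0.3) on arms A and C. The composite endpoint is built
#' from two binary components whose reference marginal probabilities
#' (`p_radiological`, `p_biological`) and association odds ratio
#' (`endpoint_or`, 1 = independence) define its dependence structure;
#' per-arm component marginals are rescaled so the composite rate
#' `1 - p00` matches each arm's true rate.
#'
#' @param n_arm_a Number of registered arm-A patients.
#' @param n_randomized Number of patients randomized between B and C.
#' @param true_rate_a,true_rate_b True composite responder rates for the
#'   registered and control arms.
#' @param true_rate_c True composite rate for arm C, or `NULL` to induce
#'   it from `true_log_or` applied to `true_rate_b`.
#' @param true_log_or Log-odds ratio of arm C versus B, used when
#'   `true_rate_c` is `NULL`.
#' @param p_radiological,p_biological Reference marginal probabilities
#'   of the radiological (CR/PR) and biological (>= 30% biomarker
#'   change) components.
#' @param endpoint_or Association odds ratio between the two components.
#' @param block_sizes Permuted-block sizes (even positive integers).
#' @param seed Integer seed; every simulation is reproducible from it.
#' @param n_reps Replicates for operating-characteristic runs.
#' @param n_reps_randomized Replicates for the randomized-comparison
#'   operating characteristics (each needs a posterior quadrature, so
#'   the default is smaller).
#' @param biomarker_direction Passed to [biological_response()] when
#'   decorating records: `"either"` counts a 30% change in either
#'   direction, `"increase"` only increases.
#' @param cr_fraction Fraction of radiological responders decorated as
#'   complete (rather than partial) responses.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_arm_a = 18L, n_randomized = 22L,
                              true_rate_a = 0.3, true_rate_b = 0.1,
                              true_rate_c = 0.3, true_log_or = NULL,
                              p_radiological = 0.15, p_biological = 0.20,
                              endpoint_or = 1, block_sizes = c(2L, 4L),
                              seed = 1L, n_reps = 1000L,
                              n_reps_randomized = 200L,
                              biomarker_direction = c("either", "increase"),
                              cr_fraction = 0.15) {
  n_arm_a <- assert_count(n_arm_a, "n_arm_a")
  n_randomized <- assert_count(n_randomized, "n_randomized")
  for (nm in c("true_rate_a", "true_rate_b"))
    assert_prob(get(nm), nm, open = FALSE)
  if (is.null(true_rate_c)) {
    if (is.null(true_log_or))
      stopf("supply either true_rate_c or true_log_or")
    assert_scalar_num(true_log_or, "true_log_or")
    true_rate_c <- stats::plogis(stats::qlogis(true_rate_b) + true_log_or)
  }
  assert_prob(true_rate_c, "true_rate_c", open = FALSE)
  assert_prob(p_radiological, "p_radiological", open = FALSE)
  assert_prob(p_biological, "p_biological", open = FALSE)
  assert_scalar_num(endpoint_or, "endpoint_or")
  if (endpoint_or <= 0) stopf("endpoint_or must be positive")
  if (any(block_sizes <= 0) || any(block_sizes %% 2 != 0))
    stopf("block sizes must be positive even integers")
  assert_prob(cr_fraction, "cr_fraction", open = FALSE)
  structure(list(n_arm_a = n_arm_a, n_randomized = n_randomized,
                 true_rate_a = true_rate_a, true_rate_b = true_rate_b,
                 true_rate_c = true_rate_c,
                 p_radiological = p_radiological,
                 p_biological = p_biological, endpoint_or = endpoint_or,
                 block_sizes = as.integer(block_sizes),
                 seed = as.integer(seed),
                 n_reps = assert_count(n_reps, "n_reps"),
                 n_reps_randomized = assert_count(n_reps_randomized,
                                                  "n_reps_randomized"),
                 biomarker_direction = match.arg(biomarker_direction),
                 cr_fraction = cr_fraction),
            class = "simulation_config")
}

#' Joint distribution of two correlated binary endpoints
#'
#' Unique 2x2 cell table with the given marginal probabilities and cell
#' odds ratio `(p11 p00) / (p10 p01)` (a Plackett-type construction):
#' the admissible root of the defining quadratic. Degenerate margins (0
#' or 1) short-circuit to the forced table.
#'
#' @param p1,p2 Marginal probabilities of the two components.
#' @param or_assoc Association odds ratio, `> 0` (1 = independence).
#' @return An object of class `joint_binary_cells` with fields `p11`,
#'   `p10`, `p01`, `p00`.
#' @examples
#' joint_binary_cells(0.3, 0.4, 3)
#' @export
joint_binary_cells <- function(p1, p2, or_assoc) {
  assert_prob(p1, "p1", open = FALSE); assert_prob(p2, "p2", open = FALSE)
  assert_scalar_num(or_assoc, "or_assoc")
  if (or_assoc <= 0) stopf("or_assoc must be positive")
  degenerate <- p1 %in% c(0, 1) || p2 %in% c(0, 1)
  p11 <- if (degenerate || or_assoc == 1) {
    p1 * p2
  } else {
    ## roots of (or-1) p11^2 - S p11 + or p1 p2 = 0, S = 1 + (p1+p2)(or-1)
    S <- 1 + (p1 + p2) * (or_assoc - 1)
    disc <- sqrt(S^2 - 4 * or_assoc * (or_assoc - 1) * p1 * p2)
    roots <- (S + c(-1, 1) * disc) / (2 * (or_assoc - 1))
    lo <- max(0, p1 + p2 - 1); hi <- min(p1, p2)
    adm <- roots[roots >= lo - 1e-12 & roots <= hi + 1e-12]
    if (!length(adm)) stopf("no admissible cell table (internal error)")
    min(max(adm[1L], lo), hi)
  }
  structure(list(p11 = p11, p10 = p1 - p11, p01 = p2 - p11,
                 p00 = 1 - p1 - p2 + p11),
            class = "joint_binary_cells")
}

## Scale the reference component margins so the composite rate
## 1 - p00 hits `target` while preserving their ratio and the cell OR.
component_margins_for_rate <- function(target, p1, p2, or_assoc) {
  if (target <= 0) return(c(0, 0))
  if (p1 == 0 && p2 == 0)
    stopf("cannot reach a positive responder rate with both component margins 0")
  composite <- function(t) {
    cells <- joint_binary_cells(min(t * p1, 1), min(t * p2, 1), or_assoc)
    1 - cells$p00
  }
  t_hi <- 1 / max(p1, p2)
  if (composite(t_hi) < target) return(c(min(t_hi * p1, 1), min(t_hi * p2, 1)))
  t <- stats::uniroot(function(t) composite(t) - target, c(1e-12, t_hi),
                      tol = 1e-12)$root
  c(t * p1, t * p2)
}

#' Permuted-block 1:1 randomization sequence
#'
#' Builds an allocation sequence over arms B and C from blocks whose
#' sizes are drawn uniformly from `block_sizes`; each block is a random
#' permutation of an equal number of B and C assignments. The sequence
#' is truncated to `n`, so only the final block can be incomplete, and
#' any prefix imbalance is at most half the largest block size.
#'
#' @param n Number of patients to allocate.
#' @param block_sizes Even positive block sizes (default `c(2, 4)`).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return Character vector of `"B"`/`"C"` labels with attribute
#'   `block_sizes_drawn`.
#' @export
permuted_block_randomization <- function(n, block_sizes = c(2L, 4L),
                                         seed = NULL) {
  n <- assert_count(n, "n", min = 1L)
  if (any(block_sizes <= 0) || any(block_sizes %% 2 != 0))
    stopf("block sizes must be positive even integers")
  with_seed_if(seed, {
    alloc <- character(0); drawn <- integer(0)
    while (length(alloc) < n) {
      bs <- block_sizes[sample.int(length(block_sizes), 1L)]
      alloc <- c(alloc, sample(rep(c("B", "C"), bs / 2L)))
      drawn <- c(drawn, bs)
    }
    structure(alloc[seq_len(n)], block_sizes_drawn = drawn)
  })
}

#' RECIST-style response categorization from target-lesion sums
#'
#' Single-assessment reduction of the RECIST 1.1 target-lesion rules:
#' progressive disease (PD) for new lesions or a >= 20% and >= 5 mm
#' increase in the sum of target-lesion diameters, complete response
#' (CR) for disappearance, partial response (PR) for a >= 30% decrease,
#' stable disease (SD) otherwise. Nadir tracking across serial scans and
#' non-target lesions are deliberately out of scope. Vectorized.
#'
#' @param baseline_sum_mm Baseline sum of target-lesion diameters (> 0).
#' @param current_sum_mm Current sum (>= 0).
#' @param new_lesions Logical; any new lesions?
#' @return Character vector with values in `CR`, `PR`, `SD`, `PD`.
#' @examples
#' classify_recist(100, 70)  # "PR"
#' @export
classify_recist <- function(baseline_sum_mm, current_sum_mm,
                            new_lesions = FALSE) {
  k <- max(length(baseline_sum_mm), length(current_sum_mm), length(new_lesions))
  base <- rep_len(baseline_sum_mm, k)
  cur <- rep_len(current_sum_mm, k)
  nl <- rep_len(as.logical(new_lesions), k)
  if (any(!is.finite(base)) || any(base <= 0))
    stopf("baseline_sum_mm must be positive")
  if (any(!is.finite(cur)) || any(cur < 0))
    stopf("current_sum_mm must be non-negative")
  change <- (cur - base) / base
  ifelse(nl | (change >= 0.20 & cur - base >= 5), "PD",
         ifelse(cur == 0, "CR",
                ifelse(change <= -0.30, "PR", "SD")))
}

#' Biological (biomarker) response from pre/post scores
#'
#' A biomarker endpoint is met when the score changes by at least
#' `threshold_pct` percent of its pre-treatment value. The direction of
#' a pharmacodynamic "30% change" is ambiguous for an immune-activation
#' readout, so both readings are available: `"either"` (default)
#' accepts a change in either direction, `"increase"` only an increase.
#' Vectorized.
#'
#' @param pre_score Pre-treatment score (> 0).
#' @param post_score Post-treatment score (>= 0).
#' @param threshold_pct Percent-change threshold (default 30).
#' @param direction `"either"` or `"increase"`.
#' @return Logical vector.
#' @export
biological_response <- function(pre_score, post_score, threshold_pct = 30,
                                direction = c("either", "increase")) {
  direction <- match.arg(direction)
  k <- max(length(pre_score), length(post_score))
  pre <- rep_len(pre_score, k); post <- rep_len(post_score, k)
  if (any(!is.finite(pre)) || any(pre <= 0))
    stopf("pre_score must be positive")
  if (any(!is.finite(post)) || any(post < 0))
    stopf("post_score must be non-negative")
  rel <- (post - pre) / pre
  if (direction == "either") abs(rel) >= threshold_pct / 100
  else rel >= threshold_pct / 100
}

#' Composite biomarker endpoint from two assay criteria
#'
#' Combines a gene-expression criterion and a macrophage (CD14+)
#' criterion, each a >= 30% change per [biological_response()]. Whether
#' the biological endpoint requires both criteria or either one is left
#' open by the endpoint definition, so the combination rule is a flag.
#'
#' @param gene_pre,gene_post,cd14_pre,cd14_post Assay scores.
#' @param threshold_pct,direction Passed to [biological_response()].
#' @param rule `"either"` or `"both"`.
#' @return Logical vector.
#' @export
composite_biomarker_response <- function(gene_pre, gene_post, cd14_pre,
                                         cd14_post, threshold_pct = 30,
                                         direction = c("either", "increase"),
                                         rule = c("either", "both")) {
  rule <- match.arg(rule)
  direction <- match.arg(direction)
  g <- biological_response(gene_pre, gene_post, threshold_pct, direction)
  m <- biological_response(cd14_pre, cd14_post, threshold_pct, direction)
  if (rule == "either") g | m else g & m
}

## Draw one arm's patient component outcomes and decorations.
simulate_arm <- function(arm, ids, rate, config) {
  k <- length(ids)
  if (k == 0L)
    return(data.frame(patient_id = integer(0), arm = character(0),
                      baseline_sum_mm = numeric(0), week6_sum_mm = numeric(0),
                      new_lesions = logical(0),
                      radiological_category = character(0),
                      radiological_response = logical(0),
                      biological_change_pct = numeric(0),
                      biological_response = logical(0),
                      composite_responder = logical(0)))
  margins <- component_margins_for_rate(rate, config$p_radiological,
                                        config$p_biological,
                                        config$endpoint_or)
  cells <- joint_binary_cells(margins[1L], margins[2L], config$endpoint_or)
  cell <- sample.int(4L, k, replace = TRUE,
                     prob = c(cells$p11, cells$p10, cells$p01, cells$p00))
  rad <- cell %in% c(1L, 2L)
  bio <- cell %in% c(1L, 3L)
  ## decorate with measurements consistent with the binary outcomes
  baseline <- round(stats::runif(k, 30, 120), 1)
  is_cr <- rad & stats::runif(k) < config$cr_fraction
  shrink <- stats::runif(k, 0.30, 0.95)
  nonresp_pd <- !rad & stats::runif(k) < 0.35
  grow <- stats::runif(k, 0.20, 0.60)
  sd_change <- stats::runif(k, -0.295, 0.195)
  week6 <- ifelse(rad, ifelse(is_cr, 0, round(baseline * (1 - shrink), 1)),
                  ifelse(nonresp_pd, round(baseline * (1 + grow), 1),
                         round(baseline * (1 + sd_change), 1)))
  new_lesions <- nonresp_pd & stats::runif(k) < 0.5
  category <- classify_recist(baseline, week6, new_lesions)
  sign <- ifelse(config$biomarker_direction == "either",
                 ifelse(stats::runif(k) < 0.5, -1, 1), 1)
  mag <- ifelse(bio, stats::runif(k, 30, 90), stats::runif(k, 0, 29.5))
  bio_pct <- round(sign * mag, 1)
  data.frame(patient_id = ids, arm = arm,
             baseline_sum_mm = baseline, week6_sum_mm = week6,
             new_lesions = new_lesions,
             radiological_category = category,
             radiological_response = category %in% c("CR", "PR"),
             biological_change_pct = bio_pct,
             biological_response = bio,
             composite_responder = rad | bio)
}

#' Simulate one synthetic trial
#'
#' Generates a patient table for the emulated trial structure: arm A
#' patients are registered (never randomized); the remaining patients
#' are allocated to arms B and C by [permuted_block_randomization()].
#' Each patient's radiological and biological component outcomes are
#' drawn jointly from [joint_binary_cells()] at the arm's rescaled
#' margins, and the composite responder flag applies the
#' at-least-one-of rule. Lesion measurements and biomarker changes are
#' decorated consistently with the drawn binary outcomes. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A data frame of class `trial_patients`, one row per patient,
#'   with the generating `config` attached as an attribute.
#' @examples
#' head(simulate_trial(simulation_config(seed = 7)))
#' @export
simulate_trial <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed_if(config$seed, {
    alloc <- permuted_block_randomization(max(config$n_randomized, 1L),
                                          config$block_sizes, seed = NULL)
    alloc <- alloc[seq_len(config$n_randomized)]
    ids_a <- seq_len(config$n_arm_a)
    ids_r <- config$n_arm_a + seq_len(config$n_randomized)
    out <- rbind(
      simulate_arm("A", ids_a, config$true_rate_a, config),
      simulate_arm("B", ids_r[alloc == "B"], config$true_rate_b, config),
      simulate_arm("C", ids_r[alloc == "C"], config$true_rate_c, config))
    out <- out[order(out$patient_id), ]
    rownames(out) <- NULL
    structure(out, class = c("trial_patients", "data.frame"),
              config = config,
              block_sizes_drawn = attr(alloc, "block_sizes_drawn"))
  })
}

#' Simulation-based operating characteristics
#'
#' Cross-validates the exact calculations by simulation. For the
#' single-arm design, `n_reps` trials are simulated at the configured
#' true arm-A rate: stage-1 responder counts are drawn, the interim
#' decision table (or the design's futility boundary) is applied, and
#' continuing trials are completed and judged against the final success
#' boundary. For the randomized comparison, `n_reps_randomized` trials
#' draw block-randomized arm sizes and responder counts at the
#' configured B/C rates, run the posterior quadrature, and apply the
#' recommendation rule. Empirical frequencies carry binomial Monte
#' Carlo standard errors.
#'
#' @param config A [simulation_config()].
#' @param rules An [bayesian_interim_rules()] table or a
#'   [two_stage_design()] governing the single-arm trial.
#' @param priors A [comparison_priors()] for the B/C posterior.
#' @param recommend_threshold Threshold for
#'   [recommend_further_research()].
#' @param include_randomized Set `FALSE` to skip the (slower)
#'   randomized-comparison simulation.
#' @param quad A [quad_control()] used per replicate (the default here
#'   is lighter than the single-analysis default).
#' @return A list of class `oc_report` with components `arm_a`
#'   (`rate`, `success_rate`, `se`, `n_reps`) and `randomized`
#'   (`recommend_rate`, `se`, `n_reps`), or `NULL` entries where
#'   skipped.
#' @export
estimate_operating_characteristics <- function(
    config = simulation_config(), rules = bayesian_interim_rules(7, 18),
    priors = comparison_priors(), recommend_threshold = 0.80,
    include_randomized = TRUE,
    quad = quad_control(inner_levels = 20L, inner_nodes = 8L,
                        outer_points = 601L, tol = 1e-3)) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed_if(config$seed, {
    arm_a <- NULL
    if (config$n_reps >= 1L) {
      p <- config$true_rate_a
      if (inherits(rules, "interim_decision_table")) {
        n1 <- attr(rules, "n1"); n_tot <- attr(rules, "n_total")
        r_tot <- attr(rules, "r_total")
        dec <- rules$decision
      } else if (inherits(rules, "two_stage_design")) {
        n1 <- rules$n1; n_tot <- rules$n; r_tot <- rules$r_total
        dec <- ifelse(0:n1 <= rules$r1, "stop-futility", "continue")
      } else stopf("'rules' must be an interim decision table or design")
      x1 <- stats::rbinom(config$n_reps, n1, p)
      d <- dec[x1 + 1L]
      x2 <- stats::rbinom(config$n_reps, n_tot - n1, p)
      success <- d == "stop-efficacy" |
        (d == "continue" & x1 + x2 >= r_tot)
      phat <- mean(success)
      arm_a <- data.frame(rate = p, success_rate = phat,
                          se = sqrt(phat * (1 - phat) / config$n_reps),
                          n_reps = config$n_reps)
    }
    randomized <- NULL
    if (include_randomized && config$n_reps_randomized >= 1L) {
      rec <- vapply(seq_len(config$n_reps_randomized), function(i) {
        alloc <- permuted_block_randomization(config$n_randomized,
                                              config$block_sizes, seed = NULL)
        nb <- sum(alloc == "B"); nc <- sum(alloc == "C")
        xb <- stats::rbinom(1L, nb, config$true_rate_b)
        xc <- stats::rbinom(1L, nc, config$true_rate_c)
        post <- posterior_prob_or_gt1(two_arm_data(xb, nb, xc, nc), priors,
                                      control = quad)
        recommend_further_research(post, recommend_threshold)
      }, logical(1))
      phat <- mean(rec)
      randomized <- data.frame(
        recommend_rate = phat,
        se = sqrt(phat * (1 - phat) / config$n_reps_randomized),
        n_reps = config$n_reps_randomized)
    }
    structure(list(arm_a = arm_a, randomized = randomized, config = config),
              class = "oc_report")
  })
}

#' @export
print.oc_report <- function(x, ...) {
  if (!is.null(x$arm_a))
    cat(sprintf("Arm A: P(success | p = %g) = %.4f (SE %.4f, %d reps)\n",
                x$arm_a$rate, x$arm_a$success_rate, x$arm_a$se,
                x$arm_a$n_reps))
  if (!is.null(x$randomized))
    cat(sprintf("B/C: P(recommend) = %.4f (SE %.4f, %d reps)\n",
                x$randomized$recommend_rate, x$randomized$se,
                x$randomized$n_reps))
  invisible(x)
}
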