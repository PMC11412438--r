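unc_design <- function(threshold = threshold_spec("multi_arm", lambda = 0.63, gamma = 1)) {
  design_spec(K = 3, N = 60, schedule = c(15, 30, 45, 60),
              phi_eff = 0.45, phi_tox = 0.30,
              prior = c(0.15, 0.30, 0.15, 0.40), threshold = threshold)
}

test_that("accrual schedules follow the plan", {
  d <- unc_design()
  expect_equal(build_schedule(d, accrual_plan("planned"))[, 2], c(15L, 30L, 45L, 60L))
  expect_equal(build_schedule(d, accrual_plan("psi_shaped", psi = 1))[, 1],
               c(15L, 30L, 45L, 60L))
  # front-loaded accrual, round half to even
  expect_equal(build_schedule(d, accrual_plan("psi_shaped", psi = 0.25))[, 1],
               c(42L, 50L, 56L, 60L))
  expect_equal(build_schedule(d, accrual_plan("reduced_N", reduced_N = 20))[, 1],
               c(5L, 10L, 15L, 20L))
  set.seed(1)
  expect_equal(build_schedule(d, accrual_plan("imbalanced", u = 0)),
               build_schedule(d, accrual_plan("planned")))
  set.seed(2)
  sc <- build_schedule(d, accrual_plan("imbalanced", u = 3))
  expect_true(all(abs(sc - c(15, 30, 45, 60)) <= 3 * row(sc)))
  expect_true(all(apply(sc, 2, function(x) all(diff(x) > 0))))
  expect_error(build_schedule(d, accrual_plan("reduced_N", reduced_N = 80)), "exceeds")
})

test_that("cohort sampling matches the multinomial outcome model", {
  expect_equal(unname(sample_cohort(outcome_probs(0.25, 0.25, 0.25, 0.25), 0)),
               rep(0L, 4))
  expect_equal(unname(sample_cohort(outcome_probs(1, 0, 0, 0), 7)), c(7L, 0L, 0L, 0L))
  set.seed(3)
  theta <- outcome_probs(0.15, 0.30, 0.15, 0.40)
  draws <- stats::rmultinom(1e5, 15, theta)  # same generator the engine uses
  freq <- rowMeans(draws) / 15
  se <- sqrt(unclass(theta) * (1 - unclass(theta)) / (15 * 1e5))
  expect_true(all(abs(freq - unclass(theta)) < 3 * se))
})

test_that("arm evaluation obeys the strict-inequality rule at cutoff extremes", {
  d <- unc_design()
  dat <- arm_data(15, x_eff = 2, x_tox = 9)
  expect_equal(evaluate_arm(d, dat, cutoff = 1), "continue")
  expect_equal(evaluate_arm(d, dat, cutoff = 0), "stop_both")

  # independent oracle: both tail probabilities by direct quadrature
  pf <- stats::integrate(function(p) stats::dbeta(p, 0.45 + 2, 0.55 + 13), 0, 0.45,
                         rel.tol = 1e-12)$value
  pt <- 1 - stats::integrate(function(p) stats::dbeta(p, 0.30 + 9, 0.70 + 6), 0, 0.30,
                             rel.tol = 1e-12)$value
  cutoff <- 0.8425
  want <- if (pf > cutoff && pt > cutoff) "stop_both" else if (pf > cutoff)
    "stop_futility" else if (pt > cutoff) "stop_toxicity" else "continue"
  expect_equal(evaluate_arm(d, dat, cutoff = cutoff), want)
  expect_error(evaluate_arm(d, dat, ctrl_data = arm_data(10), cutoff = 0.5), "no ctrl_data")
})

test_that("single trials are reproducible and respect extreme scenarios", {
  d <- unc_design()
  sc <- trial_scenario(rep(list(outcome_probs(0.18, 0.42, 0.02, 0.38)), 3))
  t1 <- run_trial(d, sc, seed = 99)
  t2 <- run_trial(d, sc, seed = 99)
  expect_identical(t1, t2)

  # never efficacious, never toxic: futility evidence only grows
  dead <- trial_scenario(rep(list(outcome_probs(0, 0, 0, 1)), 3))
  tr <- run_trial(d, dead, seed = 5)
  expect_true(all(!tr$arms$promising))
  expect_true(all(tr$arms$stop_reason %in% c("futility", "none")))
  expect_true(all(tr$arms$sample_size <= 60))

  # a boundary no posterior probability can cross: all arms run to N
  tiny <- design_spec(K = 2, N = 8, schedule = c(4, 8), phi_eff = 0.45, phi_tox = 0.30,
                      prior = c(0.15, 0.30, 0.15, 0.40),
                      threshold = threshold_spec("constant", eps = 1 - 1e-9))
  tr <- run_trial(tiny, trial_scenario(rep(list(outcome_probs(0.15, 0.30, 0.15, 0.40)), 2)),
                  seed = 6)
  expect_true(all(tr$arms$promising))
  expect_equal(tr$arms$sample_size, c(8L, 8L))
  expect_equal(tr$looks_performed, 2L)
})

test_that("lowering every cutoff only enlarges the stopped set (common random numbers)", {
  d_hi <- unc_design(threshold_spec("multi_arm", lambda = 0.4, gamma = 1))
  sc <- trial_scenario(rep(list(outcome_probs(0.15, 0.30, 0.15, 0.40)), 3))
  set.seed(11)
  cnt <- bop2mams:::sim_counts(d_hi, sc, accrual_plan("planned"), 400)
  mon <- bop2mams:::monitor_arrays(d_hi, cnt)
  dec_hi <- bop2mams:::apply_decisions(mon, d_hi)
  d_lo <- unc_design(threshold_spec("multi_arm", lambda = 0.8, gamma = 1))
  dec_lo <- bop2mams:::apply_decisions(mon, d_lo)
  expect_true(all(dec_lo$promising <= dec_hi$promising))
  both <- !is.na(dec_hi$stop_look) & !is.na(dec_lo$stop_look)
  expect_true(all(dec_lo$stop_look[both] <= dec_hi$stop_look[both]))
})

test_that("controlled evaluation matches the defining exceedance integral", {
  h0 <- outcome_probs(0.30, 0.30, 0.10, 0.30)
  d <- design_spec(K = 2, N = 20, schedule = c(10, 20), controlled = TRUE, prior = h0,
                   threshold = threshold_spec("multi_arm", lambda = 0.63, gamma = 1))
  dat <- arm_data(10, x_eff = 3, x_tox = 6)
  ctl <- arm_data(10, x_eff = 7, x_tox = 2)
  # prior margins: efficacy Beta(0.6, 0.4), toxicity Beta(0.4, 0.6)
  pf <- 1 - oracle_exceedance(0.6 + 3, 0.4 + 7, 0.6 + 7, 0.4 + 3)
  pt <- oracle_exceedance(0.4 + 6, 0.6 + 4, 0.4 + 2, 0.6 + 8)
  for (cutoff in c(0.3, 0.7, 0.95)) {
    want <- if (pf > cutoff && pt > cutoff) "stop_both" else if (pf > cutoff)
      "stop_futility" else if (pt > cutoff) "stop_toxicity" else "continue"
    expect_equal(evaluate_arm(d, dat, ctl, cutoff), want)
  }
  expect_error(evaluate_arm(d, dat, cutoff = 0.5), "require ctrl_data")

  # controlled per-trial path, including random per-arm accrual imbalance
  sc <- trial_scenario(rep(list(h0), 2), control = h0)
  tr1 <- run_trial(d, sc, accrual_plan("imbalanced", u = 2), seed = 44)
  tr2 <- run_trial(d, sc, accrual_plan("imbalanced", u = 2), seed = 44)
  expect_identical(tr1, tr2)
  oc <- estimate_oc(d, sc, accrual_plan("imbalanced", u = 2),
                    truth_labels = rep("inadmissible", 2), R = 40, seed = 45)
  expect_true(is.finite(oc$fwer))
  expect_true(all(oc$arms$mean_ss <= 22))  # at most N + accumulated overshoot
})

test_that("controlled trials treat exchangeable experimental arms symmetrically", {
  h0 <- outcome_probs(0.30, 0.30, 0.10, 0.30)
  d <- design_spec(K = 3, N = 30, schedule = c(15, 30), controlled = TRUE,
                   prior = h0, threshold = threshold_spec("multi_arm", lambda = 0.7, gamma = 1))
  sc <- trial_scenario(rep(list(h0), 3), control = h0)
  oc <- estimate_oc(d, sc, R = 10000, seed = 13)
  p <- oc$arms$ent_pct / 100
  se <- sqrt(mean(p) * (1 - mean(p)) / 10000)
  expect_true(max(p) - min(p) < 2 * 3 * se)
})

test_that("sample-size accounting is exact for never-stopping and consistent otherwise", {
  tiny <- design_spec(K = 2, N = 8, schedule = c(4, 8), phi_eff = 0.45, phi_tox = 0.30,
                      prior = c(0.15, 0.30, 0.15, 0.40),
                      threshold = threshold_spec("constant", eps = 1 - 1e-9))
  sc <- trial_scenario(rep(list(outcome_probs(0.15, 0.30, 0.15, 0.40)), 2))
  oc <- estimate_oc(tiny, sc, R = 200, seed = 17)
  expect_equal(oc$arms$mean_ss, c(8, 8))
  expect_equal(oc$arms$ent_pct, c(100, 100))
  expect_equal(oc$arms$es_pct, c(0, 0))

  d <- unc_design()
  sc3 <- trial_scenario(rep(list(outcome_probs(0.15, 0.30, 0.15, 0.40)), 3))
  oc <- estimate_oc(d, sc3, R = 2000, seed = 19)
  # mean SS must equal N minus the savings implied by the stop-look distribution
  expect_true(all(oc$arms$mean_ss <= 60))
  expect_true(all(oc$arms$mean_ss >= 15))
})
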