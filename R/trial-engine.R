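# Design, scenario and accrual specifications, plus the single-trial
# simulator. Replicated simulation lives in oc.R / simulate-internal.R.

#' Specify a multi-arm multi-stage design
#'
#' @param K Number of experimental arms.
#' @param N Planned maximum sample size per arm.
#' @param schedule Strictly increasing cumulative per-arm analysis sizes
#'   ending at `N` (interim analyses plus the terminal analysis). Defaults to
#'   four equally spaced looks.
#' @param controlled If `TRUE`, arms are monitored against a randomized
#'   control arm via posterior exceedance probabilities; otherwise against
#'   the fixed reference rates `phi_eff`, `phi_tox`.
#' @param phi_eff,phi_tox Reference efficacy and toxicity rates in (0, 1);
#'   required in the uncontrolled setting, forbidden in the controlled one.
#' @param prior A [normalize_prior()] object (or raw weights), shared by all
#'   arms including the control.
#' @param threshold A [threshold_spec()]; may be omitted for a design
#'   skeleton used only in calibration.
#' @param single_threshold Companion `single_arm` [threshold_spec()],
#'   required when `threshold` has family `active_arm` (the applied cutoff is
#'   their minimum, see [effective_cutoff()]).
#' @return An object of class `design_spec`.
#' @examples
#' design_spec(K = 3, N = 60, schedule = c(15, 30, 45, 60),
#'             phi_eff = 0.45, phi_tox = 0.30,
#'             prior = c(0.15, 0.30, 0.15, 0.40),
#'             threshold = threshold_spec("multi_arm", lambda = 0.63, gamma = 1))
#' @export
design_spec <- function(K, N, schedule = NULL, controlled = FALSE,
                        phi_eff = NULL, phi_tox = NULL, prior,
                        threshold = NULL, single_threshold = NULL) {
  if (anyNA(K) || K < 1 || K != round(K)) stopf("K must be a positive integer")
  if (anyNA(N) || N < 1 || N != round(N)) stopf("N must be a positive integer")
  if (is.null(schedule)) schedule <- round(N * (1:4) / 4)
  schedule <- as.integer(schedule)
  if (anyNA(schedule) || any(diff(schedule) <= 0) || any(schedule <= 0) ||
      schedule[length(schedule)] != N)
    stopf("schedule must be strictly increasing positive integers ending at N")
  if (controlled) {
    if (!is.null(phi_eff) || !is.null(phi_tox))
      stopf("controlled designs compare to the control arm; phi_eff/phi_tox must be NULL")
  } else {
    if (is.null(phi_eff) || is.null(phi_tox) ||
        phi_eff <= 0 || phi_eff >= 1 || phi_tox <= 0 || phi_tox >= 1)
      stopf("uncontrolled designs require phi_eff and phi_tox in (0, 1)")
  }
  if (!inherits(prior, "dirichlet_prior")) prior <- normalize_prior(prior)
  if (!is.null(threshold)) {
    if (!inherits(threshold, "threshold_spec")) stopf("threshold must be a threshold_spec")
    if (threshold$family == "active_arm") {
      if (threshold$K != K) stopf("active_arm threshold K (%d) must match design K (%d)",
                                  threshold$K, K)
      if (is.null(single_threshold) || single_threshold$family != "single_arm")
        stopf("active_arm threshold requires a single_arm companion spec")
    }
  }
  structure(list(K = as.integer(K), N = as.integer(N), schedule = schedule,
                 controlled = isTRUE(controlled), phi_eff = phi_eff,
                 phi_tox = phi_tox, prior = prior, threshold = threshold,
                 single_threshold = single_threshold),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("%s BOP2 design: K = %d experimental arm(s)%s, N = %d per arm\n",
              if (x$controlled) "Controlled" else "Uncontrolled", x$K,
              if (x$controlled) " plus control" else "", x$N))
  cat("  analyses at n =", paste(x$schedule, collapse = ", "), "\n")
  if (!x$controlled)
    cat(sprintf("  reference rates: efficacy %g, toxicity %g\n", x$phi_eff, x$phi_tox))
  if (!is.null(x$threshold)) print(x$threshold)
  invisible(x)
}

#' Specify a simulation scenario
#'
#' @param arms List of `K` [outcome_probs()] giving each experimental arm's
#'   true joint outcome probabilities.
#' @param control True [outcome_probs()] of the control arm (controlled
#'   setting only).
#' @param truth Optional character vector labelling each experimental arm
#'   `"admissible"` or `"inadmissible"`; used for FWER / power / correct
#'   selection accounting.
#' @param label Optional scenario label.
#' @return An object of class `trial_scenario`.
#' @export
trial_scenario <- function(arms, control = NULL, truth = NULL, label = NULL) {
  arms <- lapply(arms, function(a) if (inherits(a, "outcome_probs")) a else outcome_probs(a))
  if (!is.null(control) && !inherits(control, "outcome_probs"))
    control <- outcome_probs(control)
  if (!is.null(truth)) {
    truth <- match.arg(truth, c("admissible", "inadmissible"), several.ok = TRUE)
    if (length(truth) != length(arms)) stopf("truth labels must match the number of arms")
  }
  structure(list(arms = arms, control = control, truth = truth, label = label),
            class = "trial_scenario")
}

#' @export
print.trial_scenario <- function(x, ...) {
  cat(sprintf("Scenario%s: %d experimental arm(s)%s\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              length(x$arms), if (is.null(x$control)) "" else " plus control"))
  for (k in seq_along(x$arms)) {
    m <- marginal_rates(x$arms[[k]])
    cat(sprintf("  arm %d: (%.2f, %.2f)%s\n", k, m[1], m[2],
                if (is.null(x$truth)) "" else paste0(" [", x$truth[k], "]")))
  }
  if (!is.null(x$control)) {
    m <- marginal_rates(x$control)
    cat(sprintf("  control: (%.2f, %.2f)\n", m[1], m[2]))
  }
  invisible(x)
}

#' Specify an accrual plan
#'
#' `planned` follows the design schedule. `reduced_N` emulates slower-than-
#' planned overall accrual: the arm caps out at `reduced_N` patients with
#' analyses every `reduced_N / J` patients (J = number of planned looks).
#' The threshold parameters stay those optimized for the planned `N`, but
#' the boundary follows the actual information fraction `n / reduced_N`, so
#' the terminal analysis still applies the full-information cutoff.
#' `psi_shaped` deforms
#' the schedule to cumulative size `round(N (j/J)^psi)`: `psi < 1` front-
#' loads accrual, `psi > 1` slows it early. `imbalanced` perturbs each arm's
#' per-look increment by an independent uniform draw from `{-u, ..., u}`.
#'
#' @param mode One of `"planned"`, `"reduced_N"`, `"psi_shaped"`,
#'   `"imbalanced"`.
#' @param psi Accrual-shape exponent (> 0), `psi_shaped` mode.
#' @param u Maximum per-arm, per-look deviation (nonnegative integer),
#'   `imbalanced` mode.
#' @param reduced_N Actual per-arm cap, `reduced_N` mode.
#' @return An object of class `accrual_plan`.
#' @export
accrual_plan <- function(mode = c("planned", "reduced_N", "psi_shaped", "imbalanced"),
                         psi = 1, u = 0L, reduced_N = NULL) {
  mode <- match.arg(mode)
  if (mode == "psi_shaped" && (anyNA(psi) || psi <= 0)) stopf("psi must be positive")
  if (mode == "imbalanced" && (anyNA(u) || u < 0 || u != round(u)))
    stopf("u must be a nonnegative integer")
  if (mode == "reduced_N" && (is.null(reduced_N) || anyNA(reduced_N) ||
                              reduced_N < 1 || reduced_N != round(reduced_N)))
    stopf("reduced_N mode requires a positive integer reduced_N")
  structure(list(mode = mode, psi = psi, u = as.integer(u),
                 reduced_N = if (is.null(reduced_N)) NULL else as.integer(reduced_N)),
            class = "accrual_plan")
}

#' Build the per-look, per-arm accrual schedule
#'
#' Rounding uses round-half-to-even; looks made duplicate by rounding are
#' merged. In `imbalanced` mode the increments are random, so results depend
#' on the RNG state (seed it for reproducibility). In controlled designs the
#' control arm occupies the last column and accrues on the same plan.
#'
#' @param design A [design_spec()].
#' @param plan An [accrual_plan()].
#' @return Integer matrix of cumulative sample sizes, one row per look, one
#'   column per arm (control last when present).
#' @examples
#' d <- design_spec(K = 3, N = 60, phi_eff = 0.45, phi_tox = 0.3,
#'                  prior = c(0.15, 0.30, 0.15, 0.40))
#' build_schedule(d, accrual_plan("psi_shaped", psi = 0.25))[, 1]  # 42 50 56 60
#' @export
build_schedule <- function(design, plan = accrual_plan("planned")) {
  J <- length(design$schedule)
  n_arms <- design$K + as.integer(design$controlled)
  per_arm <- switch(plan$mode,
    planned = design$schedule,
    reduced_N = {
      if (plan$reduced_N > design$N) stopf("reduced_N exceeds the planned N")
      unique(round(plan$reduced_N * seq_len(J) / J))
    },
    psi_shaped = unique(round(design$N * (seq_len(J) / J)^plan$psi)),
    imbalanced = NULL)
  if (plan$mode != "imbalanced") {
    per_arm <- per_arm[per_arm > 0]
    if (any(diff(per_arm) <= 0)) stopf("accrual schedule is not strictly increasing")
    out <- matrix(per_arm, nrow = length(per_arm), ncol = n_arms)
  } else {
    base <- diff(c(0L, design$schedule))
    if (any(base - plan$u <= 0))
      stopf("imbalance u = %d can exhaust a planned increment", plan$u)
    dev <- matrix(sample(seq(-plan$u, plan$u), J * n_arms, replace = TRUE),
                  nrow = J, ncol = n_arms)
    out <- apply(base + dev, 2, cumsum)
  }
  colnames(out) <- c(paste0("arm", seq_len(design$K)),
                     if (design$controlled) "control")
  storage.mode(out) <- "integer"
  out
}

#' Draw one accrual cohort's joint outcomes
#'
#' @param theta An [outcome_probs()] object.
#' @param m Cohort size.
#' @return Integer vector of the four cell counts, summing to `m`.
#' @export
sample_cohort <- function(theta, m) {
  if (!inherits(theta, "outcome_probs")) theta <- outcome_probs(theta)
  if (anyNA(m) || m < 0 || m != round(m)) stopf("cohort size must be a nonnegative integer")
  if (m == 0) return(structure(integer(4), names = CELLS))
  structure(as.integer(stats::rmultinom(1, m, theta)[, 1]), names = CELLS)
}

# Monitoring probabilities of the two stopping rules for one arm.
# Returns c(futility = , toxicity = ); each rule stops when its probability
# strictly exceeds the cutoff.
monitor_probs <- function(design, data, ctrl_data = NULL) {
  if (design$controlled) {
    pe <- posterior_beta(design$prior, data, "efficacy")
    pt <- posterior_beta(design$prior, data, "toxicity")
    ce <- posterior_beta(design$prior, ctrl_data, "efficacy")
    ct <- posterior_beta(design$prior, ctrl_data, "toxicity")
    c(futility = 1 - beta_exceedance(pe$alpha, pe$beta, ce$alpha, ce$beta),
      toxicity = beta_exceedance(pt$alpha, pt$beta, ct$alpha, ct$beta))
  } else {
    c(futility = prob_below_fixed(posterior_beta(design$prior, data, "efficacy"),
                                  design$phi_eff),
      toxicity = prob_above_fixed(posterior_beta(design$prior, data, "toxicity"),
                                  design$phi_tox))
  }
}

#' Evaluate the stopping rules for one arm at one analysis
#'
#' Computes the futility and toxicity posterior probabilities (against fixed
#' references or the control arm, per the design) and compares each with the
#' cutoff; a rule fires on strict inequality.
#'
#' @param design A [design_spec()].
#' @param data [arm_data()] for the experimental arm.
#' @param ctrl_data [arm_data()] for the control arm (controlled designs
#'   only).
#' @param cutoff The decision threshold at this analysis.
#' @return One of `"continue"`, `"stop_futility"`, `"stop_toxicity"`,
#'   `"stop_both"`.
#' @export
evaluate_arm <- function(design, data, ctrl_data = NULL, cutoff) {
  if (design$controlled && is.null(ctrl_data))
    stopf("controlled designs require ctrl_data")
  if (!design$controlled && !is.null(ctrl_data))
    stopf("uncontrolled designs take no ctrl_data")
  pr <- monitor_probs(design, data, ctrl_data)
  fut <- pr[["futility"]] > cutoff
  tox <- pr[["toxicity"]] > cutoff
  if (fut && tox) "stop_both"
  else if (fut) "stop_futility"
  else if (tox) "stop_toxicity"
  else "continue"
}

# cutoff(s) applied at one look; n may be a vector (one per arm, for
# imbalanced schedules); a = number of active experimental arms.
#
# N_anchor is the denominator of the information fraction n/N. Under reduced
# accrual the threshold parameters stay those optimized for the planned N,
# but the boundary follows the actual information fraction (terminal cutoff
# 1 - lambda regardless of how many patients the arm reached), so N_anchor
# is the reduced cap there. Imbalanced accrual can overshoot the planned N;
# overshoot is evaluated at full information.
look_cutoffs <- function(design, n, a, N_anchor = design$N) {
  th <- design$threshold
  if (is.null(th)) stopf("design has no threshold specification")
  n <- pmin(n, N_anchor)
  if (th$family == "active_arm") {
    effective_cutoff(th, design$single_threshold, n, N_anchor, a)
  } else {
    threshold_value(th, n, N_anchor)
  }
}

# information-fraction denominator implied by an accrual plan
plan_anchor <- function(design, plan) {
  if (plan$mode == "reduced_N") plan$reduced_N else design$N
}

#' Simulate one multi-arm multi-stage trial
#'
#' Runs the accrual and decision sequence of a single trial. At each look
#' every active experimental arm is evaluated against the cutoff computed
#' with the number of active arms counted *before* any decision of that look
#' (decisions within a look are simultaneous). Arms that trigger a rule stop
#' accruing; the control arm (controlled setting) accrues to its cap
#' regardless, and every evaluation uses all control data accrued so far. An
#' arm is declared promising if and only if it reaches the terminal analysis
#' and neither rule fires there.
#'
#' @param design A [design_spec()] with a threshold.
#' @param scenario A [trial_scenario()] with matching arm count.
#' @param plan An [accrual_plan()].
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `trial_result`: a list with `arms` (a data
#'   frame with per-arm `stopped_early`, `stop_look`, `stop_reason`,
#'   `promising`, `sample_size`) and `looks_performed`.
#' @export
run_trial <- function(design, scenario, plan = accrual_plan("planned"), seed = NULL) {
  if (length(scenario$arms) != design$K)
    stopf("scenario has %d arms but design has K = %d", length(scenario$arms), design$K)
  if (design$controlled && is.null(scenario$control))
    stopf("controlled design requires a control arm in the scenario")
  if (!is.null(seed)) set.seed(seed)
  anchor <- plan_anchor(design, plan)
  sched <- build_schedule(design, plan)
  J <- nrow(sched)
  K <- design$K
  xE <- xT <- nn <- integer(K)
  c0 <- arm_data(0L)
  alive <- rep(TRUE, K)
  stop_look <- rep(NA_integer_, K)
  stop_reason <- rep("none", K)
  promising <- rep(FALSE, K)
  samp <- integer(K)
  looks_done <- 0L
  for (j in seq_len(J)) {
    if (!any(alive)) break
    looks_done <- j
    for (k in seq_len(K)) {
      if (!alive[k]) next
      cnt <- sample_cohort(scenario$arms[[k]], sched[j, k] - nn[k])
      nn[k] <- sched[j, k]
      xE[k] <- xE[k] + cnt[[1]] + cnt[[2]]
      xT[k] <- xT[k] + cnt[[1]] + cnt[[3]]
    }
    if (design$controlled) {
      cnt <- sample_cohort(scenario$control, sched[j, K + 1L] - c0$n)
      c0 <- arm_data(sched[j, K + 1L], c0$x_eff + cnt[[1]] + cnt[[2]],
                     c0$x_tox + cnt[[1]] + cnt[[3]])
    }
    a <- sum(alive)
    decisions <- rep("continue", K)
    for (k in seq_len(K)) {
      if (!alive[k]) next
      cut <- look_cutoffs(design, nn[k], a, N_anchor = anchor)
      decisions[k] <- evaluate_arm(design, arm_data(nn[k], xE[k], xT[k]),
                                   if (design$controlled) c0, cut)
    }
    for (k in seq_len(K)) {
      if (decisions[k] == "continue") next
      alive[k] <- FALSE
      samp[k] <- nn[k]
      if (j < J) {  # early stop; a terminal trigger is just "not promising"
        stop_look[k] <- j
        stop_reason[k] <- sub("^stop_", "", decisions[k])
      }
    }
  }
  promising[alive] <- TRUE
  samp[alive] <- nn[alive]
  arms <- data.frame(
    arm = seq_len(K),
    stopped_early = !is.na(stop_look),
    stop_look = stop_look,
    stop_reason = stop_reason,
    promising = promising,
    sample_size = samp
  )
  structure(list(arms = arms, looks_performed = looks_done), class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("Trial result (%d look(s) performed):\n", x$looks_performed))
  print(x$arms, row.names = FALSE)
  invisible(x)
}
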