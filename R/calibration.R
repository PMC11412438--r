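# Grid-search calibration of threshold parameters.
#
# The decisive observation: for the C_n = 1 - lambda (n/N)^gamma families the
# simulated trajectories do not depend on (lambda, gamma), and an arm is
# promising iff at every look the larger of its two monitoring probabilities
# M_j satisfies M_j <= 1 - lambda (n_j/N)^gamma, i.e. iff
#   lambda <= L = min_j (1 - M_j) / (n_j/N)^gamma.
# So one set of simulations per configuration yields, for each gamma, a
# per-replicate statistic L whose empirical tail gives the FWER and power at
# every lambda simultaneously — exact common random numbers across the whole
# grid at negligible cost. The constant family uses max_j M_j the same way.
# Only the active-arm family, whose cutoff couples the arms, needs a sweep
# over grid points.

#' Define a calibration problem
#'
#' @param design A [design_spec()] skeleton (its threshold, if any, is
#'   ignored during calibration).
#' @param H0 [outcome_probs()] of an inadmissible (inefficacious/toxic) arm;
#'   the global null puts every arm (and the control) at `H0`.
#' @param H1 [outcome_probs()] of a promising arm; the least favourable
#'   configuration puts one arm at `H1` and the rest at `H0`.
#' @param H01,H02 Optional discordant nulls (safe-but-ineffective and
#'   effective-but-toxic) for [calibrate_dual_null()].
#' @param fwer_target Nominal family-wise type I error level in (0, 1).
#' @param arm_alpha_target Optional arm-specific type I error cap, enforced
#'   under the configuration with a single inadmissible arm among promising
#'   ones.
#' @param lambda_grid,gamma_grid,eps_grid Candidate parameter values.
#' @param R_cal Replicates per configuration (all grid points share them).
#' @param seed Integer seed for the calibration simulations.
#' @return An object of class `calibration_problem`.
#' @export
calibration_problem <- function(design, H0, H1, H01 = NULL, H02 = NULL,
                                fwer_target, arm_alpha_target = NULL,
                                lambda_grid = seq(0.01, 0.99, by = 0.01),
                                gamma_grid = seq(0.05, 1, by = 0.05),
                                eps_grid = seq(0.500, 0.995, by = 0.005),
                                R_cal = 10000, seed = 1) {
  if (!inherits(design, "design_spec")) stopf("design must be a design_spec")
  H0 <- if (inherits(H0, "outcome_probs")) H0 else outcome_probs(H0)
  H1 <- if (inherits(H1, "outcome_probs")) H1 else outcome_probs(H1)
  if (!is.null(H01)) H01 <- if (inherits(H01, "outcome_probs")) H01 else outcome_probs(H01)
  if (!is.null(H02)) H02 <- if (inherits(H02, "outcome_probs")) H02 else outcome_probs(H02)
  if (anyNA(fwer_target) || fwer_target <= 0 || fwer_target >= 1)
    stopf("fwer_target must lie in (0, 1)")
  if (length(lambda_grid) == 0 || any(lambda_grid <= 0) || any(lambda_grid >= 1))
    stopf("lambda_grid must be nonempty within (0, 1)")
  if (length(gamma_grid) == 0 || any(gamma_grid <= 0) || any(gamma_grid > 1))
    stopf("gamma_grid must be nonempty within (0, 1]")
  if (length(eps_grid) == 0 || any(eps_grid <= 0) || any(eps_grid >= 1))
    stopf("eps_grid must be nonempty within (0, 1)")
  if (R_cal < 1) stopf("R_cal must be at least 1")
  structure(list(design = design, H0 = H0, H1 = H1, H01 = H01, H02 = H02,
                 fwer_target = fwer_target, arm_alpha_target = arm_alpha_target,
                 lambda_grid = sort(lambda_grid), gamma_grid = sort(gamma_grid),
                 eps_grid = sort(eps_grid), R_cal = as.integer(R_cal),
                 seed = as.integer(seed)),
            class = "calibration_problem")
}

# design skeleton with K arms and no threshold, for calibration simulations
cal_design <- function(problem, K) {
  d <- problem$design
  design_spec(K = K, N = d$N, schedule = d$schedule, controlled = d$controlled,
              phi_eff = d$phi_eff, phi_tox = d$phi_tox, prior = d$prior)
}

# M = pmax(PF, PT) array for one configuration of true arm outcomes
cal_M <- function(design, arms, control, seed, R) {
  set.seed(seed)
  sc <- trial_scenario(arms, control = control)
  mon <- monitor_arrays(design, sim_counts(design, sc, accrual_plan("planned"), R))
  list(M = pmax(mon$PF, mon$PT), n = mon$n)
}

# L statistic (see header): R x K matrix, one row per replicate
L_stat <- function(M, n, N, gamma) {
  K <- dim(M)[2]
  tg <- (n / N)^gamma
  L <- matrix(Inf, dim(M)[1], K)
  for (j in seq_along(n)) {
    mj <- matrix(M[, , j], ncol = K)
    L <- pmin(L, (1 - mj) / tg[j])
  }
  L
}

# promising matrix under the min(C_{n,a}, C_ns) rule for one grid point
active_promising <- function(M, n, N, multi_spec, single_spec) {
  R <- dim(M)[1]; K <- dim(M)[2]
  alive <- matrix(TRUE, R, K)
  for (j in seq_along(n)) {
    a <- rowSums(alive)
    a[a == 0L] <- 1L
    cut <- effective_cutoff(multi_spec, single_spec, n[j], N, a)
    alive <- alive & !(matrix(M[, , j], ncol = K) > matrix(cut, R, K))
  }
  alive
}

# Configurations used by the grid search. Each is a list of true arm joints
# (+ control, at H0, for controlled designs).
cal_configs <- function(problem, K, dual) {
  H0 <- problem$H0; H1 <- problem$H1
  cfg <- list(
    null = rep(list(H0), K),
    lfc  = c(list(H1), rep(list(H0), K - 1))
  )
  if (!is.null(problem$arm_alpha_target) && K > 1)
    cfg$one_bad <- c(list(H0), rep(list(H1), K - 1))
  if (dual) {
    cfg$null01 <- rep(list(problem$H01), K)
    cfg$null02 <- rep(list(problem$H02), K)
  }
  cfg
}

calibrate_impl <- function(problem, family, dual) {
  K <- if (family == "single_arm") 1L else problem$design$K
  design <- cal_design(problem, K)
  ctrl <- if (design$controlled) problem$H0
  cfgs <- cal_configs(problem, K, dual)
  # common random numbers: one fixed seed offset per configuration; every
  # grid point reuses the same arrays
  Ms <- vector("list", length(cfgs))
  names(Ms) <- names(cfgs)
  for (i in seq_along(cfgs))
    Ms[[i]] <- cal_M(design, cfgs[[i]], ctrl, problem$seed + i - 1L, problem$R_cal)
  n <- Ms[[1]]$n
  N <- design$N

  if (family == "constant") {
    stat_any <- function(M) {  # min over arms of max over looks
      s <- matrix(-Inf, dim(M)[1], dim(M)[2])
      for (j in seq_len(dim(M)[3])) s <- pmax(s, matrix(M[, , j], ncol = dim(M)[2]))
      apply(s, 1, min)
    }
    stat_arm <- function(M, k) {
      s <- rep(-Inf, dim(M)[1])
      for (j in seq_len(dim(M)[3])) s <- pmax(s, matrix(M[, , j], ncol = dim(M)[2])[, k])
      s
    }
    eg <- problem$eps_grid
    grid <- data.frame(eps = eg)
    grid$fwer <- colMeans(outer(stat_any(Ms$null$M), eg, "<="))
    grid$power <- colMeans(outer(stat_arm(Ms$lfc$M, 1), eg, "<="))
    if (!is.null(cfgs$one_bad))
      grid$arm_alpha <- colMeans(outer(stat_arm(Ms$one_bad$M, 1), eg, "<="))
    if (dual) {
      grid$fwer_h01 <- colMeans(outer(stat_any(Ms$null01$M), eg, "<="))
      grid$fwer_h02 <- colMeans(outer(stat_any(Ms$null02$M), eg, "<="))
    }
  } else if (family %in% c("single_arm", "multi_arm")) {
    lg <- problem$lambda_grid
    rows <- lapply(problem$gamma_grid, function(g) {
      df <- data.frame(lambda = lg, gamma = g)
      Gmax <- apply(L_stat(Ms$null$M, n, N, g), 1, max)
      df$fwer <- colMeans(outer(Gmax, lg, ">="))
      df$power <- colMeans(outer(L_stat(Ms$lfc$M, n, N, g)[, 1], lg, ">="))
      if (!is.null(cfgs$one_bad))
        df$arm_alpha <- colMeans(outer(L_stat(Ms$one_bad$M, n, N, g)[, 1], lg, ">="))
      if (dual) {
        df$fwer_h01 <- colMeans(outer(apply(L_stat(Ms$null01$M, n, N, g), 1, max), lg, ">="))
        df$fwer_h02 <- colMeans(outer(apply(L_stat(Ms$null02$M, n, N, g), 1, max), lg, ">="))
      }
      df
    })
    grid <- do.call(rbind, rows)
  } else {  # active_arm: calibrate the single-arm companion first
    single <- calibrate_impl(problem, "single_arm", dual)
    sspec <- single$threshold
    rows <- list()
    for (g in problem$gamma_grid) {
      for (l in problem$lambda_grid) {
        mspec <- threshold_spec("active_arm", lambda = l, gamma = g, K = K)
        prom0 <- active_promising(Ms$null$M, n, N, mspec, sspec)
        row <- data.frame(lambda = l, gamma = g,
                          fwer = mean(rowSums(prom0) > 0),
                          power = mean(active_promising(Ms$lfc$M, n, N, mspec, sspec)[, 1]))
        if (!is.null(cfgs$one_bad))
          row$arm_alpha <- mean(active_promising(Ms$one_bad$M, n, N, mspec, sspec)[, 1])
        if (dual) {
          row$fwer_h01 <- mean(rowSums(active_promising(Ms$null01$M, n, N, mspec, sspec)) > 0)
          row$fwer_h02 <- mean(rowSums(active_promising(Ms$null02$M, n, N, mspec, sspec)) > 0)
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
    grid <- do.call(rbind, rows)
  }

  feasible <- grid$fwer <= problem$fwer_target
  if (dual) feasible <- feasible & grid$fwer_h01 <= problem$fwer_target &
                                   grid$fwer_h02 <= problem$fwer_target
  if (!is.null(grid$arm_alpha) && !is.null(problem$arm_alpha_target))
    feasible <- feasible & grid$arm_alpha <= problem$arm_alpha_target
  grid$feasible <- feasible
  if (!any(feasible))
    stopf("no grid point satisfies the FWER constraint(s); minimum achieved FWER = %.4f (target %.4f)",
          min(grid$fwer), problem$fwer_target)

  # argmax power among feasible points; points whose power is within one MC
  # standard error of the best are tied, resolved by lower FWER, then by the
  # parameter implying more early stopping (larger lambda / smaller eps)
  feas <- grid[feasible, , drop = FALSE]
  pmax_hat <- max(feas$power)
  se <- sqrt(pmax_hat * (1 - pmax_hat) / problem$R_cal)
  cand <- feas[feas$power >= pmax_hat - se, , drop = FALSE]
  ord <- if (family == "constant") {
    order(cand$fwer, cand$eps)
  } else {
    order(cand$fwer, -cand$lambda)
  }
  best <- cand[ord[1], , drop = FALSE]

  if (family == "constant") {
    thr <- threshold_spec("constant", eps = best$eps)
  } else if (family == "active_arm") {
    thr <- threshold_spec("active_arm", lambda = best$lambda, gamma = best$gamma, K = K)
  } else {
    thr <- threshold_spec(family, lambda = best$lambda, gamma = best$gamma)
  }
  design_out <- problem$design
  design_out$threshold <- thr
  design_out$single_threshold <- if (family == "active_arm") single$threshold
  structure(list(family = family,
                 lambda = if (family != "constant") best$lambda,
                 gamma = if (family != "constant") best$gamma,
                 eps = if (family == "constant") best$eps,
                 fwer = best$fwer, power = best$power,
                 fwer_target = problem$fwer_target,
                 grid = grid, R_cal = problem$R_cal,
                 threshold = thr,
                 single = if (family == "active_arm") single,
                 design = design_out,
                 dual_null = dual),
            class = "bop2_calibration")
}

#' Calibrate a decision-threshold family
#'
#' Grid search over the family's parameters: every grid point is evaluated
#' on one common set of `R_cal` simulated trials per configuration
#' (identical random numbers across points), the feasible set keeps points
#' whose estimated FWER under the global null does not exceed
#' `fwer_target`, and the feasible point maximizing power under the least
#' favourable configuration is returned. Power ties within one Monte Carlo
#' standard error are broken toward lower FWER, then toward the more
#' stringent boundary. For `family = "single_arm"` the design is reduced to
#' one arm and the constraint is the arm-specific type I error. For
#' `family = "active_arm"` the evaluated rule is the operational
#' `min(C(n, a), C_single(n))`, whose single-arm companion is calibrated
#' first by the same procedure with K = 1.
#'
#' @param problem A [calibration_problem()].
#' @param family Threshold family to calibrate.
#' @return An object of class `bop2_calibration`: chosen parameters, their
#'   estimated FWER and power, the full audit grid, and a ready-to-simulate
#'   `design`.
#' @export
calibrate <- function(problem, family = c("multi_arm", "active_arm", "single_arm", "constant")) {
  if (!inherits(problem, "calibration_problem")) stopf("problem must be a calibration_problem")
  calibrate_impl(problem, match.arg(family), dual = FALSE)
}

#' Calibrate under two discordant null hypotheses
#'
#' As [calibrate()], but the feasible set additionally requires the FWER
#' constraint under the global safe-but-ineffective null (`H01`) and the
#' global effective-but-toxic null (`H02`). The feasible set can only
#' shrink, so the attained power never exceeds the single-null calibration
#' on the same grid and seed.
#'
#' @inheritParams calibrate
#' @export
calibrate_dual_null <- function(problem, family = c("multi_arm", "active_arm", "single_arm", "constant")) {
  if (!inherits(problem, "calibration_problem")) stopf("problem must be a calibration_problem")
  if (is.null(problem$H01) || is.null(problem$H02))
    stopf("dual-null calibration requires H01 and H02 in the problem")
  calibrate_impl(problem, match.arg(family), dual = TRUE)
}

#' @export
print.bop2_calibration <- function(x, ...) {
  cat(sprintf("Calibrated %s threshold (%s)\n", x$family,
              if (x$dual_null) "dual-null constraints" else "global-null constraint"))
  if (x$family == "constant") {
    cat(sprintf("  eps = %g\n", x$eps))
  } else {
    cat(sprintf("  lambda = %g, gamma = %g\n", x$lambda, x$gamma))
  }
  if (!is.null(x$single))
    cat(sprintf("  single-arm companion: lambda = %g, gamma = %g\n",
                x$single$lambda, x$single$gamma))
  cat(sprintf("  estimated FWER %.2f%% (target %.2f%%), LFC power %.2f%% [R_cal = %d]\n",
              100 * x$fwer, 100 * x$fwer_target, 100 * x$power, x$R_cal))
  invisible(x)
}
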