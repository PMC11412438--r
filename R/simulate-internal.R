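# Vectorized replicate simulation.
#
# For accrual plans in which all arms share one schedule (planned, reduced_N,
# psi_shaped), outcome counts for every replicate can be drawn up front and
# the monitoring probabilities evaluated as whole arrays; stopping only
# censors which looks matter, it never changes the distribution of the
# counts. The imbalanced plan randomizes per-arm schedules, so estimate_oc()
# falls back to looping run_trial() there.

# Cumulative counts for R replicates. Returns list(n = per-look sizes,
# xE, xT = R x K x J arrays, x0E, x0T = R x J matrices or NULL).
sim_counts <- function(design, scenario, plan, R) {
  sched <- build_schedule(design, plan)
  n <- sched[, 1]
  J <- length(n)
  K <- design$K
  inc <- diff(c(0L, n))
  xE <- array(0L, c(R, K, J))
  xT <- array(0L, c(R, K, J))
  cE <- matrix(0L, R, K)
  cT <- matrix(0L, R, K)
  for (j in seq_len(J)) {
    for (k in seq_len(K)) {
      d <- t(stats::rmultinom(R, inc[j], scenario$arms[[k]]))
      cE[, k] <- cE[, k] + d[, 1] + d[, 2]
      cT[, k] <- cT[, k] + d[, 1] + d[, 3]
    }
    xE[, , j] <- cE
    xT[, , j] <- cT
  }
  x0E <- x0T <- NULL
  if (design$controlled) {
    x0E <- x0T <- matrix(0L, R, J)
    cE0 <- cT0 <- integer(R)
    for (j in seq_len(J)) {
      d <- t(stats::rmultinom(R, inc[j], scenario$control))
      cE0 <- cE0 + d[, 1] + d[, 2]
      cT0 <- cT0 + d[, 1] + d[, 3]
      x0E[, j] <- cE0
      x0T[, j] <- cT0
    }
  }
  list(n = n, xE = xE, xT = xT, x0E = x0E, x0T = x0T)
}

# Monitoring probability arrays PF, PT (R x K x J) from simulated counts.
monitor_arrays <- function(design, cnt) {
  dims <- dim(cnt$xE)
  R <- dims[1]; K <- dims[2]; J <- dims[3]
  PF <- array(NA_real_, dims)
  PT <- array(NA_real_, dims)
  if (design$controlled) {
    me <- prior_margin(design$prior, "efficacy")
    mt <- prior_margin(design$prior, "toxicity")
    for (j in seq_len(J)) {
      n <- cnt$n[j]
      a0E <- me$alpha + cnt$x0E[, j]; b0E <- me$beta + n - cnt$x0E[, j]
      a0T <- mt$alpha + cnt$x0T[, j]; b0T <- mt$beta + n - cnt$x0T[, j]
      for (k in seq_len(K)) {
        PF[, k, j] <- 1 - beta_exceedance(me$alpha + cnt$xE[, k, j],
                                          me$beta + n - cnt$xE[, k, j], a0E, b0E)
        PT[, k, j] <- beta_exceedance(mt$alpha + cnt$xT[, k, j],
                                      mt$beta + n - cnt$xT[, k, j], a0T, b0T)
      }
    }
  } else {
    me <- prior_margin(design$prior, "efficacy")
    mt <- prior_margin(design$prior, "toxicity")
    for (j in seq_len(J)) {
      n <- cnt$n[j]
      PF[, , j] <- stats::pbeta(design$phi_eff, me$alpha + cnt$xE[, , j],
                                me$beta + n - cnt$xE[, , j])
      PT[, , j] <- 1 - stats::pbeta(design$phi_tox, mt$alpha + cnt$xT[, , j],
                                    mt$beta + n - cnt$xT[, , j])
    }
  }
  list(PF = PF, PT = PT, n = cnt$n)
}

# Apply look-wise cutoffs to probability arrays. cutoffs: numeric vector of
# length J (static families); for the active_arm family pass design and the
# cutoff is recomputed per replicate from the live arm count. Returns
# stop_look (R x K, NA = no early stop), promising (R x K), and the rule(s)
# firing at the stopping or terminal-failure look.
apply_decisions <- function(mon, design, N_anchor = design$N) {
  PF <- mon$PF; PT <- mon$PT
  R <- dim(PF)[1]; K <- dim(PF)[2]; J <- dim(PF)[3]
  th <- design$threshold
  active_rule <- th$family == "active_arm"
  alive <- matrix(TRUE, R, K)
  stop_look <- matrix(NA_integer_, R, K)
  fut_fired <- matrix(FALSE, R, K)
  tox_fired <- matrix(FALSE, R, K)
  for (j in seq_len(J)) {
    if (active_rule) {
      a <- rowSums(alive)
      a[a == 0L] <- 1L  # dead replicates; value irrelevant
      cut <- effective_cutoff(th, design$single_threshold, mon$n[j], N_anchor, a)
      cutm <- matrix(cut, R, K)
    } else {
      cutm <- matrix(look_cutoffs(design, mon$n[j], NA, N_anchor = N_anchor), R, K)
    }
    f <- alive & (PF[, , j] > cutm)
    t <- alive & (PT[, , j] > cutm)
    trig <- f | t
    fut_fired[f] <- TRUE
    tox_fired[t] <- TRUE
    if (j < J) stop_look[trig] <- j
    alive <- alive & !trig
  }
  list(stop_look = stop_look, promising = alive,
       fut_fired = fut_fired, tox_fired = tox_fired)
}

# sample size per replicate/arm given stop looks and the per-look sizes
sample_sizes <- function(stop_look, n) {
  ss <- matrix(n[length(n)], nrow(stop_look), ncol(stop_look))
  early <- !is.na(stop_look)
  ss[early] <- n[stop_look[early]]
  ss
}
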