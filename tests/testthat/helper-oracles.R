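# Independent oracles used across the suite.
#
# The enumeration oracle computes operating characteristics of tiny designs
# exactly, by summing multinomial path probabilities — no posterior-
# probability code is shared with the package paths it checks (monitoring
# probabilities are recomputed here from first principles with pbeta /
# numerical integration).

# exact pmf of the (efficacy, toxicity) count increments of one cohort
inc_pmf <- function(theta, m) {
  acc <- new.env(parent = emptyenv())
  for (c1 in 0:m) for (c2 in 0:(m - c1)) for (c3 in 0:(m - c1 - c2)) {
    c4 <- m - c1 - c2 - c3
    p <- stats::dmultinom(c(c1, c2, c3, c4), prob = theta)
    key <- paste(c1 + c2, c1 + c3)
    acc[[key]] <- (acc[[key]] %||% 0) + p
  }
  keys <- ls(acc)
  de <- as.integer(vapply(strsplit(keys, " "), `[`, "", 1))
  dt <- as.integer(vapply(strsplit(keys, " "), `[`, "", 2))
  data.frame(dE = de, dT = dt, p = vapply(keys, function(k) acc[[k]], 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exceedance by direct numerical integration of the defining integral
# (density against survival function) — independent of the package's
# quantile-substitution quadrature
oracle_exceedance <- function(a1, b1, a2, b2) {
  stats::integrate(function(p) (1 - stats::pbeta(p, a1, b1)) * stats::dbeta(p, a2, b2),
                   0, 1, rel.tol = 1e-10, subdivisions = 500L)$value
}

# advance enumeration states by one cohort and aggregate duplicates
enum_step <- function(st, theta, m) {
  tp <- inc_pmf(theta, m)
  i <- rep(seq_len(nrow(st)), each = nrow(tp))
  j <- rep(seq_len(nrow(tp)), times = nrow(st))
  new <- data.frame(xE = st$xE[i] + tp$dE[j], xT = st$xT[i] + tp$dT[j],
                    p = st$p[i] * tp$p[j])
  out <- stats::aggregate(p ~ xE + xT, new, sum)
  out
}

# exact per-arm OC of an uncontrolled arm under static look-wise cutoffs
enum_arm_uncontrolled <- function(prior, phi_eff, phi_tox, theta, looks, cutoffs) {
  aE <- prior[1] + prior[2]; bE <- prior[3] + prior[4]
  aT <- prior[1] + prior[3]; bT <- prior[2] + prior[4]
  J <- length(looks); inc <- diff(c(0, looks))
  st <- data.frame(xE = 0L, xT = 0L, p = 1)
  es <- 0; ss <- 0; promising <- 0
  for (j in seq_len(J)) {
    st <- enum_step(st, theta, inc[j])
    n <- looks[j]
    PF <- stats::pbeta(phi_eff, aE + st$xE, bE + n - st$xE)
    PT <- 1 - stats::pbeta(phi_tox, aT + st$xT, bT + n - st$xT)
    hit <- PF > cutoffs[j] | PT > cutoffs[j]
    if (j < J) {
      es <- es + sum(st$p[hit]); ss <- ss + n * sum(st$p[hit])
    } else {
      ss <- ss + n * sum(st$p); promising <- sum(st$p[!hit])
    }
    st <- st[!hit, , drop = FALSE]
  }
  list(promising = promising, es = es, mean_ss = ss)
}

# exact controlled OC: enumerate control paths, arms are conditionally
# independent given the control path
enum_controlled <- function(prior, thetas, theta0, looks, cutoffs) {
  aE <- prior[1] + prior[2]; bE <- prior[3] + prior[4]
  aT <- prior[1] + prior[3]; bT <- prior[2] + prior[4]
  J <- length(looks); inc <- diff(c(0, looks))
  # control paths: matrices of cumulative (x0E, x0T) per look with probs
  paths <- list(list(xE = integer(0), xT = integer(0), p = 1))
  for (j in seq_len(J)) {
    tp <- inc_pmf(theta0, inc[j])
    paths <- do.call(c, lapply(paths, function(pa) {
      lapply(seq_len(nrow(tp)), function(i) {
        last_e <- if (j == 1) 0L else pa$xE[j - 1]
        last_t <- if (j == 1) 0L else pa$xT[j - 1]
        list(xE = c(pa$xE, last_e + tp$dE[i]), xT = c(pa$xT, last_t + tp$dT[i]),
             p = pa$p * tp$p[i])
      })
    }))
  }
  arm_survival <- function(theta, path) {
    st <- data.frame(xE = 0L, xT = 0L, p = 1)
    for (j in seq_len(J)) {
      st <- enum_step(st, theta, inc[j])
      n <- looks[j]
      PF <- vapply(seq_len(nrow(st)), function(i) {
        1 - oracle_exceedance(aE + st$xE[i], bE + n - st$xE[i],
                              aE + path$xE[j], bE + n - path$xE[j])
      }, 0)
      PT <- vapply(seq_len(nrow(st)), function(i) {
        oracle_exceedance(aT + st$xT[i], bT + n - st$xT[i],
                          aT + path$xT[j], bT + n - path$xT[j])
      }, 0)
      st <- st[!(PF > cutoffs[j] | PT > cutoffs[j]), , drop = FALSE]
    }
    sum(st$p)
  }
  K <- length(thetas)
  ent <- numeric(K); fwer <- 0
  for (pa in paths) {
    pk <- vapply(thetas, arm_survival, 0, path = pa)
    ent <- ent + pa$p * pk
    fwer <- fwer + pa$p * (1 - prod(1 - pk))
  }
  list(ent = ent, fwer = fwer)
}

# small uncontrolled toy design used by several enumeration checks
toy_uncontrolled <- function(threshold = threshold_spec("multi_arm", lambda = 0.8, gamma = 1)) {
  design_spec(K = 2, N = 4, schedule = c(2, 4), controlled = FALSE,
              phi_eff = 0.45, phi_tox = 0.30,
              prior = c(0.15, 0.30, 0.15, 0.40), threshold = threshold)
}
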