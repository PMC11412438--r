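# Dirichlet-multinomial outcome model and posterior probabilities.
#
# Each patient contributes one of four joint outcomes, ordered throughout as
# (TE, T'E, TE', T'E'): toxicity+efficacy, efficacy only, toxicity only,
# neither. A Dirichlet prior on the cell probabilities is conjugate to the
# multinomial likelihood, and the aggregation property of the Dirichlet gives
# Beta marginals for the response rate p_E and the toxicity rate p_T.

CELLS <- c("tox_eff", "notox_eff", "tox_noeff", "notox_noeff")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Joint outcome probabilities for one arm
#'
#' The probability vector of the four mutually exclusive patient outcomes
#' (toxicity and efficacy, efficacy without toxicity, toxicity without
#' efficacy, neither), which defines the multinomial outcome model of an arm.
#'
#' @param p_tox_eff,p_notox_eff,p_tox_noeff,p_notox_noeff Cell probabilities,
#'   each in \[0, 1\], summing to 1. Alternatively pass a single length-4
#'   vector as the first argument.
#' @return An object of class `outcome_probs` (a named numeric vector).
#' @seealso [marginal_rates()], [joint_from_marginals()]
#' @examples
#' outcome_probs(0.15, 0.30, 0.15, 0.40)
#' @export
outcome_probs <- function(p_tox_eff, p_notox_eff, p_tox_noeff, p_notox_noeff) {
  if (missing(p_notox_eff) && length(p_tox_eff) == 4L) {
    p <- as.numeric(p_tox_eff)
  } else {
    p <- c(p_tox_eff, p_notox_eff, p_tox_noeff, p_notox_noeff)
  }
  if (length(p) != 4L || anyNA(p)) stopf("outcome probabilities must be 4 non-missing values")
  if (any(p < 0) || any(p > 1)) stopf("outcome probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-12) stopf("outcome probabilities must sum to 1 (got %.15f)", sum(p))
  names(p) <- CELLS
  structure(p, class = "outcome_probs")
}

#' @export
print.outcome_probs <- function(x, ...) {
  m <- marginal_rates(x)
  cat("Joint outcome probabilities (TE, T'E, TE', T'E'):",
      paste(format(unclass(x), digits = 4), collapse = ", "), "\n")
  cat(sprintf("  marginal efficacy %.4g, toxicity %.4g\n", m[1], m[2]))
  invisible(x)
}

#' Marginal efficacy and toxicity rates of a joint outcome vector
#'
#' @param theta An [outcome_probs()] object (or any length-4 probability
#'   vector in the canonical cell order).
#' @return Named numeric vector `c(efficacy = , toxicity = )`.
#' @examples
#' marginal_rates(outcome_probs(0.18, 0.42, 0.02, 0.38))  # (0.60, 0.20)
#' @export
marginal_rates <- function(theta) {
  if (!inherits(theta, "outcome_probs")) theta <- outcome_probs(theta)
  c(efficacy = unname(theta[1] + theta[2]), toxicity = unname(theta[1] + theta[3]))
}

#' Dirichlet prior with unit effective sample size
#'
#' Rescales four nonnegative pseudo-counts to sum to 1, so the prior carries
#' the information of a single observation (a "skeptical" prior when the
#' weights are the inefficacy/toxicity hypothesis itself).
#'
#' @param raw Four nonnegative weights (at least one strictly positive), in
#'   the cell order (TE, T'E, TE', T'E').
#' @return An object of class `dirichlet_prior` (named numeric vector
#'   summing to 1).
#' @examples
#' normalize_prior(c(1, 1, 1, 1))              # uniform, ESS 1
#' normalize_prior(c(0.15, 0.30, 0.15, 0.40))  # already normalized
#' @export
normalize_prior <- function(raw) {
  raw <- as.numeric(raw)
  if (length(raw) != 4L || anyNA(raw)) stopf("prior must be 4 non-missing weights")
  if (any(raw < 0)) stopf("prior weights must be nonnegative")
  s <- sum(raw)
  if (s <= 0) stopf("at least one prior weight must be strictly positive")
  p <- raw / s
  names(p) <- CELLS
  structure(p, class = "dirichlet_prior")
}

#' @export
print.dirichlet_prior <- function(x, ...) {
  cat("Dirichlet prior Dir(", paste(format(unclass(x), digits = 4), collapse = ", "),
      "), effective sample size 1\n", sep = "")
  invisible(x)
}

# Beta parameters of the prior margin for one endpoint.
prior_margin <- function(prior, endpoint = c("efficacy", "toxicity")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "efficacy") {
    beta_params(prior[[1]] + prior[[2]], prior[[3]] + prior[[4]])
  } else {
    beta_params(prior[[1]] + prior[[3]], prior[[2]] + prior[[4]])
  }
}

#' Observed data in one arm
#'
#' @param n Number of enrolled, fully evaluated patients (nonnegative integer).
#' @param x_eff Number of efficacy responses, `0 <= x_eff <= n`.
#' @param x_tox Number of toxicity events, `0 <= x_tox <= n`.
#' @return An object of class `arm_data`.
#' @export
arm_data <- function(n, x_eff = 0L, x_tox = 0L) {
  if (anyNA(c(n, x_eff, x_tox))) stopf("arm data must be non-missing")
  if (n < 0 || n != round(n)) stopf("n must be a nonnegative integer")
  if (x_eff < 0 || x_eff > n || x_eff != round(x_eff)) stopf("x_eff must be an integer in [0, n]")
  if (x_tox < 0 || x_tox > n || x_tox != round(x_tox)) stopf("x_tox must be an integer in [0, n]")
  structure(list(n = as.integer(n), x_eff = as.integer(x_eff), x_tox = as.integer(x_tox)),
            class = "arm_data")
}

#' Beta distribution parameters
#'
#' @param alpha,beta Positive shape parameters.
#' @return An object of class `beta_params`.
#' @export
beta_params <- function(alpha, beta) {
  if (anyNA(c(alpha, beta)) || alpha <= 0 || beta <= 0) stopf("Beta shapes must be positive")
  structure(list(alpha = alpha, beta = beta), class = "beta_params")
}

#' @export
print.beta_params <- function(x, ...) {
  cat(sprintf("Beta(%g, %g)\n", x$alpha, x$beta)); invisible(x)
}

#' Marginal Beta posterior of the efficacy or toxicity rate
#'
#' By conjugacy the joint posterior of the four cell probabilities is
#' Dirichlet (prior pseudo-counts plus cell counts), and aggregating cells
#' gives the Beta posterior of each marginal rate. The posterior depends on
#' the data only through the marginal counts, never the joint cells.
#'
#' @param prior A [normalize_prior()] object.
#' @param data An [arm_data()] object.
#' @param endpoint `"efficacy"` or `"toxicity"`.
#' @return A [beta_params()] object.
#' @examples
#' pr <- normalize_prior(c(0.15, 0.30, 0.15, 0.40))
#' posterior_beta(pr, arm_data(15, x_eff = 9), "efficacy")  # Beta(9.45, 6.55)
#' @export
posterior_beta <- function(prior, data, endpoint = c("efficacy", "toxicity")) {
  endpoint <- match.arg(endpoint)
  if (!inherits(prior, "dirichlet_prior")) prior <- normalize_prior(prior)
  if (!inherits(data, "arm_data")) stopf("data must be an arm_data object")
  m <- prior_margin(prior, endpoint)
  x <- if (endpoint == "efficacy") data$x_eff else data$x_tox
  beta_params(m$alpha + x, m$beta + data$n - x)
}

#' Posterior probability that a rate falls below (or above) a fixed reference
#'
#' `prob_below_fixed()` is the posterior CDF at `phi`, the quantity monitored
#' by the uncontrolled futility rule P(p_E <= phi_E | D); its complement
#' `prob_above_fixed()` serves the toxicity rule P(p_T > phi_T | D).
#'
#' @param post A [beta_params()] posterior.
#' @param phi Reference rate in \[0, 1\].
#' @return A probability.
#' @export
prob_below_fixed <- function(post, phi) {
  if (!inherits(post, "beta_params")) stopf("post must be a beta_params object")
  if (anyNA(phi) || any(phi < 0) || any(phi > 1)) stopf("phi must lie in [0, 1]")
  stats::pbeta(phi, post$alpha, post$beta)
}

#' @rdname prob_below_fixed
#' @export
prob_above_fixed <- function(post, phi) 1 - prob_below_fixed(post, phi)

# ---- exceedance probability P(p_exp > p_ctrl) -------------------------------

# Robust scalar quadrature. Substituting u = F_ctrl(p) turns
#   int (1 - F_exp(p)) f_ctrl(p) dp  into  int_0^1 (1 - F_exp(Q_ctrl(u))) du,
# a bounded integrand on [0,1] with no endpoint singularity even for shape
# parameters < 1. Interior split points at experimental-posterior quantiles
# keep the adaptive rule honest when the integrand is a near-step function
# (both posteriors concentrated and far apart).
exceedance_quad <- function(a1, b1, a2, b2, tol = 1e-10) {
  f <- function(u) 1 - stats::pbeta(stats::qbeta(u, a2, b2), a1, b1)
  qs <- c(1e-10, 1e-4, 0.01, 0.1, 0.5, 0.9, 0.99, 1 - 1e-4, 1 - 1e-10)
  knots <- sort(unique(c(0, 1, stats::pbeta(stats::qbeta(qs, a1, b1), a2, b2))))
  tot <- 0
  for (i in seq_len(length(knots) - 1L)) {
    lo <- knots[i]; hi <- knots[i + 1L]
    if (hi - lo < 1e-14) next
    r <- stats::integrate(f, lo, hi, rel.tol = tol, abs.tol = tol,
                          stop.on.error = FALSE)
    if (r$message != "OK" && !grepl("roundoff", r$message, fixed = TRUE)) {
      stopf("exceedance quadrature failed on [%.3g, %.3g] for Beta(%g,%g) vs Beta(%g,%g): %s",
            lo, hi, a1, b1, a2, b2, r$message)
    }
    tot <- tot + r$value
  }
  min(max(tot, 0), 1)
}

# session cache: posterior shapes arising in trials are discrete
# (prior margin + integer counts), so repeated looks hit the same keys
.exc_cache <- new.env(parent = emptyenv())

#' Probability that one Beta-distributed rate exceeds another
#'
#' Computes P(p_exp > p_ctrl) for independent Beta posteriors by adaptive
#' quadrature of the control density against the experimental survival
#' function, to absolute accuracy better than 1e-8. This is the building
#' block of the controlled-setting stopping rules: the futility rule uses
#' P(p_E <= p_0E | D) = 1 - P(p_E > p_0E | D) and the toxicity rule uses
#' P(p_T > p_0T | D) directly.
#'
#' @param post_exp,post_ctrl [beta_params()] posteriors of the experimental
#'   and control rates.
#' @return A probability.
#' @seealso [beta_exceedance()] for the vectorized, cached form used by the
#'   simulator.
#' @examples
#' prob_exceeds_control(beta_params(1, 1), beta_params(1, 1))  # 0.5
#' @export
prob_exceeds_control <- function(post_exp, post_ctrl) {
  if (!inherits(post_exp, "beta_params") || !inherits(post_ctrl, "beta_params"))
    stopf("both arguments must be beta_params objects")
  exceedance_quad(post_exp$alpha, post_exp$beta, post_ctrl$alpha, post_ctrl$beta)
}

#' Vectorized Beta exceedance probabilities
#'
#' Vectorized over the four shape vectors (recycled to a common length);
#' duplicate parameter tuples are computed once and all results are cached
#' for the session, which makes repeated interim-analysis lookups cheap.
#'
#' @param a1,b1 Shapes of the experimental posterior.
#' @param a2,b2 Shapes of the control posterior.
#' @return Numeric vector of P(Beta(a1, b1) > Beta(a2, b2)).
#' @export
beta_exceedance <- function(a1, b1, a2, b2) {
  m <- cbind(a1, b1, a2, b2)
  if (anyNA(m) || any(m <= 0)) stopf("all Beta shapes must be positive")
  keys <- sprintf("%.9g|%.9g|%.9g|%.9g", m[, 1], m[, 2], m[, 3], m[, 4])
  first <- !duplicated(keys)
  ukeys <- keys[first]
  um <- m[first, , drop = FALSE]
  uvals <- numeric(length(ukeys))
  for (i in seq_along(ukeys)) {
    v <- .exc_cache[[ukeys[i]]]
    if (is.null(v)) {
      v <- exceedance_quad(um[i, 1], um[i, 2], um[i, 3], um[i, 4])
      assign(ukeys[i], v, envir = .exc_cache)
    }
    uvals[i] <- v
  }
  uvals[match(keys, ukeys)]
}
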