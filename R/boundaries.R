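# Decision-threshold families.
#
# The stopping rules compare posterior probabilities with a cutoff C_n that
# depends on the information fraction n/N. Four families are supported:
#   single_arm  C_n = 1 - lambda (n/N)^gamma        (the original single-arm form)
#   multi_arm   same form, but (lambda, gamma) calibrated for K arms jointly
#   active_arm  C_{n,a} = 1 - ((eta - lambda)/eta) (n/N)^gamma, eta = K + 1 - a,
#               which relaxes the cutoff when many arms are still active
#   constant    C_n = eps at every analysis (the constant-threshold comparator)
# gamma <= 1 keeps the boundary convex: stringent early, relaxing as data
# accumulate.

#' Specify a decision-threshold family
#'
#' @param family One of `"single_arm"`, `"multi_arm"`, `"active_arm"`,
#'   `"constant"`.
#' @param lambda Threshold parameter in (0, 1); ignored by `constant`.
#' @param gamma Shape parameter in (0, 1\]; ignored by `constant`.
#' @param eps Constant cutoff in (0, 1); `constant` family only.
#' @param K Number of experimental arms; required by `active_arm`.
#' @return An object of class `threshold_spec`.
#' @examples
#' threshold_spec("multi_arm", lambda = 0.63, gamma = 1)
#' threshold_spec("constant", eps = 0.92)
#' @export
threshold_spec <- function(family = c("single_arm", "multi_arm", "active_arm", "constant"),
                           lambda = NULL, gamma = NULL, eps = NULL, K = NULL) {
  family <- match.arg(family)
  if (family == "constant") {
    if (is.null(eps) || anyNA(eps) || eps <= 0 || eps >= 1)
      stopf("constant family requires eps in (0, 1)")
    lambda <- gamma <- NULL
  } else {
    if (is.null(lambda) || anyNA(lambda) || lambda <= 0 || lambda >= 1)
      stopf("%s family requires lambda in (0, 1)", family)
    if (is.null(gamma) || anyNA(gamma) || gamma <= 0 || gamma > 1)
      stopf("%s family requires gamma in (0, 1]", family)
    eps <- NULL
  }
  if (family == "active_arm") {
    if (is.null(K) || anyNA(K) || K < 1 || K != round(K))
      stopf("active_arm family requires integer K >= 1")
    K <- as.integer(K)
  } else K <- NULL
  structure(list(family = family, lambda = lambda, gamma = gamma, eps = eps, K = K),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  switch(x$family,
    constant = cat(sprintf("Constant threshold eps = %g\n", x$eps)),
    active_arm = cat(sprintf(
      "Active-arm threshold C(n,a) = 1 - ((eta - %g)/eta) (n/N)^%g, eta = %d + 1 - a\n",
      x$lambda, x$gamma, x$K)),
    cat(sprintf("%s threshold C(n) = 1 - %g (n/N)^%g\n",
                if (x$family == "single_arm") "Single-arm" else "Multi-arm",
                x$lambda, x$gamma)))
  invisible(x)
}

#' Evaluate a decision threshold at an analysis
#'
#' @param spec A [threshold_spec()].
#' @param n Number of patients enrolled in the arm at this analysis,
#'   `0 < n <= N`.
#' @param N Maximum sample size per arm anchoring the information fraction.
#' @param active_arms Number `a` of experimental arms still active at the
#'   analysis (`active_arm` family only), `1 <= a <= K`.
#' @return The cutoff, a value in (0, 1\].
#' @examples
#' sp <- threshold_spec("single_arm", lambda = 0.63, gamma = 1)
#' threshold_value(sp, n = 20, N = 80)  # 0.8425
#' threshold_value(sp, n = 80, N = 80)  # 0.37
#' @export
threshold_value <- function(spec, n, N, active_arms = NULL) {
  if (!inherits(spec, "threshold_spec")) stopf("spec must be a threshold_spec")
  if (anyNA(n) || any(n <= 0) || anyNA(N) || any(N <= 0)) stopf("n and N must be positive")
  if (any(n > N)) stopf("analysis size n exceeds the planned maximum N")
  frac <- (n / N)
  switch(spec$family,
    constant = rep_len(spec$eps, length(frac)),
    single_arm = ,
    multi_arm = 1 - spec$lambda * frac^spec$gamma,
    active_arm = {
      a <- active_arms
      if (is.null(a) || anyNA(a)) stopf("active_arm family requires active_arms")
      if (any(a < 1) || any(a > spec$K)) stopf("active_arms must lie in [1, K]")
      eta <- spec$K + 1 - a
      1 - ((eta - spec$lambda) / eta) * frac^spec$gamma
    })
}

#' Operational cutoff for the active-arm rule
#'
#' The active-arm threshold alone controls the FWER but not the arm-specific
#' type I error when most arms are promising; taking the minimum with a
#' single-arm threshold restores arm-specific control. This minimum is the
#' cutoff actually applied when the `active_arm` family is simulated or
#' calibrated.
#'
#' @param multi_spec An `active_arm` [threshold_spec()].
#' @param single_spec A `single_arm` [threshold_spec()] companion.
#' @param n,N,a As in [threshold_value()].
#' @return `min(C(n, a), C_single(n))`.
#' @export
effective_cutoff <- function(multi_spec, single_spec, n, N, a) {
  if (multi_spec$family != "active_arm") stopf("multi_spec must have family 'active_arm'")
  if (single_spec$family != "single_arm") stopf("single_spec must have family 'single_arm'")
  pmin(threshold_value(multi_spec, n, N, active_arms = a),
       threshold_value(single_spec, n, N))
}
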