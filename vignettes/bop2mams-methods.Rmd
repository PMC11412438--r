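---
title: "Methods: Bayesian optimal multi-arm multi-stage designs with efficacy and toxicity monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian optimal multi-arm multi-stage designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The outcome model

Every evaluable patient in arm $k$ realizes one of four mutually exclusive
joint outcomes — toxicity with response ($TE$), response without toxicity
($\bar T E$), toxicity without response ($T\bar E$), neither
($\bar T\bar E$) — so a cohort of $m$ patients is multinomial with
probability vector $\theta_k = (\theta_{TE}, \theta_{\bar TE},
\theta_{T\bar E}, \theta_{\bar T\bar E})$. The prior on $\theta_k$ is
Dirichlet with pseudo-counts rescaled to sum to 1 (`normalize_prior()`), a
deliberately weak, *skeptical* prior: its center is the
inefficacy/toxicity hypothesis itself, and its total weight is a single
patient, so interim conclusions are driven by the data almost immediately.

Conjugacy and the aggregation property of the Dirichlet give the two
quantities the monitoring rules need in closed form: the marginal response
rate $p_{k,E}$ and toxicity rate $p_{k,T}$ have Beta posteriors whose
parameters are the aggregated prior pseudo-counts plus the marginal counts
$(x_{k,E}, n_k - x_{k,E})$ and $(x_{k,T}, n_k - x_{k,T})$
(`posterior_beta()`). The joint cell counts never enter the rules — only
the margins do — but the *correlation* between the endpoints still matters
for operating characteristics, because it shapes the joint distribution of
the two monitored statistics.

## Stopping rules and decision thresholds

At each analysis with $n_k$ evaluable patients, an active arm stops when
either posterior probability strictly exceeds the cutoff $C_n$:

* **uncontrolled**: $P(p_{k,E} \le \phi_E \mid D) > C_n$ (futility) or
  $P(p_{k,T} > \phi_T \mid D) > C_n$ (toxicity), with fixed reference
  rates $\phi_E$, $\phi_T$;
* **controlled**: the same two rules with $\phi$ replaced by the control
  arm's rates, evaluated through the exceedance probability
  $P(p_{k,\cdot} > p_{0,\cdot} \mid D) = \int_0^1 (1 - F_k(p)) f_0(p)\,dp$
  between independent Beta posteriors.

Strict inequality matters only at the extremes: a cutoff of exactly 1 can
never be crossed (an arm always continues), while a cutoff of 0 is crossed
by any positive posterior probability.

An arm that reaches the terminal analysis without triggering either rule is
declared *promising* (efficacy and acceptable toxicity). There is no
separate terminal success test and no early-graduation rule: the design
stops arms only for futility or toxicity, so the terminal decision is the
complement of the stopping rule at full information.

Four cutoff families (`threshold_spec()`):

| family | cutoff at $n$ of $N$ | role |
|---|---|---|
| `single_arm` | $1 - \lambda (n/N)^\gamma$ | original single-arm boundary |
| `multi_arm` | same form | $(\lambda,\gamma)$ calibrated jointly for $K$ arms |
| `active_arm` | $1 - \frac{\eta - \lambda}{\eta}(n/N)^\gamma$, $\eta = K + 1 - a$ | relaxes as more arms stay active |
| `constant` | $\varepsilon$ | constant-threshold comparator |

$\gamma \le 1$ keeps the boundary convex — very strict when data are
sparse, relaxing as information accrues. The active-arm boundary is
strictly increasing in the number $a$ of active arms and equals
$1 - (1 - \lambda)(n/N)^\gamma$ when all $K$ arms are active. Because
relaxing the cutoff when most arms are promising can leak arm-specific
type I error, the *operational* active-arm rule is
$\min(C^m_{n,a}, C^s_n)$ with a single-arm companion boundary
(`effective_cutoff()`); the minimum restores arm-specific control while
keeping the family-wise gain. One note on the $C^m_{n,a}$ formula: its
typeset form is ambiguous, and we adopt the reading
$1 - ((\eta-\lambda)/\eta)(n/N)^\gamma$ — the only one that is increasing
in $a$ and reduces to the BOP2-type form at $\eta = 1$.

Two conventions fix the within-look semantics: all arms analysed at a look
are evaluated against the *same* $a$, counted before any decision of that
look takes effect (decisions within a look are simultaneous), and the
control arm never counts toward $a$ and never stops.

## Calibration

`calibrate()` performs the grid search. The key computational observation:
for the $1 - \lambda(n/N)^\gamma$ families the simulated trial
trajectories do not depend on $(\lambda, \gamma)$, and an arm survives the
whole trial iff

$$\lambda \;\le\; L \;=\; \min_j \frac{1 - M_j}{(n_j/N)^\gamma},
\qquad M_j = \max(\text{futility prob}, \text{toxicity prob at look } j).$$

So one set of simulations per configuration yields, for each $\gamma$, a
per-replicate statistic $L$ whose empirical tail function gives the FWER
and power at *every* $\lambda$ simultaneously. This makes the full default
grid ($\lambda \in \{0.01,\dots,0.99\}$ by 0.01, $\gamma \in
\{0.05,\dots,1\}$ by 0.05) essentially free and gives exact common random
numbers across grid points, which stabilizes the argmax. The constant
family uses $\max_j M_j$ the same way; only the active-arm family, whose
cutoff couples the arms, is swept point by point (vectorized across
replicates).

The feasible set keeps grid points whose estimated FWER under the global
null (all arms, and the control, at the inadmissible hypothesis $H_0$) is
at most the nominal level; among them the point maximizing power under the
least favourable configuration (one arm at $H_1$, the rest at $H_0$) is
returned. Ties within one Monte Carlo standard error of the best power are
broken toward lower FWER, then toward the more stringent boundary (larger
$\lambda$, smaller $\varepsilon$) — more early stopping and smaller
expected sample size at equal power. The full audit grid is kept in the
result for inspection. `calibrate_dual_null()` adds FWER constraints under
two discordant global nulls (safe-but-ineffective, effective-but-toxic);
the feasible set can only shrink, so its power never exceeds the
single-null calibration on the same grid and seed.

Grid resolution and the calibration replicate count are not externally
mandated anywhere; the defaults (0.01/0.05 steps, $R_{cal} = 10{,}000$)
were chosen once so that $\gamma = 1$ is reachable and the selection noise
at a 10% error rate (MC SE $\approx 0.3$ points) is small against the
grid's power differences. Different but equally feasible $(\lambda,
\gamma)$ choices can emerge from different grids or seeds; their operating
characteristics agree within a point or two, which is why power
comparisons against a fixed external benchmark should always carry a
combined calibration-plus-MC tolerance.

## Numerical choices

**Exceedance integral.** The defining integrand
$(1 - F_k(p)) f_0(p)$ is unbounded at an endpoint whenever a Beta shape
parameter is below 1 — always true at the first look under a unit-weight
prior with zero events. We therefore substitute $u = F_0(p)$ and integrate
$u \mapsto 1 - F_k(F_0^{-1}(u))$ over $[0,1]$: the integrand becomes
bounded in $[0,1]$ with no singularity, at the cost of a `qbeta` call per
abscissa. Adaptive quadrature (`stats::integrate`, QUADPACK) is applied on
subintervals split at quantiles of the experimental posterior, which keeps
the adaptive rule reliable when both posteriors are concentrated and far
apart and the integrand is a near-step function. Accuracy is driven well
below $10^{-8}$; anti-symmetry $P(X>Y) + P(Y>X) = 1$ holds to about
$10^{-10}$ across the count space of an 80-patient arm. Because posterior
shapes arising in a trial are discrete (prior margin + integer counts),
results are memoised for the session (`beta_exceedance()`), which is what
makes controlled-setting simulation at $10^4$ replicates cheap: only
count pairs actually observed are ever integrated, once.

**Rounding and degenerate schedules.** Deformed accrual schedules round
cumulative sizes half-to-even (R's `round()`); looks made duplicate by
rounding are merged. Imbalanced accrual draws each arm's per-look increment
as planned $\pm$ uniform on $\{-u,\dots,u\}$, independently across arms,
looks and replicates; the terminal analysis uses whatever cumulative total
results, and a cutoff evaluation past the planned $N$ is treated as full
information. Under reduced accrual (cap $N' < N$) the threshold parameters
remain those calibrated for the planned $N$, but the boundary follows the
actual information fraction $n/N'$ — the terminal analysis still applies
the full-information cutoff $1 - \lambda$. The alternative reading
(evaluating $n/N$ against the planned $N$) would leave the terminal cutoff
far above $1-\lambda$ and forfeit error control entirely under
under-enrollment; the implemented convention keeps the type I error near
its nominal level at any realized sample size, which is the point of the
robustness analysis.

**Control-arm data.** Controlled comparisons at a look use all control
data accrued to that look, with no concurrency windowing; the control
follows its accrual plan to the cap regardless of experimental stops.

## The scenario generator

Simulation scenarios are defined by per-arm joint outcome vectors. The
built-in fixtures publish them as (efficacy, toxicity) marginal pairs; the
joints behind them are reconstructed by a *fixed-cell-shift* rule
(`joint_from_marginals()`): the $TE$ cell is the independence product plus
a constant $\delta$, compensated in the other cells so the margins are
exact, and clipped per arm to the feasible association range. $\delta$ is
anchored so the inadmissible-hypothesis margins reproduce the
inadmissible-hypothesis joint exactly ($\delta = 0.015$ uncontrolled,
$0.06$ controlled); arms sitting exactly at a design hypothesis use the
hypothesis joint itself. This preserves the positive efficacy–toxicity
association the design hypotheses imply. It is an explicit modelling
choice, not ground truth: scenario arms away from the hypotheses could
carry a different association, which would perturb joint-event rates (and
hence promising probabilities) by amounts on the order of the association
shift. The rule is overridable per arm in configs (`delta:`).

What the generator emulates: balanced randomization, fully evaluated
binary outcomes at each analysis, fixed or deformed accrual schedules, and
outcome probabilities constant over time. What it does not: staggered
outcome ascertainment and partial follow-up at interims, patient-level
covariates or drift, unequal or adaptive randomization, and real
concurrency structure between arms. Passing tests therefore validate the
decision machinery under the stated sampling model, not robustness to
those real-data features.

**"Correct selection"** is defined here as a replicate in which *every*
experimental arm's terminal declaration matches its truth label
(admissible arms declared promising, inadmissible ones not). Fixture truth
labels mark an arm admissible only when its margins are at least as good
as the promising hypothesis; intermediate arms count as inadmissible. Both
conventions are isolated (`fixture_truth()`, `estimate_oc(truth_labels =)`)
so alternatives can be swapped.

## The retrospective platform fixture

`load_fixture("aza_plus")` encodes the motivating retrospective design: a
three-arm randomized platform in high-risk myelodysplastic syndrome with
an azacitidine control and **two** experimental combination arms, 80
patients per arm, analyses at 20/40/60/80, prior equal to the
inefficacy/toxicity hypothesis Dir(0.15, 0.25, 0.15, 0.45), promising
hypothesis (0.15, 0.40, 0.05, 0.40), FWER target 15%, and the published
multi-arm threshold $\lambda = 0.63$, $\gamma = 1$. The two-experimental-
arm structure follows the trial itself (control vs. two combinations); a
three-experimental-arm variant of the same threshold produces a
family-wise error far above the design's documented level and is not what
the fixture represents.

## Problem sizes and test design

The test suite validates the probability core against independent
oracles: direct quadrature of the defining integrals, a $10^6$-draw Monte
Carlo check of the exceedance probability, and exact enumeration of all
multinomial outcome paths on toy designs ($N \le 4$, up to 2 looks, up to
2 arms, controlled and uncontrolled), where every operating characteristic
has a closed-form value to compare against at Monte Carlo tolerance.
End-to-end checks simulate 10,000 replicates — the replication count the
published operating characteristics use, giving an MC standard error of
about 0.3 points at a 10% rate — with calibrations on a reduced grid
($\lambda$ step 0.02, $\gamma$ step 0.1) at $R_{cal} = 10{,}000$. The
acceptance script uses the full default grid. These sizes keep the whole
suite within a few minutes on one CPU while leaving the Monte Carlo noise
small against every tolerance asserted.

## Known limitations

* Futility/toxicity stopping only; no early-graduation (efficacy) rules.
* Two binary endpoints; the Dirichlet machinery extends to $2^m$ cells for
  $m > 2$ endpoints but this is not implemented.
* Balanced randomization only; no adaptive allocation.
* No borrowing across arms or subgroups (each arm's posterior uses its own
  data plus the shared prior).
* Calibration optimizes $(\lambda, \gamma)$ on a grid for a fixed interim
  schedule; the schedule itself is not optimized.
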