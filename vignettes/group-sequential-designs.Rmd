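---
title: "Group-sequential stopping rules: frequentist boundaries, Bayesian thresholds, and where they meet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-sequential stopping rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqbayes)
```

## The model

A group-sequential trial inspects accumulating data at up to $K$ scheduled
looks and may stop early for efficacy. seqbayes works in the standard
normal-statistics setting: the cumulative mean $\bar Y_k$ at look $k$ is
normal with mean $\theta$ (the treatment effect) and variance $1/I_k$, where
$I_k = n_k/\sigma^2$ is the statistical *information* accrued by look $k$.
Jointly, $\mathrm{cov}(\bar Y_k, \bar Y_{k'}) = 1/I_{k'}$ for $k < k'$, so
the standardized statistics $Z_k = \bar Y_k \sqrt{I_k}$ have unit variance
and correlation $\sqrt{I_k/I_{k'}}$. A two-arm difference in means has the
same structure with $I_k = (\sigma_1^2/n_{1k} + \sigma_0^2/n_{0k})^{-1}$, so
one engine serves both cases.

A frequentist design stops at look $k$ when $Z_k \ge u_k$; the boundary
vector is chosen so that the overall probability of ever stopping under the
null ($\theta = 0$) equals a one-sided level $\alpha$. A Bayesian design
places a conjugate normal prior $\theta \sim N(\theta_0, 1/I_0)$ and stops
when the posterior probability $\Pr(\theta > 0 \mid \bar y_k) \ge p_k$.
Because that posterior probability is increasing in $\bar y_k$, the Bayesian
rule is itself a boundary rule,
$$u^B_k = \frac{-\theta_0 I_0 - \sqrt{I_0 + I_k}\,\Phi^{-1}(1 - p_k)}{\sqrt{I_k}},$$
and the two families are two parameterizations of one class: any spending
sequence maps to thresholds and back (`p_from_frequentist()`,
`bayes_boundaries()`), exactly. Everything in the package flows from that
observation — except the two-arm independent-prior case, where it breaks
down (see below).

## The crossing engine

All operating characteristics reduce to first-crossing probabilities
$$\Pr(Z_1 < u_1, \dots, Z_{k-1} < u_{k-1},\ Z_k \ge u_k;\ \theta).$$
`crossing_probabilities()` computes these by an Armitage-type forward
recursion: the sub-density of the still-continuing statistic is propagated
look to look through the independent-increments representation
$W_k = Z_k\sqrt{I_k}$, with $W_k - W_{k-1} \sim N(\theta\,\Delta I_k, \Delta
I_k)$, truncating at each boundary. The density lives on a uniform grid
spanning 8 standardized units either side of the drifted mean, integrated
with composite Simpson weights.

Numerical choices, and why:

* **Grid**: 601 nodes per look by default (minimum 301, forced odd). At the
  default the five-look cumulative probabilities are stable to well below
  $10^{-7}$ under grid doubling, and agree with multivariate-normal
  rectangle probabilities (`method = "mvnorm"`, via `mvtnorm` with the
  deterministic Miwa algorithm) to about $10^{-10}$. The recursion is the
  default because it is deterministic and scales linearly in $K$; the
  rectangle route is retained as an independent cross-check.
* **Root searches**: boundary values are bracketed on $[-10, 10]$ (standard
  deviations) and solved with `uniroot` to $10^{-8}$ on the probability
  scale. Threshold calibrations (`find_common_p*()`) search on the logit
  scale — the interesting thresholds cluster near 1, where the logit
  transform keeps the root finder well conditioned — to $10^{-6}$ in
  $\alpha$.
* **No-stopping looks**: a boundary of `+Inf` spends nothing and passes the
  continuing density through unchanged; it is the sentinel produced when a
  spending target equals the alpha already spent.
* **Degenerate inputs**: schedules must be strictly increasing (duplicate
  information would make the joint law singular); thresholds $p_k = 1$ are
  rejected rather than silently mapped to an infinite boundary.

A Monte-Carlo oracle (`simulate_paths()`, and analogues for the binomial and
two-arm modules) simulates the same independent-increments representation
directly. It shares no code with the quadrature beyond the model statement,
and the test suite holds the two within three binomial standard errors
across randomized configurations.

## Frequentist constructions

`pocock_design()` (constant $u_k = c$) and `obf_design()` (constant score
boundary, $u_k = C/\sqrt{I_k}$) find their constants by root search on the
exact crossing probability. `design_from_spending()` implements the
spending-function approach: given cumulative targets
$\alpha^*(I_k/I_K)$, the boundary at each look is solved recursively with
`solve_boundary_at_look()`. Available families are the linear rule
$\alpha t$, the Pocock-like $\alpha\log(1 + (e-1)t)$, the O'Brien–Fleming
approximation $2(1 - \Phi(z_{\alpha/2}/\sqrt t))$ (its $t = 0$ value is the
continuity limit 0), and explicit per-look vectors. Unequally spaced looks
are allowed everywhere: "Pocock" then means constant standardized boundary
and "OBF" constant score boundary, the defining properties rather than the
tabulated equal-spacing cases; the constructors warn, since the classical
constants assume equal spacing.

Two cautions surfaced by the test suite are worth knowing. The exact
spending of the constant-boundary constructions — not the Lan–DeMets
analytic approximations — is what reproduces the classical tabulated
boundaries; and the O'Brien–Fleming spending approximation is deliberately
conservative early, sitting up to a few tenths of a Z unit above the exact
boundary at the first looks of a five-look design while agreeing to better
than 0.05 from mid-trial on.

## Bayesian designs and calibration

`bayes_design()` either accepts thresholds $p_k$ or calibrates a common
$p$ so the design's frequentist size is a target $\alpha$
(`find_common_p()`). The calibrated threshold responds to the prior exactly
as intuition suggests: informative negative priors demand overwhelming data
early (boundaries like $4.4, 3.2, 2.6, \dots$ — an O'Brien–Fleming shape),
the flat prior reproduces Pocock's constant boundary exactly
($u^B_k = \Phi^{-1}(p)$, constant), and mildly informative priors land near
the linear-spending design. The monotone ordering of calibrated thresholds
across priors is asserted in the tests.

For a single-arm binary endpoint, `binom_design()` works on the exact
binomial likelihood with a conjugate $Beta(a, b)$ prior: posterior tail
probabilities convert to integer success thresholds
(`success_thresholds()`), and the exact type I error of the resulting rule
comes from a forward recursion over the continuation distribution of the
cumulative success count (`exact_type1()`) — no normal approximation. The
type I error is a left-continuous step function of the common threshold
$p$, so "the" calibrated threshold is a convention: `find_common_p_binomial()`
locates the infimum of the controlling interval (the largest attainable
posterior-tail value whose design still violates $\alpha$) and reports the
smallest value on a display grid (default $10^{-3}$) strictly above it.
For the canonical four-look design ($n = 25, 50, 75, 100$, $\pi_0 = 0.5$,
$\alpha = 0.05$) this gives $p = 0.977$ and thresholds $18, 33, 47, 61$ —
identical to rounding up the real-valued thresholds of the four-look Pocock
comparator built on the normal approximation
(`normal_approx_design()`, constant 2.067). The recursion uses plain
double-precision accumulation: the state space is at most $n_K + 1$
well-scaled probabilities and the tests pin it against closed-form binomial
tails and simulation.

## Two arms, independent priors: where equivalence fails

With independent per-arm priors $\mu_j \sim N(\mu_{j0}, 1/I_{j0})$, the
posterior mean of $\theta = \mu_1 - \mu_0$,
$$M_k = \frac{\mu_{10} I_{10} + \bar y_{1k} I_{1k}}{I_{10} + I_{1k}}
      - \frac{\mu_{00} I_{00} + \bar y_{0k} I_{0k}}{I_{00} + I_{0k}},$$
depends on the two arm means separately, not only on their difference —
independence of the priors makes $\theta$ informative about $\mu_1 + \mu_0$
and vice versa, which is also why the posterior precision under independent
priors never falls below the collapsed-prior precision
(`precision_compare()`; equality exactly when the information ratio
$\Lambda_k = (I_{1k}/I_{0k})/(I_{10}/I_{00})$ is 1). Unless the shrinkage
weights coincide at every look (`proportionality_check()`), no frequentist
boundary on $D_k$ reproduces the Bayesian rule, and the null stopping
probability depends on the true control mean $\mu_0$: under $\mu_1 = \mu_0$
the drift of $M_k$ grows linearly in $\mu_0$, so the error rate is
calibrated at one reference value (`find_common_p_two_param()`) and
inflates on one side of it (`type1_profile()`).

The joint law of $M_1, \dots, M_K$ is Gaussian with covariance assembled
analytically from the linear-in-means representation; its crossing
probabilities are not of the nested single-process form the recursion
assumes, so they are evaluated as multivariate-normal rectangle
probabilities (Miwa, 4097 grid points — deterministic and exact to far
below the $10^{-6}$ calibration tolerance for $K \le 5$). Non-informative
arms enter by direct limit substitution ($I_{j0} = 0$), never by a small-ε
stand-in. The default profile grid, $\mu_0 \in [-2, 3]$ in steps of 0.05,
brackets the effective support of a moderately informative control prior
on either side of its mean; it is a display choice, not a model input.

One practical warning this module makes vivid: the calibrated threshold is
quite sensitive to the *scale* on which prior information is stated. For
the five-look reference configuration (per-arm information $4, \dots, 20$,
control prior information 0.5, flat experimental prior) the exactly
calibrated common threshold is $p = 0.9914$. Treating the same "0.5" as a
prior standard deviation or variance instead of a precision — an easy slip
when moving between tools that parameterize priors differently — shifts the
answer to about $0.9884$. Stating the prior's units explicitly (information,
i.e. inverse variance, on the same scale as the per-arm data information)
is the package's convention throughout.

## What the reference scenarios do and do not show

`reference_scenarios()` fixes fifteen fully specified designs — the
five-look normal setting under three frequentist rules and ten priors, the
exact binomial design with its comparator, and the two-arm profile — and
`verify_scenarios()` recomputes each and checks the frozen values
(boundaries to 2 decimals, thresholds and error rates to 4, success counts
exactly, with one printed unit of slack where two tabulations of the same
quantity round differently). Passing them shows the *design machinery* is
right: joint normal law, exact binomial recursion, calibration. It says
nothing about robustness to what the model assumes away — unknown or
misspecified variance, non-normal outcomes at small $n$, information that
arrives differently from the plan, or futility stopping. Boundaries here
are efficacy-only and one-sided; a binding futility rule would change every
operating characteristic.

Problem sizes in the tests mirror desk use: $K \le 5$, quadrature at the
601-node default, oracle simulations of $2\times10^5$–$5\times10^5$ paths
(three-standard-error agreement bands), and 1000 random configurations for
the precision inequality. These sizes were chosen so the full suite
exercises every claim in minutes on one core while leaving the
Monte-Carlo bands narrow enough to detect a $10^{-3}$ bias in any crossing
probability.

## Known limitations

* Known-variance normal statistics only; no $t$-corrections.
* Efficacy (upper) boundaries only; no futility or two-sided rules.
* Two arms at most, with independent or collapsed priors; no correlated
  priors and no multi-arm extensions.
* Bayes-factor and predictive-probability stopping are supported only
  insofar as they are monotone in $\bar Y_k$ and hence reducible to a
  shifted threshold (`posterior_prob_positive(..., delta = )`); the package
  does not construct them directly.
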