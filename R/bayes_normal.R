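#' Conjugate normal prior for a scalar treatment effect
#'
#' Prior \eqn{\theta \sim N(\theta_0, 1/I_0)}. `info0 = 0` encodes the flat
#' improper prior, under which the prior mean is irrelevant and the posterior
#' is driven entirely by the data. In a two-arm trial this prior may be
#' placed directly on the difference in means; the machinery is identical
#' with \eqn{I_k} the information of the difference.
#'
#' @param theta0 Prior mean.
#' @param info0 Prior information (inverse variance), `>= 0`.
#' @return An object of class `normal_prior`.
#' @examples
#' normal_prior(-0.25, 20)
#' @export
normal_prior <- function(theta0 = 0, info0 = 0) {
  check_scalar_num(theta0, "theta0")
  check_scalar_num(info0, "info0", lower = 0)
  structure(list(theta0 = theta0, info0 = info0), class = "normal_prior")
}

#' @export
print.normal_prior <- function(x, ...) {
  if (x$info0 == 0) {
    cat("<normal_prior> flat (info0 = 0)\n")
  } else {
    cat("<normal_prior> theta0 =", format(x$theta0),
        " info0 =", format(x$info0), "\n")
  }
  invisible(x)
}

check_prior <- function(prior) {
  if (!inherits(prior, "normal_prior")) {
    abort("`prior` must be a normal_prior.", class = "seqbayes_error_input")
  }
  prior
}

#' Posterior for the effect given the cumulative mean at a look
#'
#' Conjugate update: observing cumulative mean `ybar` with information
#' `info_k` gives \eqn{\theta \mid \bar y_k \sim
#' N((\theta_0 I_0 + \bar y_k I_k)/(I_0 + I_k),\ 1/(I_0 + I_k))}.
#'
#' @param prior A [normal_prior()].
#' @param ybar Observed cumulative mean.
#' @param info_k Information at the look (positive).
#' @return A list with `mean` and `precision` (\eqn{I_0 + I_k}).
#' @examples
#' posterior_normal(normal_prior(-0.25, 20), ybar = 0, info_k = 2)
#' @export
posterior_normal <- function(prior, ybar, info_k) {
  check_prior(prior)
  if (!is.numeric(info_k) || any(info_k <= 0)) {
    abort("`info_k` must be positive.", class = "seqbayes_error_input")
  }
  prec <- prior$info0 + info_k
  list(mean = (prior$theta0 * prior$info0 + ybar * info_k) / prec,
       precision = prec)
}

#' Posterior probability of a positive effect
#'
#' \eqn{Pr(\theta > \delta \mid \bar y_k) = 1 - \Phi\big((-\bar y_k I_k -
#' \theta_0 I_0 + \delta(I_0 + I_k)) / \sqrt{I_0 + I_k}\big)}; strictly
#' increasing in `ybar`. `delta = 0` (default) is the usual
#' probability-of-benefit criterion; a positive `delta` asks for benefit
#' beyond a target value, which shifts the threshold but leaves the boundary
#' machinery unchanged.
#'
#' @inheritParams posterior_normal
#' @param delta Effect value that must be exceeded (default 0).
#' @return Posterior tail probability.
#' @examples
#' posterior_prob_positive(normal_prior(0, 0), ybar = 1.96 / 2, info_k = 4)
#' @export
posterior_prob_positive <- function(prior, ybar, info_k, delta = 0) {
  post <- posterior_normal(prior, ybar, info_k)
  pnorm((delta - post$mean) * sqrt(post$precision), lower.tail = FALSE)
}

check_p_vec <- function(p, K) {
  if (!is.numeric(p) || anyNA(p)) {
    abort("`p` must be numeric.", class = "seqbayes_error_input")
  }
  if (length(p) == 1L) p <- rep(p, K)
  if (length(p) != K) {
    abort("`p` must have one threshold per look.",
          class = "seqbayes_error_dimension")
  }
  if (any(p <= 0 | p >= 1)) {
    abort("Posterior thresholds must lie strictly in (0, 1); p = 1 makes stopping impossible.",
          class = "seqbayes_error_input")
  }
  p
}

#' Standardized boundaries implied by posterior thresholds
#'
#' The rule "stop at look \eqn{k} if \eqn{Pr(\theta > 0 \mid data) \ge p_k}"
#' is equivalent to crossing \eqn{u^B_k = (-\theta_0 I_0 - \sqrt{I_0 + I_k}\,
#' \Phi^{-1}(1 - p_k))/\sqrt{I_k}} on the Z scale, so every Bayesian design
#' of this form is also a frequentist boundary design.
#'
#' @inheritParams posterior_normal
#' @param p Posterior threshold(s): scalar (recycled) or one per look, in (0,1).
#' @param schedule An [info_schedule()].
#' @return Numeric vector of K standardized boundaries.
#' @examples
#' bayes_boundaries(normal_prior(-0.25, 20), 0.6063, info_schedule(c(2, 4, 6, 8, 10)))
#' @export
bayes_boundaries <- function(prior, p, schedule) {
  check_prior(prior)
  sched <- as_info_schedule(schedule)
  p <- check_p_vec(p, sched$K)
  I_k <- sched$info
  (-prior$theta0 * prior$info0 -
      sqrt(prior$info0 + I_k) * qnorm(1 - p)) / sqrt(I_k)
}

#' Frequentist alpha spent by a Bayesian design
#'
#' Cumulative crossing probabilities under the null (\eqn{\theta = 0}) of the
#' boundaries implied by the posterior thresholds. The final element is the
#' frequentist type I error of the Bayesian stopping rule.
#'
#' @inheritParams bayes_boundaries
#' @inheritParams crossing_probabilities
#' @return Cumulative alpha vector \eqn{\alpha^B_1, \dots, \alpha^B_K}.
#' @examples
#' bayes_alpha_spent(normal_prior(0, 0), 0.9921, info_schedule(c(2, 4, 6, 8, 10)))
#' @export
bayes_alpha_spent <- function(prior, p, schedule, nodes = 601) {
  sched <- as_info_schedule(schedule)
  bounds <- bayes_boundaries(prior, p, sched)
  crossing_probabilities(sched, bounds, theta = 0, nodes = nodes)$cumulative
}

#' Calibrate a common posterior threshold to a target type I error
#'
#' Finds the common \eqn{p_1 = \dots = p_K = p} whose implied boundaries have
#' overall null crossing probability `alpha`. The search is a monotone root
#' find on the logit scale (the type I error is strictly decreasing in
#' \eqn{p}), to within 1e-6 on the alpha scale.
#'
#' @inheritParams bayes_boundaries
#' @inheritParams pocock_design
#' @return The common threshold \eqn{p}.
#' @examples
#' find_common_p(normal_prior(0, 0), info_schedule(c(2, 4, 6, 8, 10)), 0.025)
#' @export
find_common_p <- function(prior, schedule, alpha, nodes = 601) {
  check_prior(prior)
  sched <- as_info_schedule(schedule)
  check_scalar_prob(alpha, "alpha")
  nodes <- make_node_count(nodes)
  type1 <- function(l) {
    b <- bayes_boundaries(prior, plogis(l), sched)
    sum(gs_states(sched$info, b, 0, nodes)$per_look)
  }
  lo <- qlogis(0.5)
  hi <- qlogis(1 - 1e-12)
  f_lo <- type1(lo + 1e-9) - alpha
  f_hi <- type1(hi) - alpha
  if (f_lo < 0 || f_hi > 0) {
    abort("No common threshold in (0.5, 1) attains the target alpha.",
          class = "seqbayes_error_infeasible")
  }
  root <- uniroot(function(l) type1(l) - alpha, c(lo + 1e-9, hi),
                  tol = 1e-10)$root
  p <- plogis(root)
  if (abs(type1(root) - alpha) > 1e-6) {
    abort("Threshold calibration did not reach the 1e-6 alpha tolerance.",
          class = "seqbayes_error_numeric")
  }
  p
}

#' Posterior thresholds reproducing a frequentist boundary
#'
#' Inverse of [bayes_boundaries()]: \eqn{p_k = 1 - \Phi\big((-u_k\sqrt{I_k} -
#' \theta_0 I_0)/\sqrt{I_0 + I_k}\big)}. A Bayesian design using these
#' thresholds stops exactly when the frequentist design with boundaries
#' `bounds` does.
#'
#' @inheritParams bayes_boundaries
#' @param bounds Standardized boundary vector of the frequentist design.
#' @return Threshold vector \eqn{p_1, \dots, p_K}.
#' @examples
#' p_from_frequentist(normal_prior(0, 0), rep(2.41, 5),
#'                    info_schedule(c(2, 4, 6, 8, 10)))
#' @export
p_from_frequentist <- function(prior, bounds, schedule) {
  check_prior(prior)
  sched <- as_info_schedule(schedule)
  u <- check_bounds(bounds, sched$K)
  I_k <- sched$info
  pnorm((-u * sqrt(I_k) - prior$theta0 * prior$info0) /
          sqrt(prior$info0 + I_k), lower.tail = FALSE)
}

#' Bayesian group-sequential design for a scalar normal effect
#'
#' Builds the complete design: either from given posterior thresholds `p`, or
#' by calibrating a common threshold to the target type I error `alpha` via
#' [find_common_p()]. Records the implied standardized boundaries and the
#' exact cumulative alpha spent.
#'
#' @inheritParams bayes_boundaries
#' @param p Posterior thresholds (scalar or per look); supply exactly one of
#'   `p` and `alpha`.
#' @param alpha Target overall one-sided type I error for calibration.
#' @inheritParams crossing_probabilities
#' @return A `gs_design` (subclass `bayes_design`) with fields `prior` and `p`.
#' @examples
#' bayes_design(normal_prior(0.0, 0.5), info_schedule(c(2, 4, 6, 8, 10)),
#'              alpha = 0.025)
#' @export
bayes_design <- function(prior, schedule, p = NULL, alpha = NULL, nodes = 601) {
  check_prior(prior)
  sched <- as_info_schedule(schedule)
  if (is.null(p) == is.null(alpha)) {
    abort("Supply exactly one of `p` and `alpha`.",
          class = "seqbayes_error_input")
  }
  if (is.null(p)) {
    check_scalar_prob(alpha, "alpha")
    p <- find_common_p(prior, sched, alpha, nodes = nodes)
  }
  p <- check_p_vec(p, sched$K)
  bounds <- bayes_boundaries(prior, p, sched)
  spent <- crossing_probabilities(sched, bounds, 0, nodes = nodes)$cumulative
  if (is.null(alpha)) alpha <- spent[sched$K]
  new_gs_design("bayes-normal", sched, bounds, alpha, spent,
                extra = list(prior = prior, p = p),
                subclass = c("bayes_design"))
}
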