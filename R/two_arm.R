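#' Independent per-arm normal priors
#'
#' Priors \eqn{\mu_j \sim N(\mu_{j0}, 1/I_{j0})} for the control (`j = 0`)
#' and experimental (`j = 1`) arm means, specified independently. Prior
#' information 0 encodes the flat non-informative limit for that arm. The
#' implied prior on the difference \eqn{\theta = \mu_1 - \mu_0} is normal
#' with mean \eqn{\mu_{10} - \mu_{00}} and information
#' \eqn{(I_{00}^{-1} + I_{10}^{-1})^{-1}}, but the posterior for \eqn{\theta}
#' is not the one obtained from that collapsed prior: it depends on both arm
#' means, not only their difference.
#'
#' @param mu00,info00 Control-arm prior mean and information (`info00 >= 0`).
#' @param mu10,info10 Experimental-arm prior mean and information.
#' @return An object of class `group_prior_pair`.
#' @examples
#' group_prior_pair(mu00 = 0, info00 = 0.5, mu10 = 0, info10 = 0)
#' @export
group_prior_pair <- function(mu00 = 0, info00 = 0, mu10 = 0, info10 = 0) {
  check_scalar_num(mu00, "mu00")
  check_scalar_num(info00, "info00", lower = 0)
  check_scalar_num(mu10, "mu10")
  check_scalar_num(info10, "info10", lower = 0)
  structure(list(mu00 = mu00, info00 = info00, mu10 = mu10, info10 = info10),
            class = "group_prior_pair")
}

#' @export
print.group_prior_pair <- function(x, ...) {
  cat("<group_prior_pair>\n")
  cat("  control:      mu00 =", format(x$mu00), " info00 =", format(x$info00), "\n")
  cat("  experimental: mu10 =", format(x$mu10), " info10 =", format(x$info10), "\n")
  invisible(x)
}

check_gpp <- function(priors) {
  if (!inherits(priors, "group_prior_pair")) {
    abort("`priors` must be a group_prior_pair.", class = "seqbayes_error_input")
  }
  priors
}

#' Per-arm information schedule for a two-arm design
#'
#' @param info0,info1 Strictly increasing positive information vectors
#'   \eqn{I_{jk} = n_{jk}/\sigma_j^2} for the control and experimental arm,
#'   same length K.
#' @return An object of class `two_arm_schedule`.
#' @examples
#' two_arm_schedule(info0 = seq(4, 20, 4), info1 = seq(4, 20, 4))
#' @export
two_arm_schedule <- function(info0, info1) {
  s0 <- info_schedule(info0)
  s1 <- info_schedule(info1)
  if (s0$K != s1$K) {
    abort("Per-arm schedules must have the same number of looks.",
          class = "seqbayes_error_dimension")
  }
  structure(list(K = s0$K, info0 = s0$info, info1 = s1$info),
            class = "two_arm_schedule")
}

#' @export
print.two_arm_schedule <- function(x, ...) {
  cat("<two_arm_schedule> K =", x$K, "\n")
  cat("  control info:     ", paste(format(x$info0), collapse = ", "), "\n")
  cat("  experimental info:", paste(format(x$info1), collapse = ", "), "\n")
  invisible(x)
}

check_tas <- function(schedule) {
  if (!inherits(schedule, "two_arm_schedule")) {
    abort("`schedule` must be a two_arm_schedule.",
          class = "seqbayes_error_input")
  }
  schedule
}

#' Posterior for the difference under independent per-arm priors
#'
#' The per-arm posteriors are independent normals, so the posterior for
#' \eqn{\theta = \mu_1 - \mu_0} is normal with mean
#' \eqn{M_k = (\mu_{10} I_{10} + \bar y_{1k} I_{1k})/(I_{10} + I_{1k}) -
#' (\mu_{00} I_{00} + \bar y_{0k} I_{0k})/(I_{00} + I_{0k})} and precision
#' \eqn{I_{[2]k} = \big((I_{10} + I_{1k})^{-1} + (I_{00} + I_{0k})^{-1}\big)^{-1}}.
#'
#' @param priors A [group_prior_pair()].
#' @param ybar0,ybar1 Observed cumulative means in each arm.
#' @param info0k,info1k Data information in each arm at the look (positive).
#' @return A list with `mean` (\eqn{M_k}) and `precision` (\eqn{I_{[2]k}}).
#' @examples
#' posterior_theta_two_prior(group_prior_pair(0, 0.5, 0, 0),
#'                           ybar0 = 0, ybar1 = 0.4, info0k = 4, info1k = 4)
#' @export
posterior_theta_two_prior <- function(priors, ybar0, ybar1, info0k, info1k) {
  check_gpp(priors)
  if (any(info0k <= 0) || any(info1k <= 0)) {
    abort("Data information must be positive in both arms.",
          class = "seqbayes_error_input")
  }
  m1 <- (priors$mu10 * priors$info10 + ybar1 * info1k) /
    (priors$info10 + info1k)
  m0 <- (priors$mu00 * priors$info00 + ybar0 * info0k) /
    (priors$info00 + info0k)
  prec <- 1 / (1 / (priors$info10 + info1k) + 1 / (priors$info00 + info0k))
  list(mean = m1 - m0, precision = prec)
}

#' Compare posterior precisions: collapsed prior vs independent priors
#'
#' \eqn{I_{[1]k}} is the posterior precision for \eqn{\theta} when the
#' per-arm priors are collapsed to a single prior on the difference;
#' \eqn{I_{[2]k}} is the precision under independent per-arm priors. Always
#' \eqn{I_{[1]k} \le I_{[2]k}}, with equality exactly when
#' \eqn{\Lambda_k = (I_{1k}/I_{0k})/(I_{10}/I_{00}) = 1}: knowing both arm
#' means (not just their difference) is informative about \eqn{\theta}
#' because independent priors make \eqn{\theta} and \eqn{\mu_1 + \mu_0}
#' dependent.
#'
#' @inheritParams posterior_theta_two_prior
#' @return A tibble with columns `I1` (collapsed), `I2` (independent),
#'   `ratio` (\eqn{R_k = I_{[1]k}/I_{[2]k}}) and `lambda` (\eqn{\Lambda_k};
#'   `NA` when a prior information is zero, in which case the collapsed
#'   limit is used and the two precisions are compared directly).
#' @examples
#' precision_compare(group_prior_pair(0, 1, 0, 1), info0k = 1, info1k = 4)
#' @export
precision_compare <- function(priors, info0k, info1k) {
  check_gpp(priors)
  if (any(info0k <= 0) || any(info1k <= 0)) {
    abort("Data information must be positive in both arms.",
          class = "seqbayes_error_input")
  }
  # collapsed prior information; 0 if either arm prior is flat
  I0 <- if (priors$info00 > 0 && priors$info10 > 0) {
    1 / (1 / priors$info00 + 1 / priors$info10)
  } else 0
  Ik <- 1 / (1 / info0k + 1 / info1k)
  I1 <- I0 + Ik
  I2 <- 1 / (1 / (priors$info10 + info1k) + 1 / (priors$info00 + info0k))
  lambda <- if (priors$info00 > 0 && priors$info10 > 0) {
    (info1k / info0k) / (priors$info10 / priors$info00)
  } else NA_real_
  tibble(I1 = I1, I2 = I2, ratio = I1 / I2, lambda = lambda)
}

#' Joint law of the posterior-mean statistics of a two-arm Bayesian design
#'
#' The stopping rule "posterior probability of \eqn{\theta > 0} at least
#' \eqn{p_k}" is equivalent to \eqn{M_k \ge \Phi^{-1}(p_k)/\sqrt{I_{[2]k}}},
#' where \eqn{M_k} is the posterior mean of the difference. \eqn{M_k} is
#' linear in the two arm means, so \eqn{M_1, \dots, M_K} are jointly normal:
#' \eqn{E(M_k)} depends on \eqn{\mu_0} and \eqn{\mu_1} separately (not just
#' their difference) and
#' \eqn{cov(M_k, M_{k'}) = a_k a_{k'}/I_{1,\max(k,k')} +
#' b_k b_{k'}/I_{0,\max(k,k')}} with \eqn{a_k = I_{1k}/(I_{10} + I_{1k})},
#' \eqn{b_k = I_{0k}/(I_{00} + I_{0k})}.
#'
#' @inheritParams posterior_theta_two_prior
#' @param schedule A [two_arm_schedule()].
#' @param mu0,mu1 True arm means at which the law is evaluated.
#' @param p Posterior threshold(s) in (0, 1), scalar or one per look.
#' @return A list of class `m_statistic_law` with `mean`, `cov`,
#'   `thresholds` and `precision` (\eqn{I_{[2]k}}).
#' @examples
#' m_statistic_law(group_prior_pair(0, 0.5, 0, 0),
#'                 two_arm_schedule(seq(4, 20, 4), seq(4, 20, 4)),
#'                 mu0 = 0, mu1 = 0, p = 0.9884)
#' @export
m_statistic_law <- function(priors, schedule, mu0, mu1, p) {
  check_gpp(priors)
  sched <- check_tas(schedule)
  check_scalar_num(mu0, "mu0")
  check_scalar_num(mu1, "mu1")
  p <- check_p_vec(p, sched$K)
  a <- sched$info1 / (priors$info10 + sched$info1)
  b <- sched$info0 / (priors$info00 + sched$info0)
  mean_k <- (priors$mu10 * priors$info10 + mu1 * sched$info1) /
    (priors$info10 + sched$info1) -
    (priors$mu00 * priors$info00 + mu0 * sched$info0) /
    (priors$info00 + sched$info0)
  # cov(ybar_jk, ybar_jk') = 1/I_{j,max(k,k')}
  imax1 <- outer(sched$info1, sched$info1, pmax)
  imax0 <- outer(sched$info0, sched$info0, pmax)
  cov <- outer(a, a) / imax1 + outer(b, b) / imax0
  prec <- 1 / (1 / (priors$info10 + sched$info1) +
                 1 / (priors$info00 + sched$info0))
  structure(list(mean = mean_k, cov = cov,
                 thresholds = qnorm(p) / sqrt(prec),
                 precision = prec),
            class = "m_statistic_law")
}

# first-crossing probabilities of a general Gaussian vector over upper
# thresholds, via multivariate-normal rectangle probabilities
first_crossing_mvn <- function(mean, cov, upper) {
  K <- length(mean)
  cum <- numeric(K)
  cum[1L] <- pnorm(upper[1L], mean[1L], sqrt(cov[1L, 1L]), lower.tail = FALSE)
  if (K > 1L) {
    for (k in 2:K) {
      none <- mvtnorm::pmvnorm(
        lower = rep(-Inf, k), upper = upper[seq_len(k)],
        mean = mean[seq_len(k)],
        sigma = cov[seq_len(k), seq_len(k), drop = FALSE],
        algorithm = mvtnorm::Miwa(steps = 4097))
      cum[k] <- 1 - as.numeric(none)
    }
  }
  cum <- cummax(pmin(pmax(cum, 0), 1))
  list(per_look = diff(c(0, cum)), cumulative = cum)
}

#' Stopping probability of the two-arm Bayesian rule at given arm means
#'
#' @inheritParams m_statistic_law
#' @return Overall probability that \eqn{M_k} ever crosses its threshold.
#' @keywords internal
two_arm_stop_prob <- function(priors, schedule, mu0, mu1, p) {
  law <- m_statistic_law(priors, schedule, mu0, mu1, p)
  first_crossing_mvn(law$mean, law$cov, law$thresholds)$cumulative[schedule$K]
}

#' Type I error profile over the control-arm mean
#'
#' Under independent per-arm priors the null stopping probability of the
#' Bayesian rule depends on the control mean \eqn{\mu_0} (with
#' \eqn{\mu_1 = \mu_0}), not only on \eqn{\theta = 0}. This evaluates the
#' overall stopping probability on a grid of \eqn{\mu_0} values; unless the
#' prior/data information ratios are proportional across arms the profile is
#' non-constant and exceeds the calibrated level on one side of the
#' reference point, so error control for all \eqn{\mu_0} is impossible.
#'
#' @inheritParams m_statistic_law
#' @param mu0_grid Control-mean values at which the error rate is evaluated.
#' @return A tibble of class `gs_type1_profile` with columns `mu0` and
#'   `type1`.
#' @examples
#' pr <- group_prior_pair(0, 0.5, 0, 0)
#' sc <- two_arm_schedule(seq(4, 20, 4), seq(4, 20, 4))
#' type1_profile(pr, sc, p = 0.9884, mu0_grid = c(0, 1))
#' @export
type1_profile <- function(priors, schedule, p,
                          mu0_grid = seq(-2, 3, by = 0.05)) {
  check_gpp(priors)
  sched <- check_tas(schedule)
  if (!is.numeric(mu0_grid) || length(mu0_grid) < 1L || anyNA(mu0_grid)) {
    abort("`mu0_grid` must be a numeric vector.", class = "seqbayes_error_input")
  }
  type1 <- vapply(mu0_grid, function(m0) {
    two_arm_stop_prob(priors, sched, m0, m0, p)
  }, numeric(1))
  out <- tibble(mu0 = mu0_grid, type1 = type1)
  attr(out, "p") <- p
  class(out) <- c("gs_type1_profile", class(out))
  out
}

#' Calibrate the common posterior threshold of a two-arm Bayesian design
#'
#' Finds the common \eqn{p} whose stopping probability at
#' \eqn{\mu_1 = \mu_0 = } `mu0_ref` equals `alpha` (to 1e-6), by monotone
#' root search on the logit scale. Calibration holds only at the reference
#' control mean; see [type1_profile()] for the behaviour elsewhere.
#'
#' @inheritParams m_statistic_law
#' @param alpha Target one-sided type I error at the reference point.
#' @param mu0_ref Reference control-arm mean (default 0).
#' @return The common threshold \eqn{p}.
#' @examples
#' find_common_p_two_param(group_prior_pair(0, 0.5, 0, 0),
#'                         two_arm_schedule(seq(4, 20, 4), seq(4, 20, 4)),
#'                         alpha = 0.025)
#' @export
find_common_p_two_param <- function(priors, schedule, alpha, mu0_ref = 0) {
  check_gpp(priors)
  sched <- check_tas(schedule)
  check_scalar_prob(alpha, "alpha")
  check_scalar_num(mu0_ref, "mu0_ref")
  f <- function(l) {
    two_arm_stop_prob(priors, sched, mu0_ref, mu0_ref, plogis(l)) - alpha
  }
  lo <- qlogis(0.5) + 1e-9
  hi <- qlogis(1 - 1e-12)
  if (f(lo) < 0 || f(hi) > 0) {
    abort("No common threshold in (0.5, 1) attains the target alpha.",
          class = "seqbayes_error_infeasible")
  }
  root <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  if (abs(f(root)) > 1e-6) {
    abort("Two-arm calibration did not reach the 1e-6 alpha tolerance.",
          class = "seqbayes_error_numeric")
  }
  plogis(root)
}

#' Does the two-arm design collapse to the one-parameter case?
#'
#' The posterior for the difference coincides with the collapsed-prior
#' posterior exactly when \eqn{I_{1k}/(I_{10} + I_{1k}) =
#' I_{0k}/(I_{00} + I_{0k})} at a look. When this proportionality holds at
#' every look the Bayesian rule depends on the data only through the
#' difference of means and the frequentist equivalence of the one-parameter
#' case is restored.
#'
#' @inheritParams m_statistic_law
#' @param tol Equality tolerance (default 1e-12).
#' @return Logical vector, one entry per look.
#' @examples
#' proportionality_check(group_prior_pair(0, 0.5, 0, 0),
#'                       two_arm_schedule(seq(4, 20, 4), seq(4, 20, 4)))
#' @export
proportionality_check <- function(priors, schedule, tol = 1e-12) {
  check_gpp(priors)
  sched <- check_tas(schedule)
  a <- sched$info1 / (priors$info10 + sched$info1)
  b <- sched$info0 / (priors$info00 + sched$info0)
  abs(a - b) <= tol
}

#' Monte-Carlo oracle for the two-arm stopping probability
#'
#' Simulates per-arm cumulative means directly (independent-increments
#' representation in each arm), forms the posterior means \eqn{M_k} and
#' tallies first threshold crossings.
#'
#' @inheritParams m_statistic_law
#' @param n_paths Number of simulated trials (at least 1000).
#' @param seed Integer seed.
#' @return A tibble with per-look and cumulative stopping estimates and
#'   binomial standard errors.
#' @export
simulate_two_arm_paths <- function(priors, schedule, mu0, mu1, p,
                                   n_paths, seed) {
  check_gpp(priors)
  sched <- check_tas(schedule)
  p <- check_p_vec(p, sched$K)
  if (!is.numeric(n_paths) || n_paths < 1000) {
    abort("`n_paths` must be at least 1000.", class = "seqbayes_error_input")
  }
  n_paths <- as.integer(n_paths)
  K <- sched$K
  law <- m_statistic_law(priors, sched, mu0, mu1, p)
  sim_arm <- function(info, mu) {
    delta <- diff(c(0, info))
    w <- matrix(rnorm(n_paths * K), n_paths, K)
    w <- sweep(w, 2L, sqrt(delta), `*`)
    w <- sweep(w, 2L, mu * delta, `+`)
    if (K > 1L) for (k in 2:K) w[, k] <- w[, k - 1L] + w[, k]
    sweep(w, 2L, info, `/`)   # cumulative means ybar_jk
  }
  first <- withr::with_seed(as.integer(seed), {
    y0 <- sim_arm(sched$info0, mu0)
    y1 <- sim_arm(sched$info1, mu1)
    a <- sched$info1 / (priors$info10 + sched$info1)
    b <- sched$info0 / (priors$info00 + sched$info0)
    const <- priors$mu10 * priors$info10 / (priors$info10 + sched$info1) -
      priors$mu00 * priors$info00 / (priors$info00 + sched$info0)
    m <- sweep(sweep(y1, 2L, a, `*`) - sweep(y0, 2L, b, `*`), 2L, const, `+`)
    crossed <- sweep(m, 2L, law$thresholds, `>=`)
    ifelse(rowSums(crossed) > 0, max.col(crossed, ties.method = "first"), NA)
  })
  per_look <- tabulate(first, nbins = K) / n_paths
  cum <- cumsum(per_look)
  tibble(look = seq_len(K), per_look = per_look, cumulative = cum,
         se = sqrt(pmax(cum * (1 - cum), 0) / n_paths))
}
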