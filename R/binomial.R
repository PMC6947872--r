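#' Beta prior for a success probability
#'
#' Conjugate prior \eqn{\pi \sim Beta(a, b)}; the non-informative default
#' `a = b = 1` is the uniform prior.
#'
#' @param a,b Positive shape parameters.
#' @return An object of class `beta_prior`.
#' @export
beta_prior <- function(a = 1, b = 1) {
  check_scalar_num(a, "a")
  check_scalar_num(b, "b")
  if (a <= 0 || b <= 0) {
    abort("Beta shapes must be positive.", class = "seqbayes_error_input")
  }
  structure(list(a = a, b = b), class = "beta_prior")
}

#' @export
print.beta_prior <- function(x, ...) {
  cat("<beta_prior> Beta(", x$a, ", ", x$b, ")\n", sep = "")
  invisible(x)
}

#' Look schedule for a single-arm binary endpoint
#'
#' @param n Strictly increasing positive integer cumulative sample sizes.
#' @param pi0 Reference (null) success probability in (0, 1).
#' @return An object of class `binom_schedule`.
#' @examples
#' binom_schedule(c(25, 50, 75, 100), pi0 = 0.5)
#' @export
binom_schedule <- function(n, pi0) {
  if (!is.numeric(n) || length(n) < 1L || anyNA(n) ||
      any(n != round(n)) || any(n <= 0)) {
    abort("`n` must be positive integers.",
          class = "seqbayes_error_invalid_schedule")
  }
  if (length(n) > 1L && any(diff(n) <= 0)) {
    abort("Cumulative sample sizes must be strictly increasing.",
          class = "seqbayes_error_invalid_schedule")
  }
  check_scalar_prob(pi0, "pi0")
  structure(list(K = length(n), n = as.integer(n), pi0 = pi0),
            class = "binom_schedule")
}

#' @export
print.binom_schedule <- function(x, ...) {
  cat("<binom_schedule> K =", x$K, " pi0 =", format(x$pi0), "\n")
  cat("  n:", paste(x$n, collapse = ", "), "\n")
  invisible(x)
}

check_binom_schedule <- function(x) {
  if (!inherits(x, "binom_schedule")) {
    abort("`schedule` must be a binom_schedule.", class = "seqbayes_error_input")
  }
  x
}

#' Posterior tail probability that the success rate beats the reference
#'
#' With prior \eqn{Beta(a, b)} and \eqn{x} successes in \eqn{n} patients the
#' posterior is \eqn{Beta(x + a, n - x + b)}; this returns
#' \eqn{Pr(\pi > \pi_0 \mid x, n)}, strictly increasing in \eqn{x}.
#'
#' @param prior A [beta_prior()].
#' @param x Number of successes (vectorized), `0 <= x <= n`.
#' @param n Number of patients observed.
#' @param pi0 Reference success probability.
#' @return Posterior tail probability.
#' @examples
#' posterior_tail(beta_prior(), x = 18, n = 25, pi0 = 0.5)
#' @export
posterior_tail <- function(prior, x, n, pi0) {
  if (!inherits(prior, "beta_prior")) {
    abort("`prior` must be a beta_prior.", class = "seqbayes_error_input")
  }
  check_scalar_prob(pi0, "pi0")
  if (any(x < 0 | x > n)) {
    abort("`x` must lie in [0, n].", class = "seqbayes_error_input")
  }
  pbeta(pi0, x + prior$a, n - x + prior$b, lower.tail = FALSE)
}

#' Success-count stopping thresholds for given posterior thresholds
#'
#' At look \eqn{k} the trial stops when the posterior tail probability
#' reaches \eqn{p_k}; because the tail is increasing in the success count the
#' rule is \eqn{X_k \ge s_k} with \eqn{s_k} the smallest count whose
#' posterior tail is at least \eqn{p_k}. The sentinel \eqn{n_k + 1} marks a
#' look at which no count suffices.
#'
#' @inheritParams posterior_tail
#' @param schedule A [binom_schedule()].
#' @param p Posterior threshold(s) in (0, 1), scalar or one per look.
#' @return Integer vector of K success thresholds.
#' @examples
#' success_thresholds(beta_prior(), binom_schedule(c(25, 50, 75, 100), 0.5), 0.977)
#' @export
success_thresholds <- function(prior, schedule, p) {
  sched <- check_binom_schedule(schedule)
  p <- check_p_vec(p, sched$K)
  vapply(seq_len(sched$K), function(k) {
    n_k <- sched$n[k]
    tails <- posterior_tail(prior, 0:n_k, n_k, sched$pi0)
    hit <- which(tails >= p[k])
    if (length(hit) == 0L) n_k + 1L else as.integer(hit[1L] - 1L)
  }, integer(1))
}

#' Exact stopping probability of a binomial sequential design
#'
#' Forward recursion over the continuation distribution of the cumulative
#' success count: states \eqn{x < s_k} are carried to look \eqn{k + 1} by
#' convolution with the \eqn{Binomial(n_{k+1} - n_k, \pi)} increment. The
#' result is the exact probability of ever stopping; at \eqn{\pi = \pi_0}
#' this is the frequentist type I error of the design.
#'
#' @inheritParams success_thresholds
#' @param s Integer success thresholds, one per look (sentinel `n_k + 1`
#'   allowed).
#' @param pi True success probability.
#' @param per_look If `TRUE` return the per-look and cumulative stopping
#'   probabilities as a tibble instead of the overall probability.
#' @return Overall stopping probability, or a tibble when `per_look = TRUE`.
#' @examples
#' sched <- binom_schedule(c(25, 50, 75, 100), 0.5)
#' exact_type1(sched, c(18, 33, 47, 61), pi = 0.5)
#' @export
exact_type1 <- function(schedule, s, pi, per_look = FALSE) {
  sched <- check_binom_schedule(schedule)
  check_scalar_prob(pi, "pi", open = FALSE)
  if (length(s) != sched$K || any(s != round(s)) ||
      any(s < 0 | s > sched$n + 1L)) {
    abort("`s` must be K integer thresholds with 0 <= s_k <= n_k + 1.",
          class = "seqbayes_error_input")
  }
  stop_p <- numeric(sched$K)
  counts <- 0:sched$n[1L]
  probs <- dbinom(counts, sched$n[1L], pi)
  for (k in seq_len(sched$K)) {
    if (k > 1L) {
      dn <- sched$n[k] - sched$n[k - 1L]
      inc <- dbinom(0:dn, dn, pi)
      base <- counts[1L]
      new_probs <- numeric(length(counts) + dn)
      for (j in 0:dn) {
        at <- seq_along(counts) + j
        new_probs[at] <- new_probs[at] + probs * inc[j + 1L]
      }
      counts <- base + 0:(length(new_probs) - 1L)
      probs <- new_probs
    }
    crossed <- counts >= s[k]
    stop_p[k] <- sum(probs[crossed])
    counts <- counts[!crossed]
    probs <- probs[!crossed]
    if (length(counts) == 0L) break
  }
  if (per_look) {
    tibble(look = seq_len(sched$K), n = sched$n, s = as.integer(s),
           per_look = stop_p, cumulative = cumsum(stop_p))
  } else {
    sum(stop_p)
  }
}

#' Calibrate the common posterior threshold of an exact binomial design
#'
#' The type I error is a left-continuous step function of the common
#' threshold \eqn{p}: it changes only where \eqn{p} crosses one of the
#' finitely many attainable posterior-tail values, and at such a value the
#' \eqn{\ge} stopping rule still admits the lower success count. The set of
#' controlling thresholds is therefore an open interval \eqn{(m^*, 1)} whose
#' infimum \eqn{m^*} is the largest attainable tail value whose design
#' violates `alpha`. The smallest conforming threshold is reported at the
#' display `resolution`: the smallest multiple of `resolution` strictly
#' above \eqn{m^*} (every value above \eqn{m^*} yields the same or stricter
#' thresholds, so the returned p controls `alpha`).
#'
#' @inheritParams success_thresholds
#' @param alpha Target one-sided type I error.
#' @param resolution Reporting grid for the threshold (default 1e-3).
#' @return The smallest controlling common threshold \eqn{p} at the given
#'   resolution, with attribute `infimum` (\eqn{m^*}).
#' @examples
#' find_common_p_binomial(beta_prior(), binom_schedule(c(25, 50, 75, 100), 0.5), 0.05)
#' @export
find_common_p_binomial <- function(prior, schedule, alpha, resolution = 1e-3) {
  sched <- check_binom_schedule(schedule)
  check_scalar_prob(alpha, "alpha", open = FALSE)
  check_scalar_prob(resolution, "resolution")
  cand <- sort(unique(unlist(lapply(seq_len(sched$K), function(k) {
    posterior_tail(prior, 0:sched$n[k], sched$n[k], sched$pi0)
  }))))
  cand <- cand[cand > 0 & cand < 1]
  controls <- vapply(cand, function(p) {
    exact_type1(sched, success_thresholds(prior, sched, p), sched$pi0) <= alpha
  }, logical(1))
  if (!any(controls)) {
    # even the strictest attainable design violates alpha only if stopping
    # is still too likely at every look; the no-stopping design always
    # controls, so the infimum is the largest candidate
    m_star <- cand[length(cand)]
  } else if (all(controls)) {
    m_star <- 0
  } else {
    m_star <- cand[max(which(!controls))]
  }
  p <- (floor(m_star / resolution) + 1) * resolution
  # guard against the grid point landing at or below the infimum
  while (p <= m_star) p <- p + resolution
  if (p >= 1) {
    abort("No threshold below 1 controls the requested alpha at this resolution.",
          class = "seqbayes_error_infeasible")
  }
  structure(p, infimum = m_star)
}

#' Normal-approximation Pocock comparator for the binomial design
#'
#' Treats \eqn{\hat\theta_k = X_k/n_k - \pi_0} as normal with information
#' \eqn{I_k = n_k/(\pi_0(1 - \pi_0))}, builds the K-look Pocock design at
#' level `alpha`, and converts the constant boundary \eqn{c} to the
#' success-count scale: \eqn{x_k = \pi_0 n_k + c\sqrt{\pi_0(1 - \pi_0) n_k}}.
#' Both the raw and rounded-up thresholds are reported; rounding up gives the
#' usable integer rule.
#'
#' @inheritParams success_thresholds
#' @param alpha Overall one-sided type I error.
#' @inheritParams crossing_probabilities
#' @return A tibble of class `binom_normal_approx` with columns `look`, `n`,
#'   `raw` and `rounded`, and attribute `constant` (the Pocock \eqn{c}).
#' @examples
#' normal_approx_design(binom_schedule(c(25, 50, 75, 100), 0.5), 0.05)
#' @export
normal_approx_design <- function(schedule, alpha, nodes = 601) {
  sched <- check_binom_schedule(schedule)
  check_scalar_prob(alpha, "alpha")
  info <- sched$n / (sched$pi0 * (1 - sched$pi0))
  d <- pocock_design(info_schedule(info), alpha, nodes = nodes)
  c_ <- d$bounds[1L]
  raw <- sched$pi0 * sched$n +
    c_ * sqrt(sched$pi0 * (1 - sched$pi0) * sched$n)
  out <- tibble(look = seq_len(sched$K), n = sched$n,
                raw = raw, rounded = as.integer(ceiling(raw)))
  attr(out, "constant") <- c_
  class(out) <- c("binom_normal_approx", class(out))
  out
}

#' Exact Bayesian binomial group-sequential design
#'
#' Calibrates (or accepts) the common posterior threshold and assembles the
#' full design report: thresholds, per-look and cumulative stopping
#' probabilities under the reference rate.
#'
#' @inheritParams find_common_p_binomial
#' @param p Optional common posterior threshold; if omitted it is calibrated
#'   to `alpha`.
#' @return A list of class `binom_design` with fields `prior`, `schedule`,
#'   `p`, `s`, `type1` and `table` (per-look tibble).
#' @examples
#' binom_design(beta_prior(), binom_schedule(c(25, 50, 75, 100), 0.5), alpha = 0.05)
#' @export
binom_design <- function(prior, schedule, alpha = NULL, p = NULL) {
  sched <- check_binom_schedule(schedule)
  if (is.null(p) == is.null(alpha)) {
    abort("Supply exactly one of `p` and `alpha`.",
          class = "seqbayes_error_input")
  }
  if (is.null(p)) p <- find_common_p_binomial(prior, sched, alpha)
  s <- success_thresholds(prior, sched, p)
  tab <- exact_type1(sched, s, sched$pi0, per_look = TRUE)
  structure(list(prior = prior, schedule = sched, p = p, s = s,
                 type1 = tab$cumulative[sched$K], table = tab,
                 alpha = alpha),
            class = "binom_design")
}

#' @export
print.binom_design <- function(x, ...) {
  cat("<binom_design> K =", x$schedule$K, " pi0 =", format(x$schedule$pi0),
      "\n  common posterior threshold p =", format(round(x$p, 6)),
      "\n  exact type I error =", format(round(x$type1, 6)), "\n")
  print(x$table, n = x$schedule$K)
  invisible(x)
}

#' Monte-Carlo oracle for the exact binomial recursion
#'
#' Simulates cumulative success-count paths and tallies first crossings of
#' the integer thresholds.
#'
#' @inheritParams exact_type1
#' @param n_paths Number of simulated paths (at least 1000).
#' @param seed Integer seed.
#' @return A tibble with per-look and cumulative stopping estimates and the
#'   binomial standard error of the cumulative estimate.
#' @export
simulate_binom_paths <- function(schedule, s, pi, n_paths, seed) {
  sched <- check_binom_schedule(schedule)
  if (!is.numeric(n_paths) || n_paths < 1000) {
    abort("`n_paths` must be at least 1000.", class = "seqbayes_error_input")
  }
  n_paths <- as.integer(n_paths)
  dn <- diff(c(0L, sched$n))
  first <- withr::with_seed(as.integer(seed), {
    x <- matrix(0L, n_paths, sched$K)
    run <- integer(n_paths)
    for (k in seq_len(sched$K)) {
      run <- run + rbinom(n_paths, dn[k], pi)
      x[, k] <- run
    }
    crossed <- sweep(x, 2L, s, `>=`)
    ifelse(rowSums(crossed) > 0, max.col(crossed, ties.method = "first"), NA)
  })
  per_look <- tabulate(first, nbins = sched$K) / n_paths
  cum <- cumsum(per_look)
  tibble(look = seq_len(sched$K), per_look = per_look, cumulative = cum,
         se = sqrt(pmax(cum * (1 - cum), 0) / n_paths))
}
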